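# Canonical scale constants. Off-chart acuities (counting fingers and worse)
# are imputed to 1.8 logMAR; 1.68 logMAR is the worst measurable on-chart value.
LOGMAR_OFF_CHART <- 1.8
LOGMAR_ON_CHART_MAX <- 1.68

OFF_CHART_LEVELS <- c("counting_fingers", "hand_motion",
                      "light_perception", "no_light_perception")
NOTATION_LEVELS <- c("snellen_fraction", "decimal", "logmar", "off_chart")

#' Convert a Snellen fraction to decimal acuity
#'
#' Decimal acuity is the ratio numerator/denominator of a Snellen fraction
#' (e.g. 20/200 -> 0.1). Because only the ratio is used, the unit system of
#' the chart (20-foot vs 6-metre notation) is irrelevant.
#'
#' @param numerator,denominator Positive numerics (vectorized).
#' @return Numeric vector of decimal acuities.
#' @export
#' @examples
#' snellen_to_decimal(20, 200)   # 0.1
#' snellen_to_decimal(6, 12)     # 0.5
snellen_to_decimal <- function(numerator, denominator) {
  numerator <- as.numeric(numerator)
  denominator <- as.numeric(denominator)
  if (any(!is.finite(numerator)) || any(!is.finite(denominator)) ||
      any(numerator <= 0) || any(denominator <= 0)) {
    stop("Snellen numerator and denominator must be strictly positive")
  }
  numerator / denominator
}

#' Convert decimal acuity to logMAR
#'
#' logMAR = -log10(decimal acuity). Off-chart readings have no decimal value
#' and must go through [off_chart_logmar()] instead.
#'
#' @param decimal_acuity Positive numeric (vectorized).
#' @return Numeric vector of logMAR values.
#' @export
decimal_to_logmar <- function(decimal_acuity) {
  decimal_acuity <- as.numeric(decimal_acuity)
  if (any(!is.finite(decimal_acuity)) || any(decimal_acuity <= 0)) {
    stop("decimal acuity must be strictly positive; ",
         "route off-chart readings through off_chart_logmar()")
  }
  -log10(decimal_acuity)
}

#' logMAR value assigned to an off-chart acuity category
#'
#' All four off-chart subcategories (counting fingers, hand motion, light
#' perception, no light perception) are assigned 1.8 logMAR; changes within
#' the subcategories are not analysed separately, but the subcategory is
#' retained for provenance.
#'
#' @param subcategory Character vector; one of `"counting_fingers"`,
#'   `"hand_motion"`, `"light_perception"`, `"no_light_perception"`.
#' @return A `va_measure` data frame (see [va_measure()]).
#' @export
off_chart_logmar <- function(subcategory) {
  subcategory <- as.character(subcategory)
  bad <- !(subcategory %in% OFF_CHART_LEVELS)
  if (any(bad)) {
    stop("unknown off-chart subcategory: ",
         paste(unique(subcategory[bad]), collapse = ", "))
  }
  va_measure(logmar = rep(LOGMAR_OFF_CHART, length(subcategory)),
             off_chart = TRUE, subcategory = subcategory,
             source_notation = "off_chart")
}

#' Construct a VA measure on the canonical logMAR scale
#'
#' @param logmar Numeric logMAR value(s); lower is better acuity.
#' @param off_chart Logical; off-chart measures are exactly 1.8 logMAR.
#' @param subcategory Off-chart subcategory or `NA`.
#' @param source_notation Original notation of the record.
#' @return A data frame of class `va_measure` with columns `logmar`,
#'   `off_chart`, `subcategory`, `source_notation`.
#' @export
va_measure <- function(logmar, off_chart = FALSE, subcategory = NA_character_,
                       source_notation = "logmar") {
  n <- length(logmar)
  off_chart <- rep_len(off_chart, n)
  if (any(!is.finite(logmar))) stop("logmar must be finite")
  if (any(off_chart & abs(logmar - LOGMAR_OFF_CHART) > 1e-12)) {
    stop("off-chart measures must be exactly 1.8 logMAR")
  }
  out <- data.frame(
    logmar = as.numeric(logmar),
    off_chart = off_chart,
    subcategory = rep_len(as.character(subcategory), n),
    source_notation = rep_len(as.character(source_notation), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("va_measure", "data.frame")
  out
}

#' Parse heterogeneous raw VA records to canonical logMAR
#'
#' Dispatches on notation: Snellen fractions (strings `"num/den"`, `/` the
#' only separator, whitespace tolerated) are converted to decimal then
#' logMAR; decimal values to logMAR; logMAR values pass through (negative
#' values, better than 20/20, are legal); off-chart categories are assigned
#' 1.8. On-chart results above the 1.68 on-chart bound are kept as given but
#' flagged in the `parse_warning` column.
#'
#' @param notation Character vector over
#'   `c("snellen_fraction", "decimal", "logmar", "off_chart")`.
#' @param value Character (or numeric) payload: `"20/200"` for Snellen, a
#'   number for decimal/logmar, a subcategory name for off-chart.
#' @return A `va_measure` data frame with an extra `parse_warning` column
#'   (`NA` or a short flag).
#' @export
#' @examples
#' parse_va("snellen_fraction", "20/200")
#' parse_va("off_chart", "light_perception")
parse_va <- function(notation, value) {
  notation <- as.character(notation)
  value <- as.character(value)
  n <- length(notation)
  if (length(value) != n) stop("notation and value lengths differ")
  bad <- !(notation %in% NOTATION_LEVELS)
  if (any(bad)) {
    stop("unknown VA notation: ", paste(unique(notation[bad]), collapse = ", "))
  }
  logmar <- numeric(n)
  off <- logical(n)
  sub <- rep(NA_character_, n)
  warn <- rep(NA_character_, n)

  i <- notation == "snellen_fraction"
  if (any(i)) {
    parts <- strsplit(trimws(value[i]), "/", fixed = TRUE)
    ok <- lengths(parts) == 2L
    if (any(!ok)) {
      stop("malformed Snellen fraction: ",
           paste(unique(value[i][!ok]), collapse = ", "))
    }
    num <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 1L))))
    den <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 2L))))
    if (any(is.na(num)) || any(is.na(den))) {
      stop("malformed Snellen fraction: non-numeric component in ",
           paste(unique(value[i][is.na(num) | is.na(den)]), collapse = ", "))
    }
    logmar[i] <- decimal_to_logmar(snellen_to_decimal(num, den))
  }

  i <- notation == "decimal"
  if (any(i)) {
    v <- suppressWarnings(as.numeric(value[i]))
    if (any(is.na(v))) stop("malformed decimal acuity: ",
                            paste(unique(value[i][is.na(v)]), collapse = ", "))
    logmar[i] <- decimal_to_logmar(v)
  }

  i <- notation == "logmar"
  if (any(i)) {
    v <- suppressWarnings(as.numeric(value[i]))
    if (any(is.na(v))) stop("malformed logMAR value: ",
                            paste(unique(value[i][is.na(v)]), collapse = ", "))
    logmar[i] <- v
  }

  i <- notation == "off_chart"
  if (any(i)) {
    oc <- off_chart_logmar(value[i])
    logmar[i] <- oc$logmar
    off[i] <- TRUE
    sub[i] <- oc$subcategory
  }

  above <- !off & logmar > LOGMAR_ON_CHART_MAX + 1e-12
  warn[above] <- "on_chart_above_1.68"

  out <- va_measure(logmar, off_chart = off, subcategory = sub,
                    source_notation = notation)
  out$parse_warning <- warn
  out
}

#' Convert a logMAR change to ETDRS letters
#'
#' One ETDRS line is 0.1 logMAR and 5 letters, so 50 letters per logMAR.
#' The magnitude of the change is converted; the default `"floor"`
#' convention truncates fractional letters (e.g. -0.17 logMAR -> 8 letters).
#'
#' @param delta Numeric logMAR change(s).
#' @param convention `"floor"` (default) or `"nearest"`.
#' @return Integer vector of ETDRS letters.
#' @export
#' @examples
#' logmar_delta_to_letters(-0.12)  # 6
#' logmar_delta_to_letters(-0.17)  # 8
logmar_delta_to_letters <- function(delta, convention = c("floor", "nearest")) {
  convention <- match.arg(convention)
  if (any(!is.finite(delta))) stop("delta must be finite")
  x <- 50 * abs(delta)
  # absorb binary-representation error so e.g. 50*0.12 -> exactly 6 letters
  if (convention == "floor") as.integer(floor(x + 1e-9)) else as.integer(round(x))
}

#' Read a visit table and augment it with canonical logMAR values
#'
#' The visit table is a CSV with one row per patient-eye-visit and mandatory
#' header columns `patient_id`, `eye`, `visit_date` (ISO-8601),
#' `va_notation`, `va_value`, `cohort`, `gender`, `mutation`, `onset_date`.
#' Optional columns (`age_at_onset`, `prior_idebenone`) are carried through.
#'
#' @param path Path to the CSV file, or a data frame already in that schema.
#' @return The table as a data frame augmented with `logmar`, `off_chart`,
#'   `subcategory` and `parse_warning` columns; dates parsed to `Date`.
#' @export
read_visit_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "eye", "visit_date", "va_notation", "va_value",
                "cohort", "gender", "mutation", "onset_date")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("visit table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$visit_date <- as.Date(df$visit_date)
  df$onset_date <- as.Date(df$onset_date)
  m <- parse_va(df$va_notation, df$va_value)
  df$logmar <- m$logmar
  df$off_chart <- m$off_chart
  df$subcategory <- m$subcategory
  df$parse_warning <- m$parse_warning
  # stable within-eye date order for all downstream visit arithmetic
  df <- df[order(df$patient_id, df$eye, df$visit_date), , drop = FALSE]
  rownames(df) <- NULL
  df
}
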