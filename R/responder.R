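# comparison tolerance absorbing decimal representation error in
# Snellen-converted logMAR values
.resp_tol <- 1e-9

#' Clinically relevant recovery (CRR)
#'
#' Recovery is either (i) improvement from an off-chart baseline to reading
#' at least 5 letters on-chart (endpoint <= 1.6 logMAR), or (ii) for eyes
#' already on-chart, improvement of at least 10 letters (-0.2 logMAR).
#'
#' @param baseline_logmar,endpoint_logmar Numeric logMAR values (vectorized).
#' @param baseline_off_chart,endpoint_off_chart Logical off-chart flags.
#' @return Logical vector.
#' @export
classify_crr <- function(baseline_logmar, endpoint_logmar,
                         baseline_off_chart = FALSE,
                         endpoint_off_chart = FALSE) {
  n <- length(baseline_logmar)
  baseline_off_chart <- rep_len(baseline_off_chart, n)
  endpoint_off_chart <- rep_len(endpoint_off_chart, n)
  ifelse(baseline_off_chart,
         !endpoint_off_chart & endpoint_logmar <= 1.6 + .resp_tol,
         baseline_logmar - endpoint_logmar >= 0.2 - .resp_tol)
}

#' Clinically relevant stabilization (CRS)
#'
#' Maintenance of VA below 1.0 logMAR from baseline to the endpoint. Only
#' eyes with a baseline VA < 1.0 logMAR are eligible; others return `NA`
#' (not estimable for them).
#'
#' @inheritParams classify_crr
#' @return Logical vector; `NA` where the eye is not in the CRS denominator.
#' @export
classify_crs <- function(baseline_logmar, endpoint_logmar,
                         baseline_off_chart = FALSE,
                         endpoint_off_chart = FALSE) {
  eligible <- baseline_logmar < 1.0 - .resp_tol
  out <- endpoint_logmar < 1.0 - .resp_tol
  out[!eligible] <- NA
  out
}

#' Clinically relevant worsening (CRW)
#'
#' Worsening is either a transition from on-chart to off-chart, or a loss
#' of at least 10 letters (+0.2 logMAR) on-chart. Only eyes with an
#' on-chart baseline (<= 1.68 logMAR) are eligible; others return `NA`.
#'
#' @inheritParams classify_crr
#' @return Logical vector; `NA` where the eye is not in the CRW denominator.
#' @export
classify_crw <- function(baseline_logmar, endpoint_logmar,
                         baseline_off_chart = FALSE,
                         endpoint_off_chart = FALSE) {
  n <- length(baseline_logmar)
  baseline_off_chart <- rep_len(baseline_off_chart, n)
  endpoint_off_chart <- rep_len(endpoint_off_chart, n)
  eligible <- !baseline_off_chart & baseline_logmar <= 1.68 + .resp_tol
  out <- endpoint_off_chart |
    (endpoint_logmar - baseline_logmar >= 0.2 - .resp_tol)
  out[!eligible] <- NA
  out
}

#' Clinically relevant benefit (CRB)
#'
#' The composite endpoint: CRR and/or CRS. An eye outside the CRS
#' denominator (`crs = NA`) can still achieve CRB through CRR; the CRB
#' denominator is the full analysis set.
#'
#' @param crr Logical CRR verdicts.
#' @param crs Logical CRS verdicts (`NA` = not eligible, contributes FALSE).
#' @return Logical vector.
#' @export
classify_crb <- function(crr, crs) {
  crr | (!is.na(crs) & crs)
}

#' Classify all four responder outcomes for a matched dataset
#'
#' @param data Matched dataset rows (see [build_matched_dataset()]) with
#'   `baseline_logmar`, `endpoint_logmar`, `baseline_off_chart`,
#'   `endpoint_off_chart` columns.
#' @return `data` with logical columns `crr`, `crs`, `crw`, `crb` appended
#'   (`NA` marks ineligibility for CRS/CRW).
#' @export
responder_flags <- function(data) {
  data$crr <- classify_crr(data$baseline_logmar, data$endpoint_logmar,
                           data$baseline_off_chart, data$endpoint_off_chart)
  data$crs <- classify_crs(data$baseline_logmar, data$endpoint_logmar,
                           data$baseline_off_chart, data$endpoint_off_chart)
  data$crw <- classify_crw(data$baseline_logmar, data$endpoint_logmar,
                           data$baseline_off_chart, data$endpoint_off_chart)
  data$crb <- classify_crb(data$crr, data$crs)
  # audit: literal CRS (maintenance below 1.0) can coexist with CRW
  both <- !is.na(data$crs) & !is.na(data$crw) & data$crs & data$crw
  if (any(both)) {
    warning(sum(both), " eye(s) classified both CRS and CRW ",
            "(worsened >= 0.2 logMAR while remaining below 1.0)")
  }
  data
}

#' Per-group responder rates with numerators and denominators
#'
#' For each outcome and group the denominator is the number of eyes
#' eligible for that outcome and the numerator the number classified
#' responders; rates are percentages. A zero denominator yields `NA`
#' (not estimable).
#'
#' @param data Output of [responder_flags()] with a `group` column.
#' @return Data frame: outcome, group, responders, eligible, rate (percent).
#' @export
responder_rates <- function(data) {
  outcomes <- c("crb", "crr", "crs", "crw")
  groups <- unique(data$group)
  grid <- expand.grid(outcome = outcomes, group = groups,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- data[data$group == grid$group[i], grid$outcome[i]]
    den <- sum(!is.na(x))
    num <- sum(x, na.rm = TRUE)
    data.frame(outcome = toupper(grid$outcome[i]), group = grid$group[i],
               responders = num, eligible = den,
               rate = if (den > 0) 100 * num / den else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
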