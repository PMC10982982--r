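#' Matching configuration
#'
#' Parameters governing selection of natural-history (NH) baselines matched
#' on time since symptom onset.
#'
#' @param onset_L Months; mean time from second-eye symptom onset to the
#'   baseline visit in the treated cohort (target baseline timing for the
#'   subacute/dynamic branch). Usually computed by [compute_onset_L()].
#' @param window_halfwidth Months; half-width of the follow-up visit window
#'   around each analysis timepoint (default 3, i.e. 12 +/- 3 months).
#' @param chronic_bins Data frame of half-open chronic bins `(low, high]` in
#'   months since onset, with midpoints. Defaults to >1-2, >2-3, >3-4,
#'   >4-5 years (midpoints 18, 30, 42, 54 months).
#' @return A list of class `matching_config`.
#' @export
matching_config <- function(onset_L = NA_real_, window_halfwidth = 3,
                            chronic_bins = NULL) {
  if (is.null(chronic_bins)) {
    chronic_bins <- data.frame(low = c(12, 24, 36, 48),
                               high = c(24, 36, 48, 60),
                               mid = c(18, 30, 42, 54))
  }
  stopifnot(window_halfwidth > 0, all(chronic_bins$low < chronic_bins$high))
  structure(list(onset_L = onset_L, window_halfwidth = window_halfwidth,
                 chronic_bins = chronic_bins),
            class = "matching_config")
}

#' Mean time from second-eye onset to baseline in the treated cohort
#'
#' For each treated patient the later of the two eyes' onset dates is taken
#' as the second-eye onset, and the time from it to the patient's baseline
#' (first) visit is averaged over patients; the result (onset_L, months) is
#' the target used to place matched NH baselines.
#'
#' @param treated Visit table for the treated cohort.
#' @return Months (scalar).
#' @export
compute_onset_L <- function(treated) {
  if (nrow(treated) == 0) stop("empty treated cohort")
  sp <- split(treated, treated$patient_id)
  vals <- vapply(sp, function(d) {
    onset2 <- max(d$onset_date)       # later-affected eye
    baseline <- min(d$visit_date)
    if (is.na(onset2)) return(NA_real_)
    as.numeric(baseline - onset2) / DAYS_PER_MONTH
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Enumerate candidate baseline/follow-up visit pairs for one eye
#'
#' All ordered pairs of an eye's visits whose separation falls within
#' `timepoint +/- window` months qualify as a candidate (baseline,
#' follow-up) pair.
#'
#' @param months Numeric vector of visit times in months since symptom
#'   onset (sorted or not).
#' @param timepoint Analysis timepoint in months (e.g. 12 or 24).
#' @param window Window half-width in months (default 3).
#' @return Data frame with columns `baseline`, `followup` (months since
#'   onset), sorted by baseline then follow-up; zero rows when no pair
#'   qualifies.
#' @export
enumerate_visit_pairs <- function(months, timepoint, window = 3) {
  m <- pairs_matrix(months, timepoint, window)
  out <- data.frame(baseline = m[, 1], followup = m[, 2])
  out[order(out$baseline, out$followup), , drop = FALSE]
}

# matrix core of enumerate_visit_pairs (baseline, followup columns),
# sorted by baseline then follow-up
pairs_matrix <- function(months, timepoint, window) {
  months <- sort(as.numeric(months))
  n <- length(months)
  if (n < 2) return(matrix(numeric(), ncol = 2))
  b <- rep(seq_len(n - 1), times = (n - 1):1)
  f <- sequence((n - 1):1, from = 2:n)
  gap <- months[f] - months[b]
  tol <- 1e-9
  keep <- gap >= timepoint - window - tol & gap <= timepoint + window + tol
  cbind(months[b][keep], months[f][keep])
}

# among pair rows, keep one per distinct baseline: the follow-up closest
# to baseline + timepoint (selection is by baseline; the follow-up tie is
# broken toward the nominal timepoint, then the earlier follow-up)
dedupe_matrix <- function(m, timepoint) {
  if (nrow(m) < 2) return(m)
  d <- abs(m[, 2] - (m[, 1] + timepoint))
  ord <- order(m[, 1], d, m[, 2])
  m <- m[ord, , drop = FALSE]
  m[!duplicated(m[, 1]), , drop = FALSE]
}

#' Select the matched NH baseline in the subacute/dynamic phase
#'
#' Among visit pairs whose baseline lies within 1 year of symptom onset,
#' the pair whose baseline time since onset is closest to `onset_L` is
#' selected; ties go to the earlier baseline.
#'
#' @param months Visit times in months since onset for one NH eye.
#' @param config A [matching_config()] with `onset_L` set.
#' @param timepoint Analysis timepoint in months.
#' @return One-row data frame (`baseline`, `followup`,
#'   `selection_distance`) or `NULL` when no pair qualifies.
#' @export
match_subacute <- function(months, config, timepoint) {
  stopifnot(inherits(config, "matching_config"), is.finite(config$onset_L))
  m <- pairs_matrix(months, timepoint, config$window_halfwidth)
  m <- m[m[, 1] <= 12 + 1e-9, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  m <- dedupe_matrix(m, timepoint)
  d <- abs(m[, 1] - config$onset_L)
  sel <- m[order(d, m[, 1])[1L], ]
  data.frame(baseline = sel[1], followup = sel[2],
             selection_distance = abs(sel[1] - config$onset_L))
}

#' Select matched NH baselines in the chronic phase (one per bin)
#'
#' Visit pairs are categorised into year bins (>1-2, >2-3, >3-4, >4-5
#' years since onset at baseline). Within a bin, the pair whose baseline is
#' closest to the bin midpoint is selected; ties go to the earlier
#' baseline. One eye can contribute a pair to each bin.
#'
#' @inheritParams match_subacute
#' @return Data frame with one row per occupied bin (`bin`, `baseline`,
#'   `followup`, `selection_distance`); zero rows when none qualify.
#' @export
match_chronic <- function(months, config, timepoint) {
  stopifnot(inherits(config, "matching_config"))
  pairs <- pairs_matrix(months, timepoint, config$window_halfwidth)
  bins <- config$chronic_bins
  out <- lapply(seq_len(nrow(bins)), function(i) {
    inbin <- pairs[, 1] > bins$low[i] & pairs[, 1] <= bins$high[i] + 1e-9
    p <- pairs[inbin, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    p <- dedupe_matrix(p, timepoint)
    d <- abs(p[, 1] - bins$mid[i])
    sel <- p[order(d, p[, 1])[1L], ]
    c(i, sel[1], sel[2], abs(sel[1] - bins$mid[i]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(bin = integer(), baseline = numeric(),
                      followup = numeric(), selection_distance = numeric()))
  }
  data.frame(bin = as.integer(out[, 1]), baseline = out[, 2],
             followup = out[, 3], selection_distance = out[, 4])
}

# per-eye helper: months since onset for each visit of one eye
visit_months <- function(d) months_since_onset(d$onset_date[1], d$visit_date)

#' Assemble the matched analysis dataset for one phase and timepoint
#'
#' Treated eyes contribute their actual baseline (first visit) and the
#' scheduled visit closest to the analysis timepoint within the follow-up
#' window; eyes lacking such an endpoint are dropped (recorded in the
#' ledger). NH eyes contribute the baseline/follow-up pair chosen by the
#' phase-appropriate matching algorithm; chronic NH eyes may contribute one
#' row per bin.
#'
#' @param treated,nh Visit tables (post-eligibility) for the two cohorts.
#' @param phase `"subacute_dynamic"` or `"chronic"`.
#' @param timepoint Analysis timepoint in months (12 or 24).
#' @param config A [matching_config()]; if `onset_L` is `NA` it is computed
#'   from the treated cohort.
#' @return A list with `data` (one row per eye: group, gender, mutation,
#'   age_at_onset, baseline/endpoint logmar and off-chart flags, months
#'   since onset at baseline) and `ledger` (treated eyes dropped for lack
#'   of an endpoint visit).
#' @export
build_matched_dataset <- function(treated, nh, phase = "subacute_dynamic",
                                  timepoint = 12, config = matching_config()) {
  stopifnot(phase %in% c("subacute_dynamic", "chronic"))
  if (is.na(config$onset_L)) config$onset_L <- compute_onset_L(treated)
  w <- config$window_halfwidth

  # per-eye selection returns global row indices (baseline, follow-up, bin);
  # the analysis table is assembled by vectorized indexing at the end
  select_eye <- function(rows, mo, is_treated) {
    if (is_treated) {
      ph <- phase_of(mo[1])
      if (is.na(ph) || ph != phase) return(NULL)
      rel <- mo - mo[1]                       # months since baseline visit
      cand <- which(rel >= timepoint - w - 1e-9 & rel <= timepoint + w + 1e-9)
      if (length(cand) == 0) return("dropped")
      f <- cand[order(abs(rel[cand] - timepoint), rel[cand])][1L]
      cbind(b = rows[1L], f = rows[f], bin = NA_integer_)
    } else if (phase == "subacute_dynamic") {
      sel <- match_subacute(mo, config, timepoint)
      if (is.null(sel)) return(NULL)
      cbind(b = rows[match(sel$baseline, mo)],
            f = rows[match(sel$followup, mo)], bin = NA_integer_)
    } else {
      sel <- match_chronic(mo, config, timepoint)
      if (nrow(sel) == 0) return(NULL)
      cbind(b = rows[match(sel$baseline, mo)],
            f = rows[match(sel$followup, mo)], bin = sel$bin)
    }
  }

  collect <- function(visits, is_treated) {
    key <- eye_keys(visits)
    mo_all <- months_since_onset(visits$onset_date, visits$visit_date)
    idx <- split(seq_len(nrow(visits)), key)
    out <- lapply(idx, function(rows) {
      select_eye(rows, mo_all[rows], is_treated)
    })
    dropped <- sum(vapply(out, identical, logical(1), "dropped"))
    sel <- do.call(rbind, Filter(is.matrix, out))
    list(sel = sel, dropped = dropped, mo = mo_all)
  }

  tsel <- collect(treated, TRUE)
  nsel <- collect(nh, FALSE)
  assemble <- function(visits, cl) {
    s <- cl$sel
    if (is.null(s)) return(NULL)
    data.frame(
      patient_id = visits$patient_id[s[, "b"]],
      eye = visits$eye[s[, "b"]],
      group = visits$cohort[s[, "b"]],
      gender = visits$gender[s[, "b"]],
      mutation = visits$mutation[s[, "b"]],
      age_at_onset = if (!is.null(visits$age_at_onset))
        visits$age_at_onset[s[, "b"]] else NA_real_,
      months_since_onset = cl$mo[s[, "b"]],
      baseline_logmar = visits$logmar[s[, "b"]],
      baseline_off_chart = visits$off_chart[s[, "b"]],
      endpoint_logmar = visits$logmar[s[, "f"]],
      endpoint_off_chart = visits$off_chart[s[, "f"]],
      timepoint = timepoint,
      bin = s[, "bin"],
      stringsAsFactors = FALSE)
  }
  data <- rbind(assemble(treated, tsel), assemble(nh, nsel))
  if (is.null(data)) {
    data <- data.frame()
  } else {
    rownames(data) <- NULL
  }
  if (!is.null(data$group) && !any(data$group == "natural_history")) {
    warning("matched dataset contains treated rows only")
  }
  ledger <- data.frame(rule = "no_endpoint_in_window",
                       patients_excluded = NA_integer_,
                       eyes_excluded = tsel$dropped,
                       reason = sprintf(
                         "treated eye lacks a visit at %g +/- %g months",
                         timepoint, w),
                       stringsAsFactors = FALSE)
  list(data = data, ledger = ledger, onset_L = config$onset_L)
}
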