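DAYS_PER_MONTH <- 30.4375  # 365.25 / 12; fixed month length for all time arithmetic

#' Months elapsed between onset and a reference date
#'
#' @param onset_date,reference_date `Date` vectors; reference must not
#'   precede onset.
#' @return Numeric months (days / 30.4375).
#' @export
months_since_onset <- function(onset_date, reference_date) {
  onset_date <- as.Date(onset_date)
  reference_date <- as.Date(reference_date)
  d <- as.numeric(reference_date - onset_date)
  if (any(d < 0, na.rm = TRUE)) stop("reference_date precedes onset_date")
  d / DAYS_PER_MONTH
}

#' Disease phase at a given time since symptom onset
#'
#' Phases: subacute (< 6 months), dynamic (6-12 months), pooled
#' subacute/dynamic (<= 12 months, the 12-month boundary inclusive), chronic
#' (> 12 to <= 60 months). Beyond 60 months the eye is not classifiable
#' (ineligible) and `NA` is returned.
#'
#' @param months Numeric months since symptom onset.
#' @param fine If `TRUE`, distinguish subacute from dynamic within the first
#'   year; default pools them as `"subacute_dynamic"`.
#' @return Character vector of phase labels (`NA` where unclassifiable).
#' @export
phase_of <- function(months, fine = FALSE) {
  out <- rep(NA_character_, length(months))
  if (fine) {
    out[months < 6] <- "subacute"
    out[months >= 6 & months <= 12] <- "dynamic"
  } else {
    out[months <= 12] <- "subacute_dynamic"
  }
  out[months > 12 & months <= 60] <- "chronic"
  out
}

new_ledger <- function() {
  data.frame(rule = character(), patients_excluded = integer(),
             eyes_excluded = integer(), reason = character(),
             stringsAsFactors = FALSE)
}

ledger_add <- function(ledger, rule, drop_keys, all_keys, patients, reason) {
  rbind(ledger, data.frame(
    rule = rule,
    patients_excluded = length(unique(patients[drop_keys])),
    eyes_excluded = length(unique(drop_keys)),
    reason = reason, stringsAsFactors = FALSE))
}

eye_keys <- function(visits) paste(visits$patient_id, visits$eye, sep = ":")

# Apply exclusion rules in declared order; each eye is excluded under its
# first failing rule only. `rules` is a named list of predicate functions
# over the per-eye summary data frame, returning TRUE where the eye FAILS.
apply_rules <- function(visits, rules, reasons) {
  key <- eye_keys(visits)
  per_eye <- visits[!duplicated(key), , drop = FALSE]
  ek <- eye_keys(per_eye)
  # per-eye visit counts after onset
  post <- !is.na(visits$onset_date) & visits$visit_date >= visits$onset_date
  per_eye$n_post_onset <- as.integer(table(factor(key[post], levels = ek)))
  ledger <- new_ledger()
  alive <- rep(TRUE, nrow(per_eye))
  pat <- setNames(per_eye$patient_id, ek)
  for (rn in names(rules)) {
    p <- rules[[rn]](per_eye)
    fail <- alive & !is.na(p) & p   # rules see NA as not-failing (handled by
                                    # the dedicated unknown-onset rule)
    ledger <- ledger_add(ledger, rn, ek[fail], ek, pat, reasons[[rn]])
    alive <- alive & !fail
  }
  keep <- key %in% ek[alive]
  retained <- visits[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, ledger = ledger)
}

baseline_age <- function(per_eye) {
  # age at the eye's first visit = age at onset + elapsed years
  elapsed <- as.numeric(per_eye$first_visit - per_eye$onset_date) / 365.25
  per_eye$age_at_onset + ifelse(is.na(elapsed), 0, elapsed)
}

add_first_visit <- function(visits, per_eye) {
  key <- eye_keys(visits)
  fv <- tapply(visits$visit_date, key, min)
  per_eye$first_visit <- as.Date(fv[eye_keys(per_eye)],
                                 origin = "1970-01-01")
  per_eye
}

#' Treated-arm eligibility
#'
#' Excludes, in order: unknown onset date; age at baseline below 12 years;
#' symptom onset more than 5 years before baseline; prior idebenone use.
#' Baseline is the eye's first recorded visit. Returns the retained visit
#' rows and an exclusion ledger with per-rule patient and eye counts.
#'
#' @param visits Visit table (see [read_visit_table()]) for the treated cohort.
#' @return A list with elements `retained` (visit table) and `ledger`
#'   (data frame: rule, patients_excluded, eyes_excluded, reason).
#' @export
apply_treated_eligibility <- function(visits) {
  rules <- list(
    unknown_onset = function(pe) is.na(pe$onset_date),
    age_below_12 = function(pe) {
      pe <- add_first_visit(visits, pe); baseline_age(pe) < 12
    },
    onset_over_5y = function(pe) {
      pe <- add_first_visit(visits, pe)
      months_since_onset(pe$onset_date, pe$first_visit) > 60
    },
    prior_idebenone = function(pe) {
      if (is.null(pe$prior_idebenone)) rep(FALSE, nrow(pe))
      else isTRUE_vec(pe$prior_idebenone)
    }
  )
  reasons <- list(
    unknown_onset = "unknown year of symptom onset",
    age_below_12 = "age at baseline < 12 years",
    onset_over_5y = "symptom onset > 5 years prior to baseline",
    prior_idebenone = "previous idebenone use"
  )
  apply_rules(visits, rules, reasons)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Natural-history cohort eligibility
#'
#' Excludes, in order: age below 12 years; unknown onset date; onset more
#' than 5 years before the first qualifying visit; fewer than 2 VA
#' assessments after onset; previous idebenone use.
#'
#' @inheritParams apply_treated_eligibility
#' @return A list with elements `retained` and `ledger`.
#' @export
apply_nh_eligibility <- function(visits) {
  rules <- list(
    age_below_12 = function(pe) {
      pe <- add_first_visit(visits, pe)
      a <- baseline_age(pe)
      !is.na(a) & a < 12
    },
    unknown_onset = function(pe) is.na(pe$onset_date),
    onset_over_5y = function(pe) {
      pe <- add_first_visit(visits, pe)
      months_since_onset(pe$onset_date, pe$first_visit) > 60
    },
    under_2_assessments = function(pe) pe$n_post_onset < 2,
    prior_idebenone = function(pe) {
      if (is.null(pe$prior_idebenone)) rep(FALSE, nrow(pe))
      else isTRUE_vec(pe$prior_idebenone)
    }
  )
  reasons <- list(
    age_below_12 = "age < 12 years",
    unknown_onset = "unknown year of symptom onset",
    onset_over_5y = "symptom onset > 5 years before first visit",
    under_2_assessments = "fewer than 2 VA assessments after onset",
    prior_idebenone = "previous idebenone use"
  )
  apply_rules(visits, rules, reasons)
}

#' Restrict to the three common causative mtDNA mutations
#'
#' The modified intention-to-treat (mITT) set keeps only eyes carrying
#' m.11778G>A, m.3460G>A or m.14484T>C.
#'
#' @inheritParams apply_treated_eligibility
#' @return A list with elements `retained` and `ledger`.
#' @export
restrict_to_common_mutations <- function(visits) {
  common <- c("m11778GA", "m3460GA", "m14484TC")
  rules <- list(uncommon_mutation = function(pe) !(pe$mutation %in% common))
  reasons <- list(uncommon_mutation =
    "mutation not one of m.11778G>A, m.3460G>A, m.14484T>C (mITT)")
  apply_rules(visits, rules, reasons)
}
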