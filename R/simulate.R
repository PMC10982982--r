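# Standard Snellen line set used when emitting Snellen-notation records;
# values are snapped to the nearest line by logMAR distance.
SNELLEN_LINES <- data.frame(
  num = 20,
  den = c(20, 25, 32, 40, 50, 63, 80, 100, 125, 160,
          200, 250, 320, 400, 500, 640, 800, 1000))
SNELLEN_LINES$logmar <- -log10(SNELLEN_LINES$num / SNELLEN_LINES$den)

#' Configuration of the synthetic LHON cohort generator
#'
#' Defaults emulate the study conditions: a treated trial cohort with a
#' fixed follow-up schedule and an untreated natural-history (NH) cohort
#' reconstructed from irregular case records in mixed VA notations
#' (Snellen 51.3%, logMAR 12.7%, decimal 14.5% among on-chart readings).
#' Disease course is subacute decline to a nadir around 6 months, then a
#' plateau, with mutation-dependent spontaneous recovery; treatment adds
#' log-odds to the recovery probability.
#'
#' @param n_treated,n_nh Patients per cohort (two eyes each).
#' @param mutation_mix Named proportions over the three common mutations.
#' @param male_prop Proportion male.
#' @param age_onset_mean,age_onset_sd Age at onset (years), truncated at
#'   `age_min`.
#' @param age_min Minimum age at onset.
#' @param nadir_time_mean,nadir_time_sd Months from onset to nadir.
#' @param nadir_depth_mean,nadir_depth_sd Nadir logMAR (clipped to
#'   `[0.5, 1.8]`; defaults put roughly a third of eyes off-chart at nadir).
#' @param recovery_prob Named per-mutation spontaneous recovery
#'   probabilities (untreated).
#' @param treatment_logodds Additive log-odds of recovery under treatment.
#' @param treatment_drift Additive logMAR change per year under treatment
#'   (negative improves acuity); 0 by default.
#' @param recovery_onset_range Months since onset between which recovery
#'   begins (uniform draw).
#' @param recovery_amount_range logMAR improvement achieved by recoverers
#'   (uniform draw).
#' @param recovery_ramp Months over which the recovery ramps in.
#' @param noise_sd Measurement noise sd (logMAR).
#' @param visit_jitter_sd Jitter sd (months) on scheduled treated visits.
#' @param notation_mix Named proportions over
#'   `c("snellen_fraction", "logmar", "decimal")` for on-chart NH records
#'   (renormalised internally); treated records are always logMAR (ETDRS).
#' @param missing_prob Probability a scheduled visit is missing.
#' @param treated_phase `"subacute_dynamic"`, `"chronic"` or `"both"`:
#'   which phase treated baselines are drawn in.
#' @param treated_baseline_range Months since second-eye onset between
#'   which the treated baseline falls (defaults per phase).
#' @param second_eye_delay_mean Mean months between fellow-eye onsets
#'   (exponential).
#' @param nh_schedule `"irregular"` (gamma-distributed gaps) or
#'   `"regular"` (visits at first visit + 0, 12, 24 months).
#' @param nh_first_visit_range Months since onset of the first NH visit.
#' @param nh_gap_mean Mean months between NH visits (irregular schedule).
#' @param nh_max_months NH records end this many months after onset.
#' @param nh_unknown_onset_prob Fraction of NH patients with unknown onset
#'   (eligibility-test injection).
#' @param nh_single_visit_prob Fraction of NH eyes with only one visit.
#' @param seed RNG seed fixing the full output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_treated = 100, n_nh = 372,
                       mutation_mix = c(m11778GA = 0.60, m3460GA = 0.20,
                                        m14484TC = 0.20),
                       male_prop = 0.735,
                       age_onset_mean = 32.5, age_onset_sd = 14.3,
                       age_min = 8,
                       nadir_time_mean = 6, nadir_time_sd = 2,
                       nadir_depth_mean = 1.55, nadir_depth_sd = 0.35,
                       recovery_prob = c(m11778GA = 0.15, m3460GA = 0.20,
                                         m14484TC = 0.50),
                       treatment_logodds = 0.8,
                       treatment_drift = 0,
                       recovery_onset_range = c(6, 18),
                       recovery_amount_range = c(0.3, 0.8),
                       recovery_ramp = 3,
                       noise_sd = 0.1,
                       visit_jitter_sd = 0.5,
                       notation_mix = c(snellen_fraction = 0.513,
                                        logmar = 0.127, decimal = 0.145),
                       missing_prob = 0.10,
                       treated_phase = "subacute_dynamic",
                       treated_baseline_range = NULL,
                       second_eye_delay_mean = 2,
                       nh_schedule = "irregular",
                       nh_first_visit_range = c(1, 12),
                       nh_gap_mean = 6,
                       nh_max_months = 60,
                       nh_unknown_onset_prob = 0,
                       nh_single_visit_prob = 0,
                       seed = 1L) {
  stopifnot(abs(sum(mutation_mix) - 1) < 1e-8,
            all(mutation_mix >= 0), noise_sd >= 0,
            all(notation_mix >= 0), missing_prob >= 0, missing_prob <= 1,
            treated_phase %in% c("subacute_dynamic", "chronic", "both"))
  if (is.null(treated_baseline_range)) {
    treated_baseline_range <- switch(treated_phase,
      subacute_dynamic = c(1, 11), chronic = c(13, 58), both = c(1, 58))
  }
  cfg <- as.list(environment())
  cfg$notation_mix <- notation_mix / sum(notation_mix)
  structure(cfg, class = "sim_config")
}

#' Simulate one eye's latent logMAR trajectory
#'
#' Piecewise-linear course: decline from ~0.0 logMAR to a drawn nadir
#' depth by the drawn nadir time, plateau, and — for (mutation- and
#' treatment-dependent) recoverers — a linear improvement from a drawn
#' recovery-onset time toward the recovered level. Latent values are
#' clipped to [-0.3, 1.8].
#'
#' @param recoverer Logical; does this eye spontaneously recover.
#' @param config A [sim_config()]; RNG state is used as-is (callers seed).
#' @param treated Logical; applies the treatment drift if configured.
#' @return A list of trajectory parameters; evaluate with
#'   [latent_logmar()].
#' @export
simulate_trajectory <- function(recoverer, config, treated = FALSE) {
  nadir_t <- max(1, stats::rnorm(1, config$nadir_time_mean,
                                 config$nadir_time_sd))
  nadir_d <- min(1.8, max(0.5, stats::rnorm(1, config$nadir_depth_mean,
                                            config$nadir_depth_sd)))
  rec_t <- stats::runif(1, config$recovery_onset_range[1],
                        config$recovery_onset_range[2])
  rec_a <- stats::runif(1, config$recovery_amount_range[1],
                        config$recovery_amount_range[2])
  list(start = 0.0, nadir_time = nadir_t, nadir_depth = nadir_d,
       recoverer = recoverer, recovery_onset = max(rec_t, nadir_t),
       recovery_amount = rec_a, recovery_ramp = config$recovery_ramp,
       drift = if (treated) config$treatment_drift else 0)
}

#' Evaluate a latent trajectory at months since onset
#'
#' @param traj Output of [simulate_trajectory()].
#' @param months Numeric vector of times (months since onset).
#' @return logMAR values, clipped to [-0.3, 1.8].
#' @export
latent_logmar <- function(traj, months) {
  v <- ifelse(months < traj$nadir_time,
              traj$start + (traj$nadir_depth - traj$start) *
                months / traj$nadir_time,
              traj$nadir_depth)
  if (traj$recoverer) {
    prog <- pmin(1, pmax(0, (months - traj$recovery_onset) /
                           traj$recovery_ramp))
    v <- v - prog * traj$recovery_amount
  }
  if (traj$drift != 0) v <- v + traj$drift * months / 12
  pmin(1.8, pmax(-0.3, v))
}

# map a latent value > 1.68 to an off-chart subcategory by severity band
off_chart_band <- function(v) {
  cut(pmin(v, 1.8), breaks = c(1.68, 1.71, 1.74, 1.77, Inf),
      labels = OFF_CHART_LEVELS, right = TRUE) |> as.character()
}

#' Render a latent trajectory as raw VA visit records
#'
#' Adds Gaussian measurement noise, maps values above the 1.68 on-chart
#' bound to off-chart subcategory records, and emits each on-chart value
#' in a notation drawn from the configured mix (Snellen values snap to the
#' nearest standard Snellen line).
#'
#' @param traj Output of [simulate_trajectory()].
#' @param months Visit times (months since onset), already jittered and
#'   thinned by the caller.
#' @param config A [sim_config()].
#' @param notations Optional fixed notation per visit (recycled);
#'   default draws from `config$notation_mix`.
#' @return Data frame: `months`, `va_notation`, `va_value`.
#' @export
emit_visits <- function(traj, months, config, notations = NULL) {
  n <- length(months)
  if (n == 0) {
    return(data.frame(months = numeric(), va_notation = character(),
                      va_value = character()))
  }
  v <- latent_logmar(traj, months) +
    stats::rnorm(n, 0, config$noise_sd)
  if (is.null(notations)) {
    notations <- sample(names(config$notation_mix), n, replace = TRUE,
                        prob = config$notation_mix)
  } else {
    notations <- rep_len(notations, n)
  }
  off <- v > LOGMAR_ON_CHART_MAX
  value <- character(n)
  notation <- notations
  notation[off] <- "off_chart"
  value[off] <- off_chart_band(v[off])
  i <- !off & notation == "logmar"
  value[i] <- formatC(v[i], digits = 15, format = "g")
  i <- !off & notation == "decimal"
  value[i] <- formatC(10^(-v[i]), digits = 15, format = "g")
  i <- !off & notation == "snellen_fraction"
  if (any(i)) {
    j <- vapply(v[i], function(x) which.min(abs(SNELLEN_LINES$logmar - x)),
                integer(1))
    value[i] <- paste0(SNELLEN_LINES$num[j], "/", SNELLEN_LINES$den[j])
  }
  data.frame(months = months, va_notation = notation, va_value = value,
             stringsAsFactors = FALSE)
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate matched treated and natural-history cohorts
#'
#' Treated patients get a baseline visit within the configured phase and
#' scheduled follow-ups at 1, 3, 6, 12, 18 and 24 months after baseline
#' (jittered, possibly missing); NH patients get irregular
#' case-record-style visits in mixed notations. Both eyes of each patient
#' are simulated; the fellow eye's onset trails the first by an
#' exponential delay. The seed fixes the full output.
#'
#' @param config A [sim_config()].
#' @return A list with `treated` and `nh` visit tables in the schema
#'   consumed by [read_visit_table()], plus `config`.
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    origin <- as.Date("2016-01-01")
    make_patient <- function(id, cohort) {
      mut <- sample(names(config$mutation_mix), 1,
                    prob = config$mutation_mix)
      gender <- if (stats::runif(1) < config$male_prop) "male" else "female"
      age <- max(config$age_min,
                 stats::rnorm(1, config$age_onset_mean, config$age_onset_sd))
      onset1 <- origin + round(stats::runif(1, 0, 730))
      delay <- stats::rexp(1, 1 / config$second_eye_delay_mean)
      onset2 <- onset1 + round(delay * DAYS_PER_MONTH)
      p_rec <- config$recovery_prob[[mut]]
      if (cohort == "treated") {
        p_rec <- stats::plogis(stats::qlogis(p_rec) + config$treatment_logodds)
      }
      list(id = id, cohort = cohort, mutation = mut, gender = gender,
           age = age, onsets = c(right = onset1, left = onset2),
           p_rec = p_rec)
    }

    eye_records <- function(p, eye, months, notations = NULL) {
      recoverer <- stats::runif(1) < p$p_rec
      traj <- simulate_trajectory(recoverer, config,
                                  treated = p$cohort == "treated")
      months <- months[months >= 0]
      em <- emit_visits(traj, months, config, notations)
      n <- nrow(em)
      if (n == 0) return(NULL)
      list(
        patient_id = rep(p$id, n), eye = rep(eye, n),
        visit_date = format(p$onsets[[eye]] +
                              round(em$months * DAYS_PER_MONTH)),
        va_notation = em$va_notation, va_value = em$va_value,
        cohort = rep(p$cohort, n), gender = rep(p$gender, n),
        mutation = rep(p$mutation, n),
        onset_date = rep(format(p$onsets[[eye]]), n),
        age_at_onset = rep(round(p$age, 1), n),
        prior_idebenone = rep(FALSE, n))
    }

    bind_records <- function(recs) {
      recs <- Filter(Negate(is.null), recs)
      cols <- lapply(names(recs[[1]]), function(nm)
        unlist(lapply(recs, `[[`, nm), use.names = FALSE))
      names(cols) <- names(recs[[1]])
      as.data.frame(cols, stringsAsFactors = FALSE)
    }

    treated <- lapply(seq_len(config$n_treated), function(i) {
      p <- make_patient(sprintf("T%04d", i), "treated")
      # one baseline visit per patient, in months since second-eye onset
      b <- stats::runif(1, config$treated_baseline_range[1],
                        config$treated_baseline_range[2])
      baseline_date <- p$onsets[["left"]] + round(b * DAYS_PER_MONTH)
      lapply(c("right", "left"), function(eye) {
        b_eye <- as.numeric(baseline_date - p$onsets[[eye]]) / DAYS_PER_MONTH
        sched <- c(1, 3, 6, 12, 18, 24)
        fup <- sched + stats::rnorm(length(sched), 0, config$visit_jitter_sd)
        fup <- fup[stats::runif(length(fup)) >= config$missing_prob]
        eye_records(p, eye, c(b_eye, b_eye + fup), notations = "logmar")
      })
    })

    nh <- lapply(seq_len(config$n_nh), function(i) {
      p <- make_patient(sprintf("N%04d", i), "natural_history")
      unknown <- stats::runif(1) < config$nh_unknown_onset_prob
      lapply(c("right", "left"), function(eye) {
        first <- stats::runif(1, config$nh_first_visit_range[1],
                              config$nh_first_visit_range[2])
        if (config$nh_schedule == "regular") {
          months <- first + c(0, 12, 24)
        } else {
          gaps <- stats::rgamma(12, shape = 2,
                                scale = config$nh_gap_mean / 2)
          months <- first + cumsum(c(0, gaps))
          months <- months[months <= config$nh_max_months]
        }
        if (stats::runif(1) < config$nh_single_visit_prob) {
          months <- months[1]
        }
        rec <- eye_records(p, eye, months)
        if (!is.null(rec) && unknown) {
          rec$onset_date <- rep(NA_character_, length(rec$onset_date))
        }
        rec
      })
    })

    treated <- bind_records(unlist(treated, recursive = FALSE))
    nh <- bind_records(unlist(nh, recursive = FALSE))
    list(treated = treated, nh = nh, config = config)
  })
}
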