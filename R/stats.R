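#' Crude odds ratio from a 2x2 table
#'
#' OR = (a d)/(b c) from the table (a = treated responders, b = treated
#' non-responders, c = control responders, d = control non-responders).
#' When any cell is zero, 0.5 is added to all four cells (Haldane-Anscombe
#' continuity correction). The 95% CI is the Wald interval on the log
#' scale: exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param a,b,c,d Nonnegative counts.
#' @return A list with `odds_ratio`, `ci95` (length-2), `p_value`
#'   (two-sided Wald) and `counts`; `NA`s when the table is degenerate.
#' @export
crude_odds_ratio <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if ((a + b) == 0 && (c + d) == 0) {
    return(list(odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                p_value = NA_real_, counts = counts))
  }
  if (any(counts == 0)) counts <- counts + 0.5
  lor <- log(counts["a"]) + log(counts["d"]) -
    log(counts["b"]) - log(counts["c"])
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(0.975)
  list(odds_ratio = unname(exp(lor)),
       ci95 = unname(exp(lor + c(-1, 1) * z * se)),
       p_value = unname(2 * stats::pnorm(-abs(lor / se))),
       counts = c(a = a, b = b, c = c, d = d))
}

# Bias-reduced (Firth) logistic regression via IWLS with the hat-diagonal
# score correction; used when ordinary ML shows complete separation.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    inv <- solve(info)
    # hat diagonals of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
    h <- rowSums((X %*% inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, vcov = solve(crossprod(X, X * (stats::plogis(drop(X %*% beta)) *
                                                   (1 - stats::plogis(drop(X %*% beta)))))))
}

#' Logistic regression comparison of a responder outcome
#'
#' Fits outcome ~ treatment (+ covariates) by maximum likelihood and
#' reports the treatment odds ratio with a Wald 95% CI and two-sided
#' p value. The treated group is the reference-coded contrast
#' (natural_history is the reference level). Complete or quasi-complete
#' separation triggers a warning and a bias-reduced (Firth) refit.
#'
#' @param data Matched dataset with responder flags (see
#'   [responder_flags()]); rows with `NA` outcome are dropped (they are
#'   outside the outcome's denominator).
#' @param outcome One of `"crb"`, `"crr"`, `"crs"`, `"crw"`.
#' @param covariates Character vector of additional fixed factors; default
#'   gender and mutation, matching the primary analysis model.
#' @param age_interaction If `TRUE`, adds `age_group` (under/over 18 at
#'   baseline) and its interaction with treatment.
#' @return A list of class `lhon_comparison`: `outcome`, `odds_ratio`,
#'   `ci95`, `p_value`, `counts` (per-group numerator/denominator),
#'   `covariates`, `fit` and a `separation` flag.
#' @export
logistic_compare <- function(data, outcome = "crb",
                             covariates = c("gender", "mutation"),
                             age_interaction = FALSE) {
  stopifnot(outcome %in% c("crb", "crr", "crs", "crw"))
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (length(unique(d$group)) < 2) stop("need rows from both groups")
  d$y <- as.integer(d[[outcome]])
  d$treatment <- factor(d$group, levels = c("natural_history", "treated"))
  counts <- tapply(d$y, d$group, function(x) c(sum(x), length(x)))

  if (length(unique(d$y)) < 2) {
    return(structure(list(outcome = outcome, odds_ratio = NA_real_,
                          ci95 = c(NA_real_, NA_real_), p_value = NA_real_,
                          counts = counts, covariates = covariates,
                          fit = NULL, separation = FALSE),
                     class = "lhon_comparison"))
  }
  # drop covariates without variation (they would be aliased)
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(d[[v]])) > 1, logical(1))]
  rhs <- paste(c("treatment", covariates), collapse = " + ")
  if (age_interaction) {
    d$age_group <- factor(ifelse(d$age_at_onset + d$months_since_onset / 12 < 18,
                                 "under18", "adult"))
    rhs <- paste(rhs, "+ age_group + treatment:age_group")
  }
  form <- stats::as.formula(paste("y ~", rhs))
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = d))
  co <- stats::coef(fit)
  separation <- !fit$converged || any(abs(co) > 15, na.rm = TRUE) ||
    any(sqrt(diag(stats::vcov(fit))) > 100, na.rm = TRUE)
  if (separation) {
    warning("separation detected; using bias-reduced (Firth) logistic fit")
    X <- stats::model.matrix(form, d)
    fr <- firth_logistic(X, d$y)
    est <- fr$coef
    V <- fr$vcov
    names(est) <- colnames(X)
  } else {
    est <- co
    V <- stats::vcov(fit)
  }
  k <- "treatmenttreated"
  se <- sqrt(V[k, k])
  z <- stats::qnorm(0.975)
  structure(list(outcome = outcome,
                 odds_ratio = unname(exp(est[k])),
                 ci95 = unname(exp(est[k] + c(-1, 1) * z * se)),
                 p_value = unname(2 * stats::pnorm(-abs(est[k] / se))),
                 counts = counts, covariates = covariates, fit = fit,
                 separation = separation),
            class = "lhon_comparison")
}

#' @export
print.lhon_comparison <- function(x, ...) {
  cat(sprintf("%s: OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              toupper(x$outcome), x$odds_ratio, x$ci95[1], x$ci95[2],
              x$p_value))
  invisible(x)
}

#' ANCOVA on VA change from baseline
#'
#' Models the change in logMAR (endpoint minus baseline) on treatment,
#' gender, mutation and baseline logMAR, and reports the treatment
#' least-squares mean difference (treated minus natural history; negative
#' favours treatment) with a 95% CI and two-sided p value. In this
#' additive model the LS-mean difference equals the treatment coefficient.
#'
#' @param data Matched dataset (see [build_matched_dataset()]).
#' @return A list: `lsmean_diff`, `ci95`, `p_value`, `letters` (ETDRS
#'   letter equivalent of the difference), `fit`.
#' @export
ancova_va_change <- function(data) {
  d <- data
  d$change <- d$endpoint_logmar - d$baseline_logmar
  d$treatment <- factor(d$group, levels = c("natural_history", "treated"))
  covs <- c("gender", "mutation")[vapply(c("gender", "mutation"), function(v)
    length(unique(d[[v]])) > 1, logical(1))]
  form <- stats::as.formula(paste(
    "change ~ treatment + baseline_logmar",
    if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""))
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  k <- "treatmenttreated"
  est <- stats::coef(fit)[k]
  ci <- stats::confint(fit)[k, ]
  p <- summary(fit)$coefficients[k, 4]
  list(lsmean_diff = unname(est), ci95 = unname(ci), p_value = unname(p),
       letters = logmar_delta_to_letters(unname(est)), fit = fit)
}

#' Kaplan-Meier time to first clinically relevant recovery
#'
#' For each treated eye, each post-baseline visit is classified for CRR
#' against the eye's baseline; the event time is the months from baseline
#' to the first visit meeting CRR, with censoring at the last visit. The
#' product-limit estimate of the cumulative incidence 1 - S(t) is reported
#' at the requested months.
#'
#' @param treated Visit table for treated eyes (post-eligibility).
#' @param at Months at which to report cumulative incidence
#'   (default 6, 12, 18, 24).
#' @return A list of class `lhon_km`: `incidence` (named vector at `at`),
#'   `table` (time, n.risk, n.event, incidence), `fit` (a
#'   [survival::survfit] object), `n`.
#' @export
km_first_crr <- function(treated, at = c(6, 12, 18, 24)) {
  eyes <- split(treated, eye_keys(treated))
  if (length(eyes) == 0) stop("no eyes supplied")
  rec <- lapply(eyes, function(d) {
    mo <- visit_months(d)
    rel <- mo - mo[1]
    if (length(rel) < 2) return(NULL)
    cr <- classify_crr(rep(d$logmar[1], length(rel) - 1), d$logmar[-1],
                       rep(d$off_chart[1], length(rel) - 1), d$off_chart[-1])
    hit <- which(cr)
    if (length(hit)) data.frame(time = rel[hit[1] + 1], status = 1L)
    else data.frame(time = rel[length(rel)], status = 0L)
  })
  surv <- do.call(rbind, rec)
  if (is.null(surv) || nrow(surv) == 0) stop("no evaluable eyes")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = surv)
  sm <- summary(fit, times = at, extend = TRUE)
  inc <- stats::setNames(1 - sm$surv, paste0("month", at))
  list(incidence = inc,
       table = data.frame(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, incidence = 1 - fit$surv),
       fit = fit, n = nrow(surv)) |>
    structure(class = "lhon_km")
}

#' @export
print.lhon_km <- function(x, ...) {
  cat("Kaplan-Meier first-CRR cumulative incidence (", x$n, " eyes):\n",
      sep = "")
  print(round(100 * x$incidence, 1))
  invisible(x)
}

#' Sample size for comparing two proportions
#'
#' Normal-approximation sample size for a two-sided binomial comparison of
#' two independent proportions: variance pooled under the null, unpooled
#' under the alternative,
#' n = ceiling(((z_{1-a/2} sqrt(2 pbar (1-pbar)) +
#'   z_{1-b} sqrt(p1(1-p1)+p2(1-p2)))^2) / (p1-p2)^2)
#' with pbar the simple average of the proportions.
#'
#' @param p_control,p_treated Expected responder proportions in (0, 1);
#'   must differ.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.90).
#' @return Integer eyes per group.
#' @export
#' @examples
#' sample_size_two_proportions(0.22, 0.40)  # 137
#' sample_size_two_proportions(0.24, 0.40)  # 177
sample_size_two_proportions <- function(p_control, p_treated,
                                        alpha = 0.05, power = 0.90) {
  stopifnot(p_control > 0, p_control < 1, p_treated > 0, p_treated < 1)
  if (p_control == p_treated) stop("proportions must differ (infinite n)")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- (p_control + p_treated) / 2
  num <- za * sqrt(2 * pbar * (1 - pbar)) +
    zb * sqrt(p_control * (1 - p_control) + p_treated * (1 - p_treated))
  as.integer(ceiling((num / (p_control - p_treated))^2))
}

#' Sensitivity rerun over widened follow-up windows
#'
#' Reruns matching and the responder analysis with follow-up windows of
#' +/- 3, 3.5 and 4 months around the analysis timepoint, reporting the
#' responder rates and treatment odds ratio side by side. Widening the
#' window can only add matched eyes.
#'
#' @param treated,nh Visit tables (post-eligibility).
#' @param phase,timepoint As in [build_matched_dataset()].
#' @param windows Window half-widths in months.
#' @param outcome Outcome for the odds ratio (default `"crb"`).
#' @return Data frame with one row per window: window, n_treated, n_nh,
#'   rate_treated, rate_nh, odds_ratio, p_value.
#' @export
sensitivity_window_rerun <- function(treated, nh, phase = "subacute_dynamic",
                                     timepoint = 12, windows = c(3, 3.5, 4),
                                     outcome = "crb") {
  rows <- lapply(windows, function(w) {
    cfg <- matching_config(window_halfwidth = w)
    md <- build_matched_dataset(treated, nh, phase, timepoint, cfg)
    d <- responder_flags(md$data)
    rr <- responder_rates(d)
    rr <- rr[rr$outcome == toupper(outcome), ]
    cmp <- tryCatch(logistic_compare(d, outcome),
                    error = function(e) list(odds_ratio = NA_real_,
                                             p_value = NA_real_))
    get <- function(g, col) {
      v <- rr[rr$group == g, col]
      if (length(v)) v else NA
    }
    data.frame(window = w,
               n_treated = get("treated", "eligible"),
               n_nh = get("natural_history", "eligible"),
               rate_treated = get("treated", "rate"),
               rate_nh = get("natural_history", "rate"),
               odds_ratio = cmp$odds_ratio, p_value = cmp$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
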