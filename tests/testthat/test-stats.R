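test_that("crude odds ratio follows the cross-product with Wald CI", {
  r <- crude_odds_ratio(60, 82, 40, 153)
  expect_equal(r$odds_ratio, 60 * 153 / (82 * 40), tolerance = 1e-12)
  expect_equal(round(r$odds_ratio, 3), 2.799)
  # Wald CI form: exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))
  se <- sqrt(1 / 60 + 1 / 82 + 1 / 40 + 1 / 153)
  expect_equal(r$ci95,
               exp(log(r$odds_ratio) + c(-1, 1) * qnorm(0.975) * se))
  expect_equal(crude_odds_ratio(10, 10, 10, 10)$odds_ratio, 1.0)
  # continuity correction keeps zero-cell tables finite
  r0 <- crude_odds_ratio(5, 0, 3, 7)
  expect_equal(r0$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5))
  expect_true(all(is.finite(r0$ci95)))
  expect_true(is.na(crude_odds_ratio(0, 0, 0, 0)$odds_ratio))
  expect_error(crude_odds_ratio(-1, 2, 3, 4), "nonnegative")
})

make_outcome_data <- function(n_t, n_n, p_t, p_n, seed = 1) {
  set.seed(seed)
  data.frame(
    group = rep(c("treated", "natural_history"), c(n_t, n_n)),
    gender = "male", mutation = "m11778GA", age_at_onset = 30,
    months_since_onset = 6,
    crb = c(runif(n_t) < p_t, runif(n_n) < p_n))
}

test_that("no-covariate logistic OR equals the 2x2 cross-product OR", {
  d <- make_outcome_data(150, 200, 0.4, 0.2)
  a <- sum(d$crb[d$group == "treated"])
  b <- sum(!d$crb[d$group == "treated"])
  c0 <- sum(d$crb[d$group == "natural_history"])
  d0 <- sum(!d$crb[d$group == "natural_history"])
  fit <- logistic_compare(d, "crb", covariates = character())
  crude <- crude_odds_ratio(a, b, c0, d0)
  expect_equal(signif(fit$odds_ratio, 4), signif(crude$odds_ratio, 4))
  # constant-covariate model collapses to the same OR
  fit2 <- logistic_compare(d, "crb")
  expect_equal(signif(fit2$odds_ratio, 4), signif(crude$odds_ratio, 4))
})

test_that("degenerate outcomes are not estimable; separation falls back", {
  d <- make_outcome_data(30, 30, 0, 0)
  d$crb <- FALSE
  expect_true(is.na(logistic_compare(d, "crb")$odds_ratio))
  # complete separation: all treated respond, no NH responds
  d2 <- make_outcome_data(25, 25, 1, 0)
  d2$crb <- d2$group == "treated"
  expect_warning(f <- logistic_compare(d2, "crb"), "Firth")
  expect_true(f$separation)
  expect_true(is.finite(f$odds_ratio) && f$odds_ratio > 1)
})

test_that("ANCOVA reduces to the raw mean difference in balanced null designs", {
  set.seed(5)
  # identical covariate values in both groups: treatment is orthogonal to
  # gender and baseline, so the adjusted contrast equals the raw difference
  b <- runif(60, 0.5, 1.5)
  d <- data.frame(
    group = rep(c("treated", "natural_history"), each = 60),
    gender = rep(rep(c("male", "female"), 30), 2),
    mutation = "m11778GA",
    baseline_logmar = c(b, b))
  d$endpoint_logmar <- d$baseline_logmar + c(rnorm(60, -0.1, 0.05),
                                             rnorm(60, 0.05, 0.05))
  a <- ancova_va_change(d)
  chg <- d$endpoint_logmar - d$baseline_logmar
  raw <- mean(chg[d$group == "treated"]) -
    mean(chg[d$group == "natural_history"])
  expect_equal(a$lsmean_diff, raw, tolerance = 1e-9)
  # identical groups give a zero difference
  d0 <- d
  d0$endpoint_logmar <- d0$baseline_logmar + 0.1
  expect_equal(suppressWarnings(ancova_va_change(d0)$lsmean_diff), 0)
})

test_that("ANCOVA recovers an injected treatment effect on VA change", {
  set.seed(11)
  n <- 500
  d <- data.frame(
    group = rep(c("treated", "natural_history"), each = n),
    gender = sample(c("male", "female"), 2 * n, TRUE),
    mutation = sample(c("m11778GA", "m3460GA"), 2 * n, TRUE),
    baseline_logmar = runif(2 * n, 0.5, 1.5))
  d$endpoint_logmar <- d$baseline_logmar +
    ifelse(d$group == "treated", -0.15, 0) + rnorm(2 * n, 0, 0.1)
  a <- ancova_va_change(d)
  expect_lt(abs(a$lsmean_diff - (-0.15)), 0.02)
  expect_lt(a$p_value, 0.001)
})

test_that("ANCOVA treatment contrast matches the LS-means machinery", {
  skip_if_not_installed("emmeans")
  set.seed(2)
  d <- data.frame(
    group = sample(c("treated", "natural_history"), 160, TRUE),
    gender = sample(c("male", "female"), 160, TRUE),
    mutation = sample(c("m11778GA", "m3460GA", "m14484TC"), 160, TRUE),
    baseline_logmar = runif(160, 0.3, 1.6))
  d$endpoint_logmar <- d$baseline_logmar + rnorm(160, 0, 0.2)
  a <- ancova_va_change(d)
  em <- emmeans::emmeans(a$fit, "treatment")
  diff <- summary(emmeans::contrast(em, method = list(
    trt_vs_nh = c(-1, 1))))$estimate
  expect_equal(a$lsmean_diff, diff, tolerance = 1e-8)
})

test_that("Kaplan-Meier first-CRR equals the hand product-limit estimate", {
  # 4 eyes: events at months 3 and 9, censored at 6, survivor to 24
  tab <- rbind(
    make_eye_visits("K1", months = c(0, 3), logmar = c(1.0, 0.7),
                    cohort = "treated"),
    make_eye_visits("K2", months = c(0, 6), logmar = c(1.0, 1.0),
                    cohort = "treated"),
    make_eye_visits("K3", months = c(0, 6, 9), logmar = c(1.0, 1.0, 0.6),
                    cohort = "treated"),
    make_eye_visits("K4", months = c(0, 12, 24), logmar = c(1.0, 1.0, 1.0),
                    cohort = "treated"))
  # evaluation grid sits just past each nominal month because visit dates
  # are whole days (reconstructed times differ by < 0.02 months)
  km <- km_first_crr(read_visit_table(tab), at = c(3, 9, 24) + 0.1)
  # hand product-limit: S(9) = (3/4)(1/2) -> incidence 0.625
  expect_equal(unname(km$incidence), c(0.25, 0.625, 0.625), tolerance = 1e-3)
  # brute-force comparison on random instances with <= 20 eyes
  set.seed(9)
  for (r in 1:20) {
    n <- sample(3:20, 1)
    time <- sample(c(3, 6, 9, 12, 18, 24), n, TRUE)
    status <- rbinom(n, 1, 0.5)
    rows <- lapply(seq_len(n), function(i) {
      if (status[i] == 1) {
        make_eye_visits(paste0("E", i), months = c(0, time[i]),
                        logmar = c(1.0, 0.7), cohort = "treated")
      } else {
        make_eye_visits(paste0("E", i), months = c(0, time[i]),
                        logmar = c(1.0, 1.0), cohort = "treated")
      }
    })
    km <- km_first_crr(read_visit_table(do.call(rbind, rows)),
                       at = c(6, 12, 18, 24) + 0.1)
    hand <- brute_km_incidence(time, status, c(6, 12, 18, 24))
    expect_equal(unname(km$incidence), hand, tolerance = 1e-3)
  }
  expect_error(km_first_crr(read_visit_table(tab)[0, ]), "no eyes")
})

test_that("KM cumulative incidence is nondecreasing and within [0, 1]", {
  sim <- simulate_cohorts(sim_config(n_treated = 30, n_nh = 5, seed = 21))
  km <- km_first_crr(read_visit_table(sim$treated))
  expect_true(all(diff(km$incidence) >= -1e-12))
  expect_true(all(km$incidence >= 0 & km$incidence <= 1))
})

test_that("two-proportion sample size reproduces the trial calculations", {
  expect_identical(sample_size_two_proportions(0.22, 0.40), 137L)
  expect_identical(sample_size_two_proportions(0.24, 0.40), 177L)
  expect_error(sample_size_two_proportions(0.3, 0.3), "differ")
  # monotonicity: larger effects need fewer eyes, more power needs more
  n_small <- sample_size_two_proportions(0.30, 0.40)
  n_large <- sample_size_two_proportions(0.20, 0.40)
  expect_gt(n_small, n_large)
  expect_gt(sample_size_two_proportions(0.22, 0.40, power = 0.95),
            sample_size_two_proportions(0.22, 0.40, power = 0.80))
})

test_that("widening the observation window only adds matched eyes", {
  sim <- simulate_cohorts(sim_config(n_treated = 25, n_nh = 60, seed = 31))
  tr <- read_visit_table(sim$treated)
  nh <- read_visit_table(sim$nh)
  out <- suppressWarnings(sensitivity_window_rerun(tr, nh))
  expect_equal(out$window, c(3, 3.5, 4))
  expect_true(all(diff(out$n_nh) >= 0))
  expect_true(all(diff(out$n_treated) >= 0))
})
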