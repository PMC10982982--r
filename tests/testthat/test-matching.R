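test_that("visit-pair enumeration matches the worked examples", {
  p <- enumerate_visit_pairs(c(2, 5, 14), 12, 3)
  expect_equal(p$baseline, c(2, 5))
  expect_equal(p$followup, c(14, 14))
  expect_equal(nrow(enumerate_visit_pairs(c(0, 20), 12, 3)), 0)
  p2 <- enumerate_visit_pairs(c(0, 12), 12, 3)
  expect_equal(unlist(p2, use.names = FALSE), c(0, 12))
})

test_that("onset_L is the mean months from second-eye onset to baseline", {
  one <- rbind(
    make_eye_visits("P1", "right", onset = "2020-01-01",
                    months = 6 + 2, logmar = 1, cohort = "treated"),
    make_eye_visits("P1", "left", onset = "2020-03-02",
                    months = 6, logmar = 1, cohort = "treated"))
  df <- read_visit_table(one)
  # both eyes share the baseline date; second (left) onset is 2020-03-02
  expect_equal(compute_onset_L(df),
               as.numeric(min(df$visit_date) - as.Date("2020-03-02")) /
                 30.4375)
  p2 <- read_visit_table(make_eye_visits("P2", "right", onset = "2021-01-01",
                                         months = c(4, 16), logmar = c(1, 1),
                                         cohort = "treated"))
  p2_months <- as.numeric(min(p2$visit_date) - as.Date("2021-01-01")) / 30.4375
  expect_equal(compute_onset_L(rbind(df, p2)),
               mean(c(compute_onset_L(df), p2_months)))
  expect_error(compute_onset_L(df[0, ]), "empty")
})

test_that("subacute matching picks the baseline closest to onset_L", {
  cfg <- matching_config(onset_L = 4.5)
  sel <- match_subacute(c(2, 5, 14, 17), cfg, 12)
  expect_equal(sel$baseline, 5)   # |5-4.5| < |2-4.5|
  # tie broken toward the earlier baseline
  cfg$onset_L <- 4.5
  sel2 <- match_subacute(c(3, 6, 15, 18), cfg, 12)
  expect_equal(sel2$baseline, 3)
  # baselines beyond one year since onset never qualify
  expect_null(match_subacute(c(13, 25), cfg, 12))
  expect_null(match_subacute(c(2, 30), cfg, 12))
})

test_that("chronic matching selects per-bin baselines closest to midpoints", {
  cfg <- matching_config()
  sel <- match_chronic(c(15, 20, 27, 32), cfg, 12)
  expect_equal(sel$baseline[sel$bin == 1], 20)  # |20-18| < |15-18|
  sel2 <- match_chronic(c(30, 42), cfg, 12)
  expect_equal(sel2$baseline, 30)               # exact midpoint of bin 2
  # one eye can contribute a pair to each bin
  sel3 <- match_chronic(c(20, 30, 42, 54, 66), cfg, 12)
  expect_equal(sel3$bin, 1:4)
})

test_that("matching equals exhaustive brute-force enumeration (<= 6 visits)", {
  set.seed(42)
  cfg <- matching_config(onset_L = 5.2)
  for (rep in 1:250) {
    nv <- sample(2:6, 1)
    months <- sort(round(runif(nv, 0, 58), 2))
    tp <- sample(c(12, 24), 1)
    # enumeration oracle
    bp <- brute_pairs(months, tp, 3)
    ep <- enumerate_visit_pairs(months, tp, 3)
    expect_equal(nrow(ep), if (is.null(bp)) 0 else nrow(bp))
    if (!is.null(bp)) {
      expect_equal(unname(as.matrix(ep)), bp)
    }
    # subacute argmin oracle
    bs <- brute_subacute(months, cfg$onset_L, tp, 3)
    ms <- match_subacute(months, cfg, tp)
    if (is.null(bs)) expect_null(ms)
    else expect_equal(c(ms$baseline, ms$followup), unname(bs))
    # chronic per-bin argmin oracle
    bc <- brute_chronic(months, tp, 3)
    mc <- match_chronic(months, cfg, tp)
    if (is.null(bc)) expect_equal(nrow(mc), 0)
    else expect_equal(unname(as.matrix(mc[, 1:3])), unname(bc))
  }
})

test_that("selection is invariant to input visit order", {
  cfg <- matching_config(onset_L = 6)
  months <- c(3, 7, 11, 16, 19, 31)
  for (i in 1:10) {
    perm <- sample(months)
    expect_equal(match_subacute(perm, cfg, 12), match_subacute(months, cfg, 12))
    expect_equal(match_chronic(perm, cfg, 12), match_chronic(months, cfg, 12))
  }
})

test_that("widening the window never removes a qualifying pair", {
  set.seed(7)
  for (i in 1:50) {
    months <- sort(runif(sample(2:6, 1), 0, 40))
    p3 <- enumerate_visit_pairs(months, 12, 3)
    p35 <- enumerate_visit_pairs(months, 12, 3.5)
    p4 <- enumerate_visit_pairs(months, 12, 4)
    key <- function(p) paste(p$baseline, p$followup)
    expect_true(all(key(p3) %in% key(p35)))
    expect_true(all(key(p35) %in% key(p4)))
  }
})

test_that("matched datasets join treated baselines with matched NH pairs", {
  treated <- rbind(
    make_eye_visits("T1", "right", months = c(5, 8, 17), logmar = c(1.0, 1.2, 1.3),
                    cohort = "treated"),
    make_eye_visits("T2", "right", months = c(4, 28), logmar = c(0.8, 0.9),
                    cohort = "treated"))   # no 12-month endpoint: dropped
  nh <- rbind(
    make_eye_visits("N1", "right", months = c(3, 6, 15), logmar = c(1.1, 1.2, 1.4)),
    make_eye_visits("N2", "left", months = c(2, 20), logmar = c(1.0, 1.0)))
  md <- build_matched_dataset(read_visit_table(treated), read_visit_table(nh),
                              "subacute_dynamic", 12,
                              matching_config(onset_L = 5))
  expect_equal(sort(unique(md$data$group)), c("natural_history", "treated"))
  expect_equal(sum(md$data$group == "treated"), 1)       # T2 dropped
  expect_equal(md$ledger$eyes_excluded, 1)
  # N1: pairs (3,15) and (6,15); 6 is closer to onset_L = 5
  n1 <- md$data[md$data$patient_id == "N1", ]
  expect_equal(n1$months_since_onset, 6, tolerance = 0.02)
  # N2 has no qualifying pair within a year... (2,20) gap 18 > 15
  expect_false("N2" %in% md$data$patient_id)
  # an NH eye matched at both 12 and 24 months appears in both tables
  nh3 <- make_eye_visits("N3", "right", months = c(4, 16, 28),
                         logmar = c(1, 1, 1))
  md12 <- build_matched_dataset(read_visit_table(treated),
                                read_visit_table(nh3), "subacute_dynamic",
                                12, matching_config(onset_L = 5))
  md24 <- build_matched_dataset(read_visit_table(treated),
                                read_visit_table(nh3), "subacute_dynamic",
                                24, matching_config(onset_L = 5))
  expect_true("N3" %in% md12$data$patient_id)
  expect_true("N3" %in% md24$data$patient_id)
  # treated-only input warns
  expect_warning(
    build_matched_dataset(read_visit_table(treated), read_visit_table(nh)[0, ],
                          "subacute_dynamic", 12, matching_config(onset_L = 5)),
    "treated rows only")
})
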