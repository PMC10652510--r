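test_that("standardized mean differences match hand-computed values", {
  expect_equal(smd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(smd(rep(c(TRUE, FALSE), c(10, 10)),
                   rep(c(TRUE, FALSE), c(10, 10))), 0)

  # continuous toy: means 1 and 0, both sample variances 1
  expect_equal(smd(c(0, 1, 2), c(-1, 0, 1)), 1.0)

  # matched-cohort sex balance: 784/913 vs 778/913 prints as 0.02
  g1 <- rep(c(TRUE, FALSE), c(784, 913 - 784))
  g2 <- rep(c(TRUE, FALSE), c(778, 913 - 778))
  expect_equal(round(smd(g1, g2), 2), 0.02)

  # categorical SMD is a single nonnegative number, zero iff identical
  a <- rep(c("x", "y", "z"), c(50, 30, 20))
  b <- rep(c("x", "y", "z"), c(30, 40, 30))
  expect_gt(smd(a, b), 0)
  expect_equal(smd(a, a), 0)
  # two observed levels reduce to the signed binary form (on the second of
  # the sorted levels, here "m")
  expect_equal(smd(rep(c("m", "f"), c(60, 40)), rep(c("m", "f"), c(40, 60)),
                   type = "categorical"),
               smd(rep(c(TRUE, FALSE), c(60, 40)),
                   rep(c(TRUE, FALSE), c(40, 60))))

  expect_error(smd(c(1, 1), c(2, 2)), "degenerate comparison")
  expect_error(smd(numeric(0), c(1)), "at least one observation")
})

test_that("balance tables summarize arms and flag imbalance at 0.25", {
  # configure an unmistakable treatment-selection imbalance for the sign check
  co <- simulate_cohort(sim_config(
    n = 4000, seed = 8,
    hazard_params = list(ecpr = list(coefs = c(age_c = -0.6, witnessed = 0.8,
                                               shockable = 0.7)))))$cohort
  bt <- balance_table(co)
  expect_true(all(is.finite(bt$smd[!is.na(bt$smd)])))
  expect_equal(attr(bt, "cohort_label"), "original")
  expect_identical(bt$balanced[!is.na(bt$smd)],
                   abs(bt$smd[!is.na(bt$smd)]) < 0.25)
  # the generator makes treated younger and more often witnessed; the
  # original-cohort table must reproduce that imbalance direction
  age_smd <- bt$smd[bt$covariate == "age"]
  wit_smd <- bt$smd[bt$covariate == "witnessed"]
  expect_lt(age_smd, 0)
  expect_gt(wit_smd, 0)
  expect_error(balance_table(co, covariates = "nonexistent"),
               "unknown covariate")
})

test_that("matched balance uses one row per pair and hand-checkable medians", {
  recs <- list(
    toy_record("t1", age = 40L), toy_record("t2", age = 50L),
    toy_record("t3", age = 60L), toy_record("c1", age = 41L),
    toy_record("c2", age = 52L))
  tls <- list(
    toy_timeline("t1", "ECPR", 5, ecpr = 5L),
    toy_timeline("t2", "ECPR", 6, ecpr = 6L),
    toy_timeline("t3", "ECPR", 7, ecpr = 7L),
    toy_timeline("c1", "censored", 120), toy_timeline("c2", "censored", 120))
  co <- toy_cohort(recs, tls)
  m <- structure(list(pairs = data.frame(
    minute = c(5L, 6L, 7L), treated_id = c("t1", "t2", "t3"),
    control_id = c("c1", "c1", "c2"),  # c1 reused: counted once per pair
    treated_score = 0, control_score = 0, distance = 0,
    stringsAsFactors = FALSE)), class = "matched_cohort")
  bt <- balance_table(m, co, covariates = "age")
  expect_equal(bt$g1, "50 (45, 55)")      # median (IQR) of 40, 50, 60
  expect_equal(bt$g2, "41 (41, 46.5)")    # of 41, 41, 52
  identical_arms <- structure(list(pairs = data.frame(
    minute = 5L, treated_id = "t1", control_id = "t1",
    treated_score = 0, control_score = 0, distance = 0,
    stringsAsFactors = FALSE)), class = "matched_cohort")
  bt0 <- balance_table(identical_arms, co, covariates = c("age", "witnessed"))
  expect_true(all(bt0$smd[!is.na(bt0$smd)] == 0))
})

test_that("outcome proportions reproduce printed-count arithmetic", {
  x <- counts_pairs(913, 225, 149)
  op <- outcome_proportions(x$pairs, x$timelines, "survival_30d")
  expect_equal(op$n, c(913, 913))
  expect_equal(op$pct, c(24.6, 16.3))

  y <- counts_pairs(370, 44, 9)
  expect_equal(outcome_proportions(y$pairs, y$timelines)$pct, c(11.9, 2.4))

  z <- counts_pairs(50, 0, 0)
  expect_equal(outcome_proportions(z$pairs, z$timelines)$pct, c(0, 0))
})

test_that("conditional logistic odds ratios follow the discordant counts", {
  mk <- function(n10, n01, n11 = 0, n00 = 0) data.frame(
    treated_outcome = rep(c(TRUE, FALSE, TRUE, FALSE),
                          c(n10, n01, n11, n00)),
    control_outcome = rep(c(FALSE, TRUE, TRUE, FALSE),
                          c(n10, n01, n11, n00)))

  e <- conditional_logit_1to1(mk(15, 15))
  expect_equal(e$or, 1.0)

  e2 <- conditional_logit_1to1(mk(20, 10))
  expect_equal(e2$or, 2.0)
  expect_equal(round(c(e2$ci_low, e2$ci_high), 2), c(0.94, 4.27))
  expect_equal(e2$or, e2$or_numeric, tolerance = 1e-6)

  # concordant pairs are ancillary
  e3 <- conditional_logit_1to1(mk(20, 10, n11 = 60, n00 = 40))
  expect_equal(e3$or, e2$or)
  expect_equal(c(e3$ci_low, e3$ci_high), c(e2$ci_low, e2$ci_high))
  expect_equal(e3$n_pairs, 130)

  z1 <- conditional_logit_1to1(mk(5, 0))
  expect_equal(z1$estimate_type, "infinite")
  expect_true(is.finite(z1$ci_low) && z1$ci_low > 0)
  z0 <- conditional_logit_1to1(mk(0, 5))
  expect_equal(z0$estimate_type, "zero")
  expect_true(is.finite(z0$ci_high))
  expect_error(conditional_logit_1to1(mk(0, 0, n11 = 3)), "no discordant")
})

test_that("closed form equals independent maximizers on random pair sets", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    yt <- runif(n) < runif(1, 0.2, 0.6)
    yc <- runif(n) < runif(1, 0.2, 0.6)
    n10 <- sum(yt & !yc); n01 <- sum(!yt & yc)
    if (n10 == 0 || n01 == 0) next
    e <- conditional_logit_1to1(data.frame(treated_outcome = yt,
                                           control_outcome = yc))
    expect_equal(log(e$or), oracle_clogit(yt, yc), tolerance = 1e-6)
  }
  # cross-check against the survival package's conditional logistic fit
  yt <- runif(80) < 0.4; yc <- runif(80) < 0.3
  e <- conditional_logit_1to1(data.frame(treated_outcome = yt,
                                         control_outcome = yc))
  d <- data.frame(y = as.integer(c(yt, yc)), treat = rep(c(1, 0), each = 80),
                  strat = rep(seq_len(80), 2), one = 1)
  cf <- survival::coxph(survival::Surv(one, y) ~ treat +
                          survival::strata(strat),
                        data = d, method = "exact")
  expect_equal(log(e$or), unname(stats::coef(cf)), tolerance = 1e-5)
})
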