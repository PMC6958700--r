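test_that("linear_fit reproduces closed-form OLS on a hand dataset", {
  x <- c(1, 2, 4, 5, 7, 9)
  y <- c(2.1, 2.9, 5.2, 5.8, 8.3, 9.6)
  f <- linear_fit(x, y, "hand")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  tstat <- r * sqrt((length(x) - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = length(x) - 2)
  expect_equal(f$slope, slope)
  expect_equal(f$intercept, intercept)
  expect_equal(f$r, r)
  expect_equal(f$p, p)
})

test_that("linear_fit handles exact and degenerate relationships", {
  x <- 1:10
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)
  g <- linear_fit(x, rep(5, 10))
  expect_false(g$defined)
  expect_error(linear_fit(c(1, 2), c(1, 2)), "at least 3")
  # pairwise deletion of missing values
  h <- linear_fit(c(x, NA), c(2 * x + 1, 3))
  expect_identical(h$n, 10L)
})

test_that("Pearson r is invariant to positive affine rescaling", {
  set.seed(99)
  x <- stats::rnorm(40)
  y <- x + stats::rnorm(40)
  r0 <- linear_fit(x, y)$r
  expect_equal(linear_fit(3 * x + 7, y)$r, r0)
  expect_equal(linear_fit(x, 0.2 * y - 4)$r, r0)
})

test_that("anchor MCID conversion reproduces the published equivalences", {
  mk <- function(slope, r) structure(list(anchor_name = "a", n = 21,
                                          slope = slope, intercept = 0,
                                          r = r, p = 0.01, defined = TRUE),
                                     class = "correlation_result")
  expect_equal(anchor_mcid(mk(1, 0.9), 4)$value, 4)
  # SGRQ: a 4-point anchor change maps to 3.5 BEST points at slope 0.875
  expect_equal(anchor_mcid(mk(0.875, 0.61), 4)$value, 3.5)
  # CAT: a 2-point anchor change maps to 4 BEST points at slope 2
  expect_equal(anchor_mcid(mk(2, 0.61), 2)$value, 4)
  # LCQ: 1.3-point anchor change maps to 4.95 BEST points (negative slope)
  expect_equal(anchor_mcid(mk(-4.95 / 1.3, -0.52), 1.3)$value, 4.95)
  expect_error(anchor_mcid(mk(1, 0.25), 4), "ineligible")
})

test_that("half-SD MCID is half the sample SD and scale-equivariant", {
  expect_equal(half_sd_mcid(rep(4, 6))$value, 0)
  expect_equal(half_sd_mcid(c(2.7, 7.1, 11.5))$value, 2.2)
  set.seed(7)
  x <- stats::rnorm(30, 10, 3)
  expect_equal(half_sd_mcid(3 * x)$value, 3 * half_sd_mcid(x)$value)
  expect_error(half_sd_mcid(5), "at least 2")
})

test_that("exacerbation-onset MCID averages pre-period rises", {
  ev1 <- data.frame(kind = "reported", pre_period_mean = 11, baseline = 7,
                    baseline_usable = TRUE)
  expect_equal(exacerbation_onset_mcid(ev1)$value, 4)
  ev2 <- data.frame(kind = c("reported", "reported", "unreported"),
                    pre_period_mean = c(10, 12, 20), baseline = c(7, 7, 7),
                    baseline_usable = TRUE)
  expect_equal(exacerbation_onset_mcid(ev2)$value, 4)
  expect_identical(exacerbation_onset_mcid(ev2)$n_events, 2L)
  ev3 <- data.frame(kind = "unreported", pre_period_mean = 1, baseline = 1,
                    baseline_usable = TRUE)
  expect_error(exacerbation_onset_mcid(ev3), "no reported events")
})

test_that("cutoff table counts episodes and windows and is monotone", {
  ev <- data.frame(kind = "reported", peak_change = c(rep(5, 9), 3))
  win <- data.frame(change = c(rep(5, 4), rep(1, 6)))
  ct <- cutoff_performance(ev, win, cutoffs = 4)
  expect_equal(ct$sensitivity, 90)
  expect_equal(ct$specificity, 60)

  ct2 <- cutoff_performance(ev, win, cutoffs = 99)
  expect_equal(ct2$sensitivity, 0)
  expect_equal(ct2$specificity, 100)

  set.seed(55)
  ev3 <- data.frame(kind = "reported", peak_change = stats::runif(50, 0, 14))
  win3 <- data.frame(change = stats::runif(80, -2, 8))
  ct3 <- cutoff_performance(ev3, win3, cutoffs = c(4, 5, 6))
  expect_true(all(diff(ct3$sensitivity) <= 0))
  expect_true(all(diff(ct3$specificity) >= 0))
  expect_error(cutoff_performance(ev3[0, ], win3), "no reported events")
})

test_that("within-subject variability is SD and CV over stable days", {
  d <- make_diary(rep(8, 30))
  v <- within_subject_variability(d)
  expect_equal(v$sd, 0)
  expect_equal(v$cv_percent, 0)

  totals <- rep(c(8, 12), 15) # mean 10, sd just over 2
  d2 <- make_diary(totals)
  v2 <- within_subject_variability(d2)
  expect_equal(v2$cv_percent, 100 * stats::sd(totals) / 10)

  v3 <- within_subject_variability(make_diary(rep(7, 5)))
  expect_false(v3$computable)
})

test_that("variability estimates recover a planted 40% CV", {
  # flare budget uncapped so the full planted variance is realised
  cfg <- synth_config(n_patients = 6, followup_days = 194,
                      daily_cv_range = c(40, 40), flare_prob_cap = 0.3,
                      reported_rate_per_year = 0, unreported_rate_per_year = 0,
                      missing_day_prob = 0, seed = 88)
  sim <- generate_cohort(cfg)
  cvs <- vapply(sim$diaries, function(d)
    within_subject_variability(d)$cv_percent, numeric(1))
  expect_lt(mean(abs(cvs - 40)), 8)
})

test_that("paired t-test matches hand computation and is antisymmetric", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")], list(t = 0, p = 1))
  before <- c(10, 10, 10)
  after <- c(11, 12, 13)
  res <- paired_t(before, after)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  swapped <- paired_t(after, before)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # constant nonzero difference floors the p-value rather than reporting 0
  fl <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_true(fl$floored)
  expect_equal(fl$p, 1e-15)
})
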