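test_that("baseline is the median of the prior week, walking back when sparse", {
  d <- make_diary(c(7, 7, 7, 7, 7, 7, 7, 12, 12, 12))
  b <- estimate_baseline(d, as.Date("2015-01-08"))
  expect_equal(b$value, 7)
  expect_true(b$usable)

  d2 <- make_diary(c(5, 6, 7, 7, 8, 9, 20, 12))
  b2 <- estimate_baseline(d2, as.Date("2015-01-08"))
  expect_equal(b2$value, 7)

  # three missing days leave four observed: median of the observed values
  d3 <- make_diary(c(6, NA, 7, NA, 8, NA, 9, 12))
  b3 <- estimate_baseline(d3, as.Date("2015-01-08"))
  expect_equal(b3$value, 7.5)
  expect_true(b3$usable)

  # sparser than min_baseline_obs: the window walks back until satisfied
  d4 <- make_diary(c(6, 6, 6, 6, 5, NA, NA, NA, 7, NA, 12))
  b4 <- estimate_baseline(d4, as.Date("2015-01-11"))
  expect_true(b4$usable)
  expect_lt(b4$window_start, as.Date("2015-01-04"))

  expect_error(estimate_baseline(d, as.Date("2014-12-30")), "precedes")
})

test_that("a sustained 3-point rise for 2 days is an event; spikes and +2 are not", {
  base <- rep(7, 20)
  ev <- detect_unreported(make_diary(c(base, 10, 11, 7, rep(7, 10))))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$peak_change, 4)
  expect_equal(ev$onset_date, as.Date("2015-01-01") + 20)
  expect_equal(ev$duration_days, 2)

  # a single-day spike does not satisfy the 48-h requirement
  ev2 <- detect_unreported(make_diary(c(base, 15, 7, rep(7, 10))))
  expect_identical(nrow(ev2), 0L)

  # sustained +2 stays below the 3-point threshold
  ev3 <- detect_unreported(make_diary(c(base, rep(9, 10), rep(7, 5))))
  expect_identical(nrow(ev3), 0L)

  # a missing day breaks the qualifying run
  ev4 <- detect_unreported(make_diary(c(base, 10, NA, 11, 7, rep(7, 10))))
  expect_identical(nrow(ev4), 0L)
})

test_that("candidates within the refractory window merge into one event", {
  base <- rep(7, 14)
  totals <- c(base, 11, 11, 8, 8, 8, 11, 11, 7, rep(7, 6))
  ev <- detect_unreported(make_diary(totals))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$duration_days, 7) # onset day 15, back to baseline day 22
  expect_equal(ev$peak_change, 4)

  # beyond the refractory gap the episodes stay separate
  totals2 <- c(base, 11, 11, rep(7, 9), 11, 11, 7, rep(7, 8))
  ev2 <- detect_unreported(make_diary(totals2))
  expect_identical(nrow(ev2), 2L)
})

test_that("raising the threshold shrinks detections (episodes may split, never grow)", {
  # With rolling baselines and refractory merging, a stricter threshold can
  # split one long episode into fragments, so the raw event count is not
  # strictly monotone; what must hold is that nothing new appears: every
  # higher-threshold event overlaps a lower-threshold event window, and the
  # total number of event days never grows.
  set.seed(202)
  n_split <- 0L
  for (case in 1:200) {
    totals <- random_totals(sample(30:60, 1))
    d <- tryCatch(make_diary(totals), error = function(e) NULL)
    if (is.null(d)) next
    evs <- lapply(c(3, 4, 5), function(thr)
      detect_unreported(d, threshold = thr))
    for (k in 2:3) {
      lo <- evs[[k - 1]]
      hi <- evs[[k]]
      if (nrow(hi) > nrow(lo)) n_split <- n_split + 1L
      if (nrow(hi) == 0) next
      for (i in seq_len(nrow(hi))) {
        expect_true(nrow(lo) > 0 &&
                      any(hi$onset_date[i] <= lo$end_date &
                            hi$end_date[i] >= lo$onset_date))
      }
      days <- function(e) sum(as.numeric(e$end_date - e$onset_date) + 1)
      expect_lte(days(hi), days(lo))
    }
  }
  expect_lt(n_split, 10) # splitting is a rare, pathological outcome
})

test_that("diaries shorter than two weeks are refused", {
  expect_error(detect_unreported(make_diary(rep(7, 10))), "14 days")
})

test_that("reported events are characterised from the treatment day", {
  # baseline 7, rise 8,10,12,14 then 16 on the treatment day, slow fall
  # reaching 7 on post-treatment day 15
  fall <- c(15, 14, 13, 13, 12, 11, 11, 10, 9, 9, 8, 8, 8, 8, 7)
  totals <- c(rep(7, 14), 8, 10, 12, 14, 16, fall, rep(7, 5))
  d <- make_diary(totals, abx_days = 19)
  ev <- characterize_reported(d, as.Date("2015-01-01") + 18)
  expect_equal(ev$baseline, 7)
  expect_equal(ev$onset_time_days, 4)
  expect_equal(ev$pre_period_mean, mean(c(8, 10, 12, 14)))
  expect_equal(ev$peak_score, 16)
  expect_equal(ev$peak_change, 9)
  expect_equal(ev$duration_days, 15)
  expect_false(ev$truncated)
})

test_that("flat and non-recovering reported events degrade gracefully", {
  d <- make_diary(rep(7, 40), abx_days = 20)
  ev <- characterize_reported(d, as.Date("2015-01-01") + 19)
  expect_equal(ev$onset_time_days, 0)
  expect_equal(ev$peak_change, 0)
  expect_true(is.na(ev$pre_period_mean))

  d2 <- make_diary(c(rep(7, 14), rep(14, 60)), abx_days = 15)
  ev2 <- characterize_reported(d2, as.Date("2015-01-15"))
  expect_true(ev2$truncated)
  expect_equal(ev2$duration_days, 42)
})

test_that("worsened-domain count reflects which items rise for 48 hours", {
  base_items <- stats::setNames(c(1L, 1L, 1L, 1L, 1L, 0L), best_item_names())
  rows <- lapply(1:24, function(i) {
    it <- base_items
    if (i >= 15 && i <= 18) {
      it["cough"] <- 3L
      it["sputum_volume"] <- 3L
    }
    data.frame(patient_id = "W1", date = as.Date("2015-02-01") + i - 1,
               as.list(it), reported_flag = FALSE, antibiotic_start = FALSE,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  entries$total <- rowSums(entries[, best_item_names()])
  d <- patient_diary(entries)
  ev <- detect_unreported(d)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$n_worsened_domains, 2L)
  expect_false(ev$met_embarc)

  # all six items rising meets the consensus definition
  rows6 <- lapply(1:24, function(i) {
    it <- base_items
    if (i >= 15 && i <= 18) it[] <- c(3L, 3L, 3L, 3L, 3L, 2L)
    data.frame(patient_id = "W2", date = as.Date("2015-02-01") + i - 1,
               as.list(it), reported_flag = FALSE, antibiotic_start = FALSE,
               stringsAsFactors = FALSE)
  })
  entries6 <- do.call(rbind, rows6)
  entries6$total <- rowSums(entries6[, best_item_names()])
  d6 <- patient_diary(entries6)
  ev6 <- detect_unreported(d6)
  expect_identical(nrow(ev6), 1L)
  expect_identical(ev6$n_worsened_domains, 6L)
  expect_true(ev6$met_embarc)
})

test_that("stable-day mask censors events with the pre-onset buffer", {
  d <- make_diary(rep(7, 60))
  none <- stable_day_mask(d, NULL)
  expect_true(all(none$mask))

  ev <- data.frame(patient_id = "T01",
                   onset_date = as.Date("2015-01-01") + 29,
                   end_date = as.Date("2015-01-01") + 44)
  sm <- stable_day_mask(d, ev, pre_buffer = 7)
  dates <- d$entries$date
  unstable <- dates[!sm$mask]
  expect_equal(min(unstable), as.Date("2015-01-01") + 22) # day 23
  expect_equal(max(unstable), as.Date("2015-01-01") + 44) # day 45

  ev_all <- data.frame(patient_id = "T01",
                       onset_date = min(dates), end_date = max(dates))
  expect_identical(stable_day_mask(d, ev_all)$n_stable, 0L)
})

test_that("the scanner agrees with a brute-force enumeration of qualifying runs", {
  set.seed(404)
  n_cases <- 400
  for (case in seq_len(n_cases)) {
    n_days <- sample(20:60, 1)
    totals <- random_totals(n_days)
    d <- tryCatch(make_diary(totals), error = function(e) NULL)
    if (is.null(d)) next
    got <- detect_unreported(d)
    want <- oracle_unreported(totals)
    expect_identical(nrow(got), length(want))
    if (nrow(got) != length(want)) next
    start <- as.Date("2015-01-01")
    for (k in seq_along(want)) {
      expect_identical(as.integer(got$onset_date[k] - start) + 1L,
                       as.integer(want[[k]]$onset))
      expect_identical(as.integer(got$end_date[k] - start) + 1L,
                       as.integer(want[[k]]$end))
      expect_equal(got$baseline[k], want[[k]]$baseline)
      expect_equal(got$peak_score[k], want[[k]]$peak)
      expect_identical(got$truncated[k], want[[k]]$truncated)
    }
  }
})

test_that("noisy cohorts recover planted events without touching censor windows", {
  # n = 500 keeps the Monte Carlo error on the detection rate near 1%
  cfg <- synth_config(n_patients = 500, followup_days = 180, seed = 77)
  sim <- generate_cohort(cfg)
  events <- detect_events(sim$diaries)
  un <- events[events$kind == "unreported", ]
  re <- events[events$kind == "reported", ]
  tu <- sim$truth$events[sim$truth$events$kind == "unreported", ]
  hit <- vapply(seq_len(nrow(tu)), function(i) {
    p <- un[un$patient_id == tu$patient_id[i], , drop = FALSE]
    nrow(p) > 0 && any(p$onset_date <= tu$onset_date[i] + tu$duration_days[i] &
                         p$end_date >= tu$onset_date[i])
  }, logical(1))
  expect_gte(mean(hit[tu$peak_change >= 4]), 0.9)
  # detected unreported events never overlap reported censor windows
  for (i in seq_len(nrow(un))) {
    rr <- re[re$patient_id == un$patient_id[i], , drop = FALSE]
    if (!nrow(rr)) next
    overlap <- un$onset_date[i] <= rr$end_date & un$end_date[i] >= rr$onset_date
    expect_false(any(overlap))
  }
})
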