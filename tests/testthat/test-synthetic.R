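test_that("generation is deterministic for a given config and seed", {
  cfg <- synth_config(n_patients = 3, followup_days = 60, seed = 17)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (pid in names(a$diaries)) {
    expect_identical(a$diaries[[pid]]$entries, b$diaries[[pid]]$entries)
  }
  expect_identical(a$anchors, b$anchors)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("zero event rates and zero noise give a constant series at the rounded baseline", {
  cfg <- synth_config(n_patients = 2, followup_days = 30,
                      daily_cv_range = c(0, 0),
                      reported_rate_per_year = 0, unreported_rate_per_year = 0,
                      missing_day_prob = 0, seed = 5)
  sim <- generate_cohort(cfg)
  for (pid in names(sim$diaries)) {
    b <- sim$truth$patients$true_baseline[sim$truth$patients$patient_id == pid]
    tot <- sim$diaries[[pid]]$entries$total
    expect_true(all(tot == round(b)))
  }
})

test_that("every generated entry passes the instrument validator", {
  cfg <- synth_config(n_patients = 8, followup_days = 90, seed = 23)
  sim <- generate_cohort(cfg)
  for (d in sim$diaries) {
    e <- d$entries
    for (i in seq_len(nrow(e))) {
      v <- validate_entry(as.list(e[i, ]))
      expect_true(v$ok)
      expect_identical(v$entry$total, e$total[i])
    }
  }
})

test_that("noise-free planted events are recovered exactly by the detector", {
  cfg <- synth_config(n_patients = 12, followup_days = 160,
                      daily_cv_range = c(0, 0), missing_day_prob = 0,
                      reported_rate_per_year = 1.5,
                      unreported_rate_per_year = 2, seed = 31)
  sim <- generate_cohort(cfg)
  events <- detect_events(sim$diaries)
  truth <- sim$truth$events
  unrep_t <- truth[truth$kind == "unreported", ]
  unrep_d <- events[events$kind == "unreported", ]
  expect_identical(nrow(unrep_d), nrow(unrep_t))
  for (i in seq_len(nrow(unrep_t))) {
    hit <- unrep_d[unrep_d$patient_id == unrep_t$patient_id[i] &
                     unrep_d$onset_date == unrep_t$onset_date[i], ]
    expect_identical(nrow(hit), 1L) # exactly one event at the planted onset
    expect_identical(hit$duration_days, unrep_t$duration_days[i])
    # integer scoring moves the latent peak by strictly less than one point
    expect_lt(abs(hit$peak_change - unrep_t$peak_change[i]), 1)
  }
  rep_t <- truth[truth$kind == "reported", ]
  rep_d <- events[events$kind == "reported", ]
  expect_identical(nrow(rep_d), nrow(rep_t))
  for (i in seq_len(nrow(rep_t))) {
    hit <- rep_d[rep_d$patient_id == rep_t$patient_id[i] &
                   rep_d$treatment_start_date == rep_t$treatment_start_date[i], ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$onset_date, rep_t$onset_date[i])
    expect_identical(hit$onset_time_days, rep_t$report_lag_days[i])
    expect_identical(hit$duration_days, rep_t$duration_days[i])
    expect_lt(abs(hit$peak_change - rep_t$peak_change[i]), 1)
  }
})

test_that("planted unreported changes stay within the 3-8 point range", {
  cfg <- synth_config(n_patients = 40, followup_days = 180, seed = 41)
  sim <- generate_cohort(cfg)
  un <- sim$truth$events[sim$truth$events$kind == "unreported", ]
  expect_gt(nrow(un), 10)
  expect_true(all(un$peak_change >= 3 & un$peak_change <= 8))
})

test_that("per-patient baselines obey the law of large numbers", {
  cfg <- synth_config(n_patients = 1000, followup_days = 14,
                      reported_rate_per_year = 0, unreported_rate_per_year = 0,
                      seed = 53)
  sim <- generate_cohort(cfg)
  m <- mean(sim$truth$patients$true_baseline)
  se <- cfg$baseline_sd_between / sqrt(cfg$n_patients)
  expect_lt(abs(m - cfg$baseline_mean), 3 * se)
})

test_that("decompose_total_to_items respects caps, sums and smoothness", {
  zero <- decompose_total_to_items(0, stats::setNames(rep(0L, 6), best_item_names()))
  expect_true(all(zero == 0))
  top <- decompose_total_to_items(30, zero)
  expect_identical(sum(top), 26L)
  expect_identical(unname(top["sputum_colour"]), 5L)
  prev <- stats::setNames(c(1L, 2L, 2L, 2L, 1L, 1L), best_item_names())
  out <- decompose_total_to_items(9.4, prev, event_intensity = 2)
  expect_identical(sum(out), 9L)
  expect_true(all(abs(out - prev) <= 2))
  # systemic symptoms only appear with an active event (or a saturated total)
  calm <- decompose_total_to_items(12, prev, event_intensity = 0)
  expect_identical(unname(calm["cold_flu"]), 0L)
})

test_that("anchor copula: null correlations give near-zero sample correlation", {
  cfg <- synth_config(n_patients = 600, followup_days = 14,
                      reported_rate_per_year = 0, unreported_rate_per_year = 0,
                      anchor_correlations = c(cat = 0, sgrq_total = 0,
                                              sgrq_symptom = 0, lcq = 0,
                                              six_mwt_m = 0),
                      seed = 61)
  sim <- generate_cohort(cfg)
  b <- sim$truth$patients$true_baseline
  for (a in c("cat", "sgrq_total", "lcq", "six_mwt_m")) {
    expect_lt(abs(stats::cor(b, sim$anchors[[a]])), 0.1)
  }
})

test_that("invalid anchor correlation structure errors before sampling", {
  expect_error(synth_config(anchor_correlations = c(cat = 1.2, sgrq_total = 0.6,
                                                    sgrq_symptom = 0.5,
                                                    lcq = -0.5,
                                                    six_mwt_m = -0.4)),
               "within \\(-1, 1\\)")
})

test_that("too-short follow-up with planted events is refused", {
  expect_error(synth_config(followup_days = 21), "longer follow-up")
})

test_that("planted slope reconfiguration produces the requested regression slope", {
  cfg <- plant_anchor_slope(synth_config(seed = 71), "cat", 2)
  expect_equal(cfg$anchor_correlations[["cat"]] * cfg$baseline_sd_between /
                 cfg$anchor_sds[["cat"]], 2)
  expect_error(plant_anchor_slope(synth_config(), "lcq", 2), "sign")
})
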