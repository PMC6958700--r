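# Run code with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic BEST cohort generator
#'
#' Defaults are calibrated to the published cohort kinetics of the instrument:
#' between-patient baseline mean 7.1 (SD 2.2) points; reported (treated)
#' exacerbations with a several-day prodrome (report lag mean 4.8 d), change
#' from baseline 9.1 (SD 2.5, range 5-14), recovery to baseline 15.3 d
#' (SD 5.7, range 5-28) after treatment start; unreported exacerbations with
#' change 4.7 (SD 1.5, range 3-8) and duration 10 d (SD 3.8); and anchor
#' questionnaires correlated with the true baseline (CAT r = 0.61, SGRQ total
#' r = 0.61, SGRQ symptoms r = 0.52, LCQ r = -0.52, 6MWT r = -0.46).
#'
#' Event change/duration parameters are specified on the *measured* scale (the
#' scale on which a detector reports them); the generator plants latent
#' amplitudes shifted by `latent_shift_*` to compensate the small positive
#' measurement offset of threshold-based detection (see the methods vignette).
#'
#' Day-to-day variation has two parts: a persistent Gaussian component
#' (SD capped at `persistent_sd_cap` points) and transient single-day flares
#' (never on consecutive days) carrying the remaining variance implied by the
#' patient's coefficient of variation, drawn from a right-skewed Beta over
#' `daily_cv_range`. Single-day flares inflate the CV but do not satisfy the
#' 48-hour persistence rule.
#'
#' @param n_patients,followup_days Cohort size and diary length.
#' @param baseline_mean,baseline_sd_between,baseline_range Between-patient
#'   baseline distribution (points), truncated to `baseline_range`.
#' @param daily_cv_range Within-patient day-to-day CV range, percent.
#' @param cv_beta_shape Two Beta shape parameters mapping onto
#'   `daily_cv_range`; the default (1, 6.5) is right-skewed.
#' @param persistent_sd_cap Cap on the persistent noise SD, points.
#' @param flare_min,flare_mean_excess Flare magnitude is
#'   `flare_min + Exp(mean = flare_mean_excess)` points.
#' @param flare_prob_cap Cap on the daily flare probability.
#' @param flare_quiet_days Flares are suppressed during an event template and
#'   for this many days after it (symptoms during and right after an
#'   exacerbation are driven by the event, not by incidental flares).
#' @param reported_rate_per_year,unreported_rate_per_year Event frequencies.
#' @param reported_change_mean,reported_change_sd,reported_change_range
#'   Measured-scale peak change of reported events (points).
#' @param reported_duration_mean,reported_duration_sd,reported_duration_range
#'   Days from treatment start back to baseline.
#' @param report_lag_mean,report_lag_sd,report_lag_range Days of prodrome
#'   before antibiotics are commenced.
#' @param unreported_change_mean,unreported_change_sd,unreported_change_range
#'   Measured-scale peak change of unreported events (points).
#' @param unreported_duration_mean,unreported_duration_sd,unreported_duration_range
#'   Days from onset back to baseline.
#' @param latent_shift_reported,latent_shift_unreported Latent-scale offsets
#'   (points) subtracted from the change means before planting.
#' @param min_event_start_day Earliest allowed event onset (patients enter the
#'   study clinically stable).
#' @param event_gap_days Minimum clear days between planted event windows.
#' @param anchor_means,anchor_sds,anchor_correlations Named vectors over
#'   `cat`, `sgrq_total`, `sgrq_symptom`, `lcq`, `six_mwt_m`. LCQ and SGRQ
#'   symptom-domain moments are not published for this cohort; the defaults
#'   are documented assumptions.
#' @param missing_day_prob Independent probability a diary day is skipped.
#' @param seed Integer seed; per-patient streams are derived from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 21, followup_days = 180,
                         baseline_mean = 7.1, baseline_sd_between = 2.2,
                         baseline_range = c(2, 14),
                         daily_cv_range = c(16.1, 97.8),
                         cv_beta_shape = c(1, 6.5),
                         persistent_sd_cap = 0.8,
                         flare_min = 3, flare_mean_excess = 4,
                         flare_prob_cap = 0.045,
                         flare_quiet_days = 7,
                         reported_rate_per_year = 1.5,
                         unreported_rate_per_year = 1.2,
                         reported_change_mean = 9.1,
                         reported_change_sd = 2.5,
                         reported_change_range = c(5, 14),
                         reported_duration_mean = 15.3,
                         reported_duration_sd = 5.7,
                         reported_duration_range = c(5, 28),
                         report_lag_mean = 4.8, report_lag_sd = 3.5,
                         report_lag_range = c(1, 14),
                         unreported_change_mean = 4.7,
                         unreported_change_sd = 1.5,
                         unreported_change_range = c(3, 8),
                         unreported_duration_mean = 10,
                         unreported_duration_sd = 3.8,
                         unreported_duration_range = c(4, 21),
                         latent_shift_reported = -0.1,
                         latent_shift_unreported = -1.55,
                         min_event_start_day = 15,
                         event_gap_days = 3,
                         anchor_means = c(cat = 19.1, sgrq_total = 41.5,
                                          sgrq_symptom = 55, lcq = 14,
                                          six_mwt_m = 439),
                         anchor_sds = c(cat = 6.1, sgrq_total = 17,
                                        sgrq_symptom = 18, lcq = 3,
                                        six_mwt_m = 104),
                         anchor_correlations = c(cat = 0.61,
                                                 sgrq_total = 0.61,
                                                 sgrq_symptom = 0.52,
                                                 lcq = -0.52,
                                                 six_mwt_m = -0.46),
                         missing_day_prob = 0.03, seed = 42) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(
    cfg$n_patients >= 1, cfg$followup_days >= 14,
    cfg$baseline_sd_between >= 0, cfg$reported_change_sd >= 0,
    cfg$unreported_change_sd >= 0, cfg$reported_duration_sd >= 0,
    cfg$unreported_duration_sd >= 0, cfg$report_lag_sd >= 0,
    cfg$reported_rate_per_year >= 0, cfg$unreported_rate_per_year >= 0,
    cfg$missing_day_prob >= 0, cfg$missing_day_prob < 1,
    length(cfg$daily_cv_range) == 2, diff(cfg$daily_cv_range) >= 0,
    all(cfg$anchor_sds >= 0)
  )
  nm <- c("cat", "sgrq_total", "sgrq_symptom", "lcq", "six_mwt_m")
  stopifnot(all(nm %in% names(cfg$anchor_means)),
            all(nm %in% names(cfg$anchor_sds)),
            all(nm %in% names(cfg$anchor_correlations)))
  rho <- cfg$anchor_correlations[nm]
  if (any(abs(rho) >= 1)) {
    stop("anchor correlations must lie strictly within (-1, 1)", call. = FALSE)
  }
  # implied correlation matrix of (baseline, anchors) under the one-factor
  # copula; checked for positive semi-definiteness before any sampling
  full <- rbind(c(1, rho), cbind(rho, outer(rho, rho)))
  diag(full) <- 1
  if (min(eigen(full, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("implied anchor correlation structure is not positive semi-definite",
         call. = FALSE)
  }
  if (cfg$followup_days < 28 &&
      (cfg$reported_rate_per_year > 0 || cfg$unreported_rate_per_year > 0)) {
    stop("follow-up shorter than 28 days cannot accommodate planted events; use a longer follow-up",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Reconfigure the anchor generator to a planted regression slope
#'
#' The expected slope of BEST-on-anchor regression under the generator is
#' `rho * baseline_sd_between / anchor_sd`. This helper keeps the configured
#' correlation and rescales the anchor SD so the planted slope equals
#' `slope` (signs must agree with the configured correlation).
#'
#' @param config A [synth_config()].
#' @param anchor One of `cat`, `sgrq_total`, `sgrq_symptom`, `lcq`,
#'   `six_mwt_m`.
#' @param slope Target regression slope of baseline BEST on the anchor.
#' @return The modified config.
#' @export
plant_anchor_slope <- function(config, anchor = "cat", slope) {
  stopifnot(inherits(config, "synth_config"),
            anchor %in% names(config$anchor_correlations), slope != 0)
  rho <- config$anchor_correlations[[anchor]]
  if (sign(slope) != sign(rho)) {
    stop("slope sign must match the configured correlation sign",
         call. = FALSE)
  }
  config$anchor_sds[[anchor]] <- abs(rho) * config$baseline_sd_between /
    abs(slope)
  validate_synth_config(config)
  config
}

rnorm_trunc <- function(n, mean, sd, range) {
  # rejection sampling; falls back to clipping if the window is tiny
  out <- numeric(n)
  need <- seq_len(n)
  for (tries in 1:50) {
    if (!length(need)) break
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= range[1] & draw <= range[2]
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  if (length(need)) out[need] <- pmin(pmax(stats::rnorm(length(need), mean, sd),
                                           range[1]), range[2])
  out
}

# Template offsets for one event, as a list(start_rel, offsets) where
# start_rel is the offset of the first template day relative to the onset day
# (onset = first day meeting the +3/48h rule in the absence of noise).
event_template <- function(kind, change, duration, lag = NULL) {
  floor_tail <- 1.8 # keeps rounded totals above baseline until the final day
  if (kind == "unreported") {
    # days: onset-2, onset-1 (sub-threshold ramp), onset (1-day peak at
    # `change`), then a decay from just below the peak reaching 0 at
    # onset+duration; the second day stays at or above the rule threshold so
    # a noise-free event always satisfies the 48-h requirement
    ramp <- c(0.8, 2.0)
    shoulder <- max(change - 0.4, 3)
    post <- pmax(shoulder * (1 - (seq_len(duration) - 1) / (duration - 1)),
                 floor_tail)
    post[length(post)] <- 0 # day onset + duration: back to baseline
    offs <- c(ramp, change, post)
    list(start_rel = -2L, offsets = offs, peak_rel = 0L)
  } else {
    rise <- pmax(change * seq_len(lag + 1) / (lag + 1), floor_tail * 2 / 3)
    decay <- pmax(change * (1 - seq_len(duration) / duration), floor_tail)
    decay[length(decay)] <- 0 # day treatment + duration
    offs <- c(rise, decay)
    # days: onset .. treatment (rise), treatment+1 .. treatment+duration
    list(start_rel = 0L, offsets = offs, peak_rel = lag)
  }
}

sample_events <- function(cfg) {
  n_rep <- stats::rpois(1, cfg$reported_rate_per_year * cfg$followup_days / 365)
  n_unrep <- stats::rpois(1, cfg$unreported_rate_per_year * cfg$followup_days / 365)
  evs <- list()
  add <- function(kind) {
    if (kind == "reported") {
      change <- rnorm_trunc(1, cfg$reported_change_mean + cfg$latent_shift_reported,
                            cfg$reported_change_sd, cfg$reported_change_range)
      duration <- round(rnorm_trunc(1, cfg$reported_duration_mean,
                                    cfg$reported_duration_sd,
                                    cfg$reported_duration_range))
      lag <- round(rnorm_trunc(1, cfg$report_lag_mean, cfg$report_lag_sd,
                               cfg$report_lag_range))
      list(kind = kind, change = change, duration = duration, lag = lag)
    } else {
      change <- rnorm_trunc(1, cfg$unreported_change_mean + cfg$latent_shift_unreported,
                            cfg$unreported_change_sd, cfg$unreported_change_range)
      duration <- round(rnorm_trunc(1, cfg$unreported_duration_mean,
                                    cfg$unreported_duration_sd,
                                    cfg$unreported_duration_range))
      list(kind = kind, change = change, duration = duration, lag = NA)
    }
  }
  for (k in seq_len(n_rep)) evs[[length(evs) + 1]] <- add("reported")
  for (k in seq_len(n_unrep)) evs[[length(evs) + 1]] <- add("unreported")
  if (!length(evs)) return(list(events = list(), dropped = 0L))

  # place events with disjoint occupied windows (template + baseline week +
  # a clear gap); unplaceable events are dropped (thinning under refractory)
  placed <- list()
  occupied <- rep(FALSE, cfg$followup_days)
  dropped <- 0L
  for (ev in evs[sample.int(length(evs))]) {
    span_pre <- 9L # baseline week + sub-threshold ramp
    span_post <- if (ev$kind == "reported") ev$lag + ev$duration else ev$duration
    lo <- max(cfg$min_event_start_day, span_pre + 1)
    hi <- cfg$followup_days - span_post - 1
    done <- FALSE
    if (hi >= lo) {
      for (try in 1:100) {
        onset <- sample(lo:hi, 1)
        win <- max(1, onset - span_pre - cfg$event_gap_days):
          min(cfg$followup_days, onset + span_post + cfg$event_gap_days)
        if (!any(occupied[win])) {
          occupied[win] <- TRUE
          ev$onset <- onset
          placed[[length(placed) + 1]] <- ev
          done <- TRUE
          break
        }
      }
    }
    if (!done) dropped <- dropped + 1L
  }
  list(events = placed, dropped = dropped)
}

#' Generate one synthetic patient
#'
#' Builds the latent daily total (baseline + noise + event-template offsets),
#' decomposes it into six valid integer item scores, drops missing days, and
#' returns the diary together with the ground truth used to generate it.
#'
#' @param config A [synth_config()].
#' @param patient_seed Integer seed for this patient's stream.
#' @param patient_id Identifier (default "P001").
#' @return list with `diary` ([patient_diary()]), `truth` (list: `patient`
#'   one-row data.frame; `events` data.frame of planted events) and `anchors`
#'   (one-row data.frame).
#' @export
generate_patient <- function(config, patient_seed, patient_id = "P001") {
  cfg <- config
  with_local_seed(patient_seed, {
    nd <- cfg$followup_days
    z_b <- stats::rnorm(1)
    b <- min(max(cfg$baseline_mean + cfg$baseline_sd_between * z_b,
                 cfg$baseline_range[1]), cfg$baseline_range[2])
    cv <- cfg$daily_cv_range[1] + diff(cfg$daily_cv_range) *
      stats::rbeta(1, cfg$cv_beta_shape[1], cfg$cv_beta_shape[2])
    target_sd <- cv * b / 100
    s0 <- min(target_sd, cfg$persistent_sd_cap)
    flare_ex2 <- cfg$flare_mean_excess^2 # Var of the Exp excess
    flare_m2 <- flare_ex2 + (cfg$flare_min + cfg$flare_mean_excess)^2
    q_flare <- min(max(target_sd^2 - s0^2, 0) / flare_m2, cfg$flare_prob_cap)

    placement <- sample_events(cfg)
    offsets <- rep(0, nd)
    truth_rows <- list()
    start_date <- as.Date("2014-03-01")
    for (ev in placement$events) {
      tpl <- event_template(ev$kind, ev$change, ev$duration, ev$lag)
      days <- ev$onset + tpl$start_rel + seq_along(tpl$offsets) - 1L
      keep <- days >= 1 & days <= nd
      offsets[days[keep]] <- offsets[days[keep]] + tpl$offsets[keep]
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        patient_id = patient_id, kind = ev$kind,
        onset_date = start_date + ev$onset - 1,
        treatment_start_date = if (ev$kind == "reported")
          start_date + ev$onset + ev$lag - 1 else as.Date(NA),
        peak_change = ev$change, duration_days = ev$duration,
        report_lag_days = if (ev$kind == "reported") ev$lag else NA_real_,
        stringsAsFactors = FALSE
      )
    }

    eps <- stats::rnorm(nd, 0, s0)
    flare <- rep(0, nd)
    # quiet window: event-template days plus a recovery margin after them
    quiet <- offsets > 0
    if (any(quiet) && cfg$flare_quiet_days > 0) {
      idx <- which(quiet)
      for (k in seq_len(cfg$flare_quiet_days)) {
        quiet[pmin(idx + k, nd)] <- TRUE
      }
    }
    p_f <- min(q_flare / max(1 - q_flare, 1e-9), 0.45)
    prev_flare <- FALSE
    for (d in seq_len(nd)) {
      if (!quiet[d] && !prev_flare && stats::runif(1) < p_f) {
        flare[d] <- cfg$flare_min + stats::rexp(1, 1 / cfg$flare_mean_excess)
        prev_flare <- TRUE
      } else {
        prev_flare <- FALSE
      }
    }

    latent <- b + offsets + eps + flare
    totals <- pmin(pmax(round(latent), 0), 26L)

    items <- matrix(0L, nrow = nd, ncol = 6,
                    dimnames = list(NULL, best_item_names()))
    prev <- starting_items(totals[1])
    for (d in seq_len(nd)) {
      prev <- decompose_total_to_items(totals[d], prev,
                                       event_intensity = offsets[d])
      items[d, ] <- prev
    }

    abx_day <- rep(FALSE, nd)
    for (tr in truth_rows) {
      if (tr$kind == "reported") {
        di <- as.integer(tr$treatment_start_date - start_date) + 1L
        if (di >= 1 && di <= nd) abx_day[di] <- TRUE
      }
    }
    observed <- stats::runif(nd) >= cfg$missing_day_prob
    observed[abx_day] <- TRUE # the patient contacted the team that day
    observed[1] <- TRUE

    entries <- data.frame(
      patient_id = patient_id,
      date = start_date + seq_len(nd) - 1,
      items, check.names = FALSE,
      reported_flag = abx_day, antibiotic_start = abx_day,
      stringsAsFactors = FALSE
    )
    entries$total <- as.integer(totals)
    entries <- entries[observed, , drop = FALSE]
    diary <- patient_diary(entries)

    eta <- stats::rnorm(5)
    nm <- c("cat", "sgrq_total", "sgrq_symptom", "lcq", "six_mwt_m")
    rho <- cfg$anchor_correlations[nm]
    av <- cfg$anchor_means[nm] + cfg$anchor_sds[nm] *
      (rho * z_b + sqrt(1 - rho^2) * eta)
    av["cat"] <- min(max(av["cat"], 0), 40)
    av["sgrq_total"] <- min(max(av["sgrq_total"], 0), 100)
    av["sgrq_symptom"] <- min(max(av["sgrq_symptom"], 0), 100)
    av["lcq"] <- min(max(av["lcq"], 3), 21)
    av["six_mwt_m"] <- max(av["six_mwt_m"], 0)
    anchors <- data.frame(patient_id = patient_id, visit = "baseline",
                          sgrq_total = round(av[["sgrq_total"]], 1),
                          sgrq_symptom = round(av[["sgrq_symptom"]], 1),
                          cat = round(av[["cat"]], 1),
                          lcq = round(av[["lcq"]], 1),
                          six_mwt_m = round(av[["six_mwt_m"]], 1),
                          stringsAsFactors = FALSE)

    truth_events <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(patient_id = character(0), kind = character(0),
                 onset_date = as.Date(character(0)),
                 treatment_start_date = as.Date(character(0)),
                 peak_change = numeric(0), duration_days = numeric(0),
                 report_lag_days = numeric(0), stringsAsFactors = FALSE)
    truth_patient <- data.frame(
      patient_id = patient_id, true_baseline = b, true_cv_percent = cv,
      persistent_sd = s0, flare_prob = p_f,
      n_events_dropped = placement$dropped, stringsAsFactors = FALSE
    )
    list(diary = diary,
         truth = list(patient = truth_patient, events = truth_events),
         anchors = anchors)
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` independent patients from per-patient seeds derived
#' deterministically from `config$seed`; patients are therefore reproducible
#' and order-independent.
#'
#' @param config A [synth_config()].
#' @return list with `diaries` ([diary_set()]), `truth` (list: `patients`
#'   data.frame, `events` data.frame), `anchors` (data.frame, one baseline
#'   visit per patient).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  pseeds <- with_local_seed(config$seed,
                            sample.int(2147483646L, config$n_patients))
  ids <- sprintf("P%04d", seq_len(config$n_patients))
  out <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    out[[i]] <- generate_patient(config, pseeds[i], ids[i])
  }
  list(
    diaries = diary_set(lapply(out, `[[`, "diary")),
    truth = list(
      patients = do.call(rbind, lapply(out, function(x) x$truth$patient)),
      events = do.call(rbind, lapply(out, function(x) x$truth$events))
    ),
    anchors = do.call(rbind, lapply(out, `[[`, "anchors"))
  )
}

starting_items <- function(total) {
  # neutral allocation of a starting total across the five non-systemic items
  caps <- c(4L, 4L, 4L, 5L, 4L)
  alloc <- c(0L, 0L, 0L, 0L, 0L)
  left <- min(total, sum(caps))
  while (left > 0) {
    for (k in order(alloc / (caps + 0.01))) {
      if (left > 0 && alloc[k] < caps[k]) {
        alloc[k] <- alloc[k] + 1L
        left <- left - 1L
      }
    }
  }
  stats::setNames(c(alloc, 0L), best_item_names())
}

#' Decompose a latent daily total into the six item scores
#'
#' Allocates `round(clamp(latent_total, 0, 26))` across the six items so that
#' every item stays within its defined levels, the realised sum equals the
#' clamped total, and each item moves by at most 2 points from the previous
#' day whenever that is feasible. The cold/flu item (systemic symptoms) is 0
#' outside exacerbations; during an event it rises with the event intensity
#' (1 from 2 points of offset, 2 from 5, 5 from 8), and it also absorbs totals
#' that exceed the 21 points available from the other five items.
#'
#' @param latent_total Real-valued latent total.
#' @param previous_items Named integer vector (six items) from the previous
#'   day, or the output of a neutral starting allocation.
#' @param event_intensity Current event-template offset (0 = no event).
#' @return Named integer vector over [best_item_names()] summing to the
#'   clamped total.
#' @export
decompose_total_to_items <- function(latent_total, previous_items,
                                     event_intensity = 0) {
  total <- as.integer(min(max(round(latent_total), 0), 26))
  nm5 <- c("breathlessness", "fatigue", "sputum_volume", "sputum_colour",
           "cough")
  caps <- c(4L, 4L, 4L, 5L, 4L)
  prev5 <- pmin(pmax(as.integer(previous_items[nm5]), 0L), caps)

  desired_cf <- if (event_intensity >= 8) 5L else if (event_intensity >= 5) 2L
    else if (event_intensity >= 2) 1L else 0L
  feas <- c(0L, 1L, 2L, 5L)
  feas <- feas[feas <= total & (total - feas) <= 21L]
  cf <- if (desired_cf %in% feas) desired_cf else
    feas[which.min(abs(feas - desired_cf))]

  target <- total - cf
  alloc <- prev5
  delta <- target - sum(alloc)
  step <- function(alloc, dir, respect_smooth) {
    chg <- alloc - prev5
    if (dir > 0) {
      ok <- alloc < caps & (!respect_smooth | chg < 2L)
      # fill proportionally lowest first for a plausible profile
      cand <- which(ok)
      if (!length(cand)) return(NA_integer_)
      cand[order(alloc[cand] / (caps[cand] + 0.01))][1]
    } else {
      ok <- alloc > 0L & (!respect_smooth | chg > -2L)
      cand <- which(ok)
      if (!length(cand)) return(NA_integer_)
      cand[order(-alloc[cand] / (caps[cand] + 0.01))][1]
    }
  }
  while (delta != 0L) {
    dir <- as.integer(sign(delta))
    k <- step(alloc, dir, TRUE)
    if (is.na(k)) k <- step(alloc, dir, FALSE)
    if (is.na(k)) break # target infeasible for the 5-item space (cannot occur)
    alloc[k] <- alloc[k] + dir
    delta <- delta - dir
  }
  stats::setNames(c(alloc, cf), best_item_names())
}
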