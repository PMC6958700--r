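# Calendar-grid helper: one row per calendar day between first and last entry.
diary_grid <- function(diary) {
  e <- diary$entries
  dates <- seq(min(e$date), max(e$date), by = "day")
  idx <- match(e$date, dates)
  total <- rep(NA_real_, length(dates))
  total[idx] <- e$total
  abx <- rep(FALSE, length(dates))
  abx[idx] <- e$antibiotic_start
  list(dates = dates, total = total, observed = !is.na(total), abx = abx)
}

#' Estimate a patient's symptom baseline
#'
#' The baseline is the median daily BEST total over the 7 calendar days
#' immediately preceding `reference_day` (for an event, the week before its
#' onset; for study entry, the first diary week). If fewer than
#' `min_baseline_obs` non-excluded entries fall in that window the window is
#' walked back one day at a time, up to `max_lookback` days before
#' `reference_day`; if still unsatisfied the estimate is flagged unusable.
#'
#' @param diary A [patient_diary()].
#' @param reference_day Date; the day the baseline refers to (window ends the
#'   day before). Must not precede the diary start.
#' @param exclusion_mask Optional Date vector of days to exclude (e.g. days
#'   inside exacerbation windows).
#' @param min_baseline_obs Minimum observed days required (default 4).
#' @param max_lookback Furthest the window start may reach back (default 21).
#' @return An object of class `baseline_estimate`: list with `reference_day`,
#'   `window_start`, `window_end`, `n_observed`, `value` (median, may be a
#'   half-integer) and `usable`.
#' @export
estimate_baseline <- function(diary, reference_day, exclusion_mask = NULL,
                              min_baseline_obs = 4, max_lookback = 21) {
  reference_day <- as.Date(reference_day)
  e <- diary$entries
  if (reference_day < min(e$date)) {
    stop("reference_day precedes the diary start", call. = FALSE)
  }
  ok <- if (is.null(exclusion_mask)) rep(TRUE, nrow(e)) else
    !(e$date %in% as.Date(exclusion_mask))
  best <- NULL
  for (shift in 0:(max_lookback - 7)) {
    w_end <- reference_day - 1 - shift
    w_start <- reference_day - 7 - shift
    inw <- ok & e$date >= w_start & e$date <= w_end
    n <- sum(inw)
    cand <- list(reference_day = reference_day, window_start = w_start,
                 window_end = w_end, n_observed = n,
                 value = if (n > 0) stats::median(e$total[inw]) else NA_real_,
                 usable = n >= min_baseline_obs)
    if (is.null(best)) best <- cand
    if (cand$usable) { best <- cand; break }
  }
  structure(best, class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("baseline %.1f at %s (window %s..%s, %d obs%s)\n", x$value,
              x$reference_day, x$window_start, x$window_end, x$n_observed,
              if (x$usable) "" else ", UNUSABLE"))
  invisible(x)
}

empty_events <- function() {
  data.frame(patient_id = character(0), kind = character(0),
             onset_date = as.Date(character(0)),
             treatment_start_date = as.Date(character(0)),
             end_date = as.Date(character(0)),
             baseline = numeric(0), peak_score = numeric(0),
             peak_change = numeric(0), pre_period_mean = numeric(0),
             onset_time_days = numeric(0), duration_days = numeric(0),
             n_worsened_domains = integer(0), met_embarc = logical(0),
             truncated = logical(0),
             baseline_window_start = as.Date(character(0)),
             baseline_window_end = as.Date(character(0)),
             baseline_usable = logical(0),
             stringsAsFactors = FALSE)
}

#' Characterise a reported (treated) exacerbation
#'
#' Given the day antibiotics were commenced, reconstructs the event from the
#' diary: the baseline is the median score in the week before onset; the onset
#' is the earliest day within `lookback` days of treatment whose run of
#' totals above baseline persists to the treatment day; the event ends on the
#' first post-treatment day the total returns to (at or below) baseline.
#' Duration is counted from treatment start, matching how recovery time is
#' reported clinically. Baseline and onset are mutually dependent, so they are
#' iterated to a fixed point (flat pre-treatment series degenerate to onset =
#' treatment day and are flagged atypical via `onset_time_days = 0`).
#'
#' @param diary A [patient_diary()].
#' @param treatment_start_day Date with `antibiotic_start` flagged.
#' @param lookback Maximum days before treatment the onset may reach
#'   (default 14).
#' @param max_duration_days Cap on post-treatment recovery search (default 42);
#'   events not back to baseline by then are truncated at the cap.
#' @param min_baseline_obs Passed to [estimate_baseline()].
#' @return One-row data.frame of event fields (see [detect_events()]).
#' @export
characterize_reported <- function(diary, treatment_start_day, lookback = 14,
                                  max_duration_days = 42,
                                  min_baseline_obs = 4) {
  g <- diary_grid(diary)
  tday <- as.Date(treatment_start_day)
  ti <- match(tday, g$dates)
  if (is.na(ti)) stop("treatment_start_day not within the diary", call. = FALSE)
  lb_start <- max(1, ti - lookback)
  if (!any(g$observed[lb_start:ti])) {
    stop("no observed entries in the onset lookback window", call. = FALSE)
  }

  onset_i <- ti
  base <- NULL
  for (iter in 1:6) {
    base <- estimate_baseline(diary, g$dates[onset_i],
                              min_baseline_obs = min_baseline_obs)
    # earliest day in the lookback window starting a run that stays above
    # baseline through treatment start (missing days do not break the run;
    # the event is anchored by the report, not by the rule)
    new_onset <- ti
    i <- ti - 1
    while (i >= lb_start) {
      if (g$observed[i]) {
        if (g$total[i] > base$value) new_onset <- i else break
      }
      i <- i - 1
    }
    if (new_onset == onset_i) break
    onset_i <- new_onset
  }

  # recovery: first post-treatment day at or below baseline
  end_i <- NA_integer_
  truncated <- FALSE
  cap_i <- min(length(g$dates), ti + max_duration_days)
  if (ti < cap_i) {
    for (i in (ti + 1):cap_i) {
      if (g$observed[i] && g$total[i] <= base$value) { end_i <- i; break }
    }
  }
  if (is.na(end_i)) {
    end_i <- cap_i
    truncated <- TRUE
  }

  ev_days <- onset_i:end_i
  obs_ev <- ev_days[g$observed[ev_days]]
  peak <- max(g$total[obs_ev])
  pre_days <- if (onset_i < ti) onset_i:(ti - 1) else integer(0)
  pre_obs <- pre_days[g$observed[pre_days]]
  pre_mean <- if (length(pre_obs)) mean(g$total[pre_obs]) else NA_real_

  ev <- data.frame(
    patient_id = diary$patient_id, kind = "reported",
    onset_date = g$dates[onset_i], treatment_start_date = tday,
    end_date = g$dates[end_i],
    baseline = base$value, peak_score = peak,
    peak_change = peak - base$value, pre_period_mean = pre_mean,
    onset_time_days = as.numeric(ti - onset_i),
    duration_days = as.numeric(end_i - ti),
    n_worsened_domains = NA_integer_, met_embarc = NA,
    truncated = truncated,
    baseline_window_start = base$window_start,
    baseline_window_end = base$window_end,
    baseline_usable = base$usable,
    stringsAsFactors = FALSE
  )
  wd <- count_worsened_domains(diary, ev)
  ev$n_worsened_domains <- wd$n_worsened
  ev$met_embarc <- wd$met_embarc
  ev
}

#' Detect unreported exacerbations
#'
#' Scans the diary, outside the censor windows of already-characterised
#' reported events, for sustained symptom rises: a candidate is a maximal run
#' of at least `min_days` consecutive *observed* calendar days whose totals
#' are at least `threshold` points above the rolling baseline (median of the
#' week before the run starts). A missing day breaks a run — the 48-hour
#' requirement is operationalised conservatively on daily data. Candidates
#' separated by fewer than `refractory_days` merge into one event (a relapse
#' within a week is the same episode). The event ends on the first day the
#' total returns to (at or below) baseline; events still elevated at the diary
#' end are truncated there. Unreported durations are counted from onset.
#'
#' @param diary A [patient_diary()] spanning at least 14 days.
#' @param reported_events data.frame of reported events (their
#'   `onset_date..end_date` windows are censored), or NULL.
#' @param threshold Minimum rise above baseline in points (default 3).
#' @param min_days Minimum consecutive qualifying days (default 2).
#' @param refractory_days Merge window between candidates (default 7).
#' @param censor_post_days Days censored after each reported event's end
#'   (default 7): the week after a treated exacerbation is recovery, not a
#'   new event.
#' @param min_baseline_obs Passed to [estimate_baseline()].
#' @return data.frame of events (possibly empty), one row per detected event.
#' @export
detect_unreported <- function(diary, reported_events = NULL, threshold = 3,
                              min_days = 2, refractory_days = 7,
                              censor_post_days = 7, min_baseline_obs = 4) {
  g <- diary_grid(diary)
  n <- length(g$dates)
  if (n < 14) {
    stop("diary spans fewer than 14 days; cannot establish a baseline plus a qualifying run",
         call. = FALSE)
  }
  censored <- rep(FALSE, n)
  censor_dates <- as.Date(character(0))
  if (!is.null(reported_events) && nrow(reported_events)) {
    for (k in seq_len(nrow(reported_events))) {
      win <- seq(reported_events$onset_date[k],
                 reported_events$end_date[k] + censor_post_days, by = "day")
      censored[g$dates %in% win] <- TRUE
      censor_dates <- c(censor_dates, win)
    }
  }
  avail <- g$observed & !censored

  # maximal qualifying run of consecutive available calendar days >= base + thr
  run_from <- function(i, base_value) {
    if (!avail[i] || g$total[i] < base_value + threshold) return(0L)
    len <- 0L
    while (i + len <= n && avail[i + len] &&
           g$total[i + len] >= base_value + threshold) {
      len <- len + 1L
    }
    len
  }

  events <- list()
  consumed_dates <- as.Date(character(0))
  i <- 1L
  while (i <= n) {
    if (!avail[i]) { i <- i + 1L; next }
    base <- estimate_baseline(diary, g$dates[i],
                              exclusion_mask = c(censor_dates, consumed_dates),
                              min_baseline_obs = min_baseline_obs)
    if (!base$usable) { i <- i + 1L; next }
    len <- run_from(i, base$value)
    if (len < min_days) { i <- i + 1L; next }

    onset_i <- i
    last_q <- i + len - 1L
    # merge later candidates (w.r.t. the same baseline) within the refractory gap
    j <- last_q + 1L
    while (j <= n && (j - last_q - 1L) < refractory_days) {
      lj <- run_from(j, base$value)
      if (lj >= min_days) {
        last_q <- j + lj - 1L
        j <- last_q + 1L
      } else {
        j <- j + 1L
      }
    }
    # event end: first day back at or below baseline after the last qualifying
    # day; stop at a censor boundary or the diary end (truncated)
    end_i <- NA_integer_
    truncated <- FALSE
    j <- last_q + 1L
    while (j <= n && !censored[j]) {
      if (g$observed[j] && g$total[j] <= base$value) { end_i <- j; break }
      j <- j + 1L
    }
    if (is.na(end_i)) {
      end_i <- max(onset_i, j - 1L)
      truncated <- TRUE
    }

    ev_days <- onset_i:end_i
    obs_ev <- ev_days[avail[ev_days]]
    peak <- max(g$total[obs_ev])
    ev <- data.frame(
      patient_id = diary$patient_id, kind = "unreported",
      onset_date = g$dates[onset_i], treatment_start_date = as.Date(NA),
      end_date = g$dates[end_i],
      baseline = base$value, peak_score = peak,
      peak_change = peak - base$value, pre_period_mean = NA_real_,
      onset_time_days = NA_real_,
      duration_days = as.numeric(end_i - onset_i),
      n_worsened_domains = NA_integer_, met_embarc = NA,
      truncated = truncated,
      baseline_window_start = base$window_start,
      baseline_window_end = base$window_end,
      baseline_usable = base$usable,
      stringsAsFactors = FALSE
    )
    wd <- count_worsened_domains(diary, ev)
    ev$n_worsened_domains <- wd$n_worsened
    ev$met_embarc <- wd$met_embarc
    events[[length(events) + 1]] <- ev
    consumed_dates <- c(consumed_dates, g$dates[ev_days])
    i <- end_i + 1L
  }
  if (length(events)) do.call(rbind, events) else empty_events()
}

#' Count worsened symptom domains within an event
#'
#' For each of the six items, the item's median over the event's baseline
#' window defines the patient's usual level; the domain counts as worsened
#' when the item exceeds that median on at least 2 consecutive observed days
#' inside the event window. An event meets the consensus (EMBARC/BRR-style)
#' symptom criterion when at least 3 domains worsen.
#'
#' @param diary A [patient_diary()].
#' @param event One-row event data.frame with `onset_date`, `end_date`,
#'   `baseline_window_start`, `baseline_window_end`, `baseline_usable`.
#' @return list with `n_worsened` (0-6, NA if baseline unusable) and
#'   `met_embarc` (logical, NA if undetermined).
#' @export
count_worsened_domains <- function(diary, event) {
  if (!isTRUE(event$baseline_usable)) {
    return(list(n_worsened = NA_integer_, met_embarc = NA))
  }
  e <- diary$entries
  basew <- e$date >= event$baseline_window_start &
    e$date <= event$baseline_window_end
  inev <- e$date >= event$onset_date & e$date <= event$end_date
  if (!any(basew) || !any(inev)) {
    return(list(n_worsened = NA_integer_, met_embarc = NA))
  }
  n_worse <- 0L
  for (nm in best_item_names()) {
    med <- stats::median(e[[nm]][basew])
    up_dates <- e$date[inev][e[[nm]][inev] > med]
    # two consecutive calendar days above the baseline median
    if (length(up_dates) >= 2 && any(diff(sort(up_dates)) == 1)) {
      n_worse <- n_worse + 1L
    }
  }
  list(n_worsened = n_worse, met_embarc = n_worse >= 3L)
}

#' Mark stable (non-exacerbation) diary days
#'
#' A day is stable unless it falls within `pre_buffer` days before the onset,
#' or `post_buffer` days after the end, of any exacerbation event. Variability
#' statistics (within-subject SD, CV) are computed over stable days only.
#'
#' @param diary A [patient_diary()].
#' @param events data.frame of events for this patient (may be empty).
#' @param pre_buffer Days censored before each onset (default 7).
#' @param post_buffer Days censored after each end (default 0).
#' @return list with `mask` (logical over `diary$entries` rows), `n_stable`,
#'   `n_total`.
#' @export
stable_day_mask <- function(diary, events, pre_buffer = 7, post_buffer = 0) {
  e <- diary$entries
  mask <- rep(TRUE, nrow(e))
  if (!is.null(events) && nrow(events)) {
    ev <- events[events$patient_id == diary$patient_id, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      lo <- ev$onset_date[k] - pre_buffer
      hi <- ev$end_date[k] + post_buffer
      mask[e$date >= lo & e$date <= hi] <- FALSE
    }
  }
  list(mask = mask, n_stable = sum(mask), n_total = length(mask))
}

#' Characterise all events of a diary set
#'
#' Runs the full per-patient detection sequence: every `antibiotic_start` day
#' becomes a reported event via [characterize_reported()], then
#' [detect_unreported()] scans the remaining days. Patients whose diaries are
#' too short for detection contribute reported events only.
#'
#' @param diaries A [diary_set()].
#' @param threshold,min_days,refractory_days,censor_post_days Passed to
#'   [detect_unreported()].
#' @param lookback,max_duration_days Passed to [characterize_reported()].
#' @param min_baseline_obs Passed to [estimate_baseline()].
#' @return data.frame of all events across patients.
#' @export
detect_events <- function(diaries, threshold = 3, min_days = 2,
                          refractory_days = 7, censor_post_days = 7,
                          lookback = 14, max_duration_days = 42,
                          min_baseline_obs = 4) {
  out <- lapply(diaries, function(d) {
    abx_days <- d$entries$date[d$entries$antibiotic_start]
    rep_ev <- if (length(abx_days)) {
      do.call(rbind, lapply(abx_days, function(td) {
        characterize_reported(d, td, lookback = lookback,
                              max_duration_days = max_duration_days,
                              min_baseline_obs = min_baseline_obs)
      }))
    } else {
      empty_events()
    }
    unrep <- tryCatch(
      detect_unreported(d, rep_ev, threshold = threshold,
                        min_days = min_days,
                        refractory_days = refractory_days,
                        censor_post_days = censor_post_days,
                        min_baseline_obs = min_baseline_obs),
      error = function(e) empty_events()
    )
    rbind(rep_ev, unrep)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write events to CSV in the standard column layout
#' @param events data.frame from [detect_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("patient_id", "kind", "onset_date", "treatment_start_date",
            "end_date", "baseline", "peak_score", "peak_change",
            "pre_period_mean", "onset_time_days", "duration_days",
            "n_worsened_domains", "met_embarc", "truncated")
  df <- events[, cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
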