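# Build a patient diary from a vector of daily totals. Totals are decomposed
# into valid item scores; NA totals become missing days. abx_days are 1-based
# day offsets flagged as reported + antibiotic start.
make_diary <- function(totals, patient_id = "T01",
                       start = as.Date("2015-01-01"), abx_days = integer(0)) {
  n <- length(totals)
  items <- matrix(0L, nrow = n, ncol = 6,
                  dimnames = list(NULL, best_item_names()))
  prev <- stats::setNames(rep(0L, 6), best_item_names())
  for (d in seq_len(n)) {
    if (is.na(totals[d])) next
    prev <- decompose_total_to_items(totals[d], prev, event_intensity = 0)
    items[d, ] <- prev
  }
  keep <- !is.na(totals)
  entries <- data.frame(
    patient_id = patient_id, date = start + seq_len(n) - 1,
    items, check.names = FALSE,
    reported_flag = seq_len(n) %in% abx_days,
    antibiotic_start = seq_len(n) %in% abx_days,
    stringsAsFactors = FALSE
  )
  entries$total <- as.integer(round(pmin(pmax(totals, 0), 26)))
  entries <- entries[keep, , drop = FALSE]
  patient_diary(entries)
}

valid_record <- function(...) {
  rec <- list(patient_id = "P1", date = "2015-01-01", breathlessness = 1,
              fatigue = 1, sputum_volume = 1, sputum_colour = 1, cough = 1,
              cold_flu = 0, reported_flag = 0, antibiotic_start = 0)
  utils::modifyList(rec, list(...))
}

# Independent brute-force reference for the unreported-event rule, working on
# integer day indices (1..n). totals[i] is NA on missing days. Returns a list
# of events with onset/end/peak/baseline in day indices. Deliberately naive:
# enumerates every (start, length) run instead of scanning.
oracle_unreported <- function(totals, censored = rep(FALSE, length(totals)),
                              threshold = 3, min_days = 2, refractory = 7,
                              min_obs = 4, max_lookback = 21) {
  n <- length(totals)
  observed <- !is.na(totals)
  avail <- observed & !censored

  baseline_at <- function(day, excluded) {
    for (s in 0:(max_lookback - 7)) {
      win <- (day - 7 - s):(day - 1 - s)
      win <- win[win >= 1]
      win <- win[observed[win] & !(win %in% excluded)]
      if (length(win) >= min_obs) return(stats::median(totals[win]))
    }
    NULL
  }

  # every maximal run of >= min_days consecutive available days at or above
  # base + threshold, where base is taken at the run's first day
  events <- list()
  consumed <- integer(0)
  day <- 1
  while (day <= n) {
    if (!avail[day]) { day <- day + 1; next }
    base <- baseline_at(day, c(which(censored), consumed))
    if (is.null(base)) { day <- day + 1; next }
    qual <- function(i) i <= n && avail[i] && totals[i] >= base + threshold
    if (!qual(day) || !all(vapply(day:(day + min_days - 1), qual, TRUE))) {
      day <- day + 1; next
    }
    # maximal first run
    run_end <- day
    while (qual(run_end + 1)) run_end <- run_end + 1
    # absorb later runs separated by < refractory days
    repeat {
      nxt <- NULL
      for (s in (run_end + 1):min(n, run_end + refractory)) {
        if (s > n) break
        if (qual(s) && all(vapply(s:(s + min_days - 1), qual, TRUE)) &&
            (s - run_end - 1) < refractory) { nxt <- s; break }
      }
      if (is.null(nxt)) break
      run_end <- nxt
      while (qual(run_end + 1)) run_end <- run_end + 1
    }
    # end: first day back at or below base, stopping at censor/diary end
    end <- NA
    j <- run_end + 1
    while (j <= n && !censored[j]) {
      if (observed[j] && totals[j] <= base) { end <- j; break }
      j <- j + 1
    }
    truncated <- is.na(end)
    if (truncated) end <- max(day, j - 1)
    ev_days <- (day:end)[avail[day:end]]
    events[[length(events) + 1]] <- list(
      onset = day, end = end, baseline = base,
      peak = max(totals[ev_days]), truncated = truncated
    )
    consumed <- c(consumed, day:end)
    day <- end + 1
  }
  events
}

# random diary corpus case for the oracle-equivalence property
random_totals <- function(n_days, rng) {
  base <- sample(4:10, 1)
  x <- pmin(pmax(round(base + stats::rnorm(n_days, 0, sample(c(0.5, 1, 2, 3), 1))), 0), 26)
  # occasional sustained bumps so events actually occur
  n_bumps <- stats::rpois(1, 1.2)
  for (b in seq_len(n_bumps)) {
    s <- sample(seq_len(max(n_days - 4, 1)), 1)
    len <- sample(1:8, 1)
    amp <- sample(2:7, 1)
    idx <- s:min(n_days, s + len - 1)
    x[idx] <- pmin(x[idx] + amp, 26)
  }
  x[stats::runif(n_days) < 0.05] <- NA
  # keep the diary span equal to the day grid so index arithmetic lines up
  x[1] <- base
  if (is.na(x[n_days])) x[n_days] <- base
  x
}
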