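#' Convergent-validity linear fit
#'
#' Ordinary least squares of the diary score on an anchor measure with the
#' Pearson correlation and its two-sided p-value (t distribution with n - 2
#' degrees of freedom). Incomplete pairs are dropped pairwise.
#'
#' @param x Anchor values.
#' @param y Baseline BEST values.
#' @param anchor_name Label carried into the result.
#' @return list of class `correlation_result`: `anchor_name`, `n`, `slope`,
#'   `intercept`, `r`, `p`, `defined` (FALSE when either variable has zero
#'   variance, in which case no fit is returned).
#' @export
linear_fit <- function(x, y, anchor_name = "anchor") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(anchor_name = anchor_name, n = n, slope = NA_real_,
                          intercept = NA_real_, r = NA_real_, p = NA_real_,
                          defined = FALSE), class = "correlation_result"))
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(anchor_name = anchor_name, n = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("%s: correlation undefined (zero variance, n=%d)\n",
                x$anchor_name, x$n))
  } else {
    cat(sprintf("%s: n=%d slope=%.3f intercept=%.2f r=%.3f p=%.3g\n",
                x$anchor_name, x$n, x$slope, x$intercept, x$r, x$p))
  }
  invisible(x)
}

#' Anchor-based MCID
#'
#' Converts an established anchor's MCID onto the BEST scale through the
#' regression of BEST on the anchor: `|slope| * anchor_mcid_points`. The
#' anchor is eligible only when |r| > 0.3.
#'
#' @param fit A `correlation_result` from [linear_fit()] (BEST on anchor).
#' @param anchor_mcid_points The anchor's established MCID (e.g. SGRQ 4,
#'   CAT 2, LCQ 1.3).
#' @return list of class `mcid_estimate`: `method` ("anchor"), `anchor_name`,
#'   `value` (points on the BEST scale).
#' @export
anchor_mcid <- function(fit, anchor_mcid_points) {
  stopifnot(inherits(fit, "correlation_result"), anchor_mcid_points > 0)
  if (!isTRUE(fit$defined) || is.na(fit$r) || abs(fit$r) <= 0.3) {
    stop(sprintf("anchor %s ineligible: |r| <= 0.3", fit$anchor_name),
         call. = FALSE)
  }
  structure(list(method = "anchor", anchor_name = fit$anchor_name,
                 value = abs(fit$slope) * anchor_mcid_points),
            class = "mcid_estimate")
}

#' Distribution-based (half-SD) MCID
#'
#' Half the sample standard deviation (n - 1 denominator) of the
#' per-participant scores.
#'
#' @param scores Numeric vector, one value per participant.
#' @return list of class `mcid_estimate` with method `half_sd`.
#' @export
half_sd_mcid <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2) stop("need at least 2 scores", call. = FALSE)
  structure(list(method = "half_sd", anchor_name = NA_character_,
                 value = stats::sd(scores) / 2), class = "mcid_estimate")
}

#' Exacerbation-onset MCID
#'
#' A reported exacerbation is by definition a clinically meaningful symptom
#' change, so the mean rise of the pre-exacerbation period over baseline
#' (`pre_period_mean - baseline`) across reported events is a third MCID
#' estimate.
#'
#' @param events data.frame of events; only reported events with usable
#'   baseline and a non-missing pre-period mean contribute.
#' @return list of class `mcid_estimate` with method `exacerbation_onset` and
#'   `n_events`; errors when no usable event exists.
#' @export
exacerbation_onset_mcid <- function(events) {
  ev <- events[events$kind == "reported" & events$baseline_usable &
                 is.finite(events$pre_period_mean), , drop = FALSE]
  if (!nrow(ev)) stop("no reported events with a usable pre-period",
                      call. = FALSE)
  structure(list(method = "exacerbation_onset", anchor_name = NA_character_,
                 value = mean(ev$pre_period_mean - ev$baseline),
                 n_events = nrow(ev)), class = "mcid_estimate")
}

#' @export
print.mcid_estimate <- function(x, ...) {
  lbl <- if (x$method == "anchor") sprintf("anchor (%s)", x$anchor_name)
    else x$method
  cat(sprintf("MCID [%s]: %.2f points\n", lbl, x$value))
  invisible(x)
}

#' Score stable diary windows for cutoff analysis
#'
#' Cuts the stable (non-exacerbation) part of each diary into non-overlapping
#' 14-day windows and scores each window by the maximum total over its second
#' week minus the median of its leading week — the same change construction a
#' detector applies to an event, evaluated where no event occurred.
#'
#' @param diaries A [diary_set()].
#' @param events data.frame of events (used to censor exacerbation periods).
#' @param window_days Window length (default 14; first 7 days form the
#'   reference week).
#' @param min_obs Minimum observed days per window (default 10).
#' @param pre_buffer Passed to [stable_day_mask()].
#' @return data.frame with `patient_id`, `window_start`, `change`.
#' @export
stable_change_windows <- function(diaries, events, window_days = 14,
                                  min_obs = 10, pre_buffer = 7) {
  out <- list()
  for (d in diaries) {
    sm <- stable_day_mask(d, events, pre_buffer = pre_buffer)
    e <- d$entries[sm$mask, , drop = FALSE]
    if (!nrow(e)) next
    # consecutive-calendar stable segments, tiled into windows
    seg_id <- cumsum(c(1, as.integer(diff(e$date) > 1)))
    for (seg in split(e, seg_id)) {
      first <- min(seg$date)
      last <- max(seg$date)
      ws <- first
      while (as.numeric(last - ws) + 1 >= window_days) {
        we <- ws + window_days - 1
        inw <- seg[seg$date >= ws & seg$date <= we, , drop = FALSE]
        lead <- inw[inw$date < ws + 7, , drop = FALSE]
        rest <- inw[inw$date >= ws + 7, , drop = FALSE]
        if (nrow(inw) >= min_obs && nrow(lead) >= 4 && nrow(rest) >= 2) {
          out[[length(out) + 1]] <- data.frame(
            patient_id = d$patient_id, window_start = ws,
            change = max(rest$total) - stats::median(lead$total),
            stringsAsFactors = FALSE
          )
        }
        ws <- we + 1
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(0),
               window_start = as.Date(character(0)), change = numeric(0),
               stringsAsFactors = FALSE)
}

#' Sensitivity/specificity of change-score cutoffs
#'
#' For each cutoff c: sensitivity = percentage of treated (reported) events
#' whose peak change reaches at least c; specificity = percentage of stable
#' windows whose change stays below c. Episodes are the unit of analysis.
#'
#' @param events data.frame of reported events with `peak_change`.
#' @param stable_windows data.frame from [stable_change_windows()].
#' @param cutoffs Numeric vector of cutoffs (default 4, 5, 6).
#' @return data.frame with `cutoff`, `sensitivity`, `specificity` (percent),
#'   `n_events`, `n_stable`.
#' @export
cutoff_performance <- function(events, stable_windows, cutoffs = c(4, 5, 6)) {
  ev <- events[events$kind == "reported", , drop = FALSE]
  if (!nrow(ev)) stop("no reported events", call. = FALSE)
  if (!nrow(stable_windows)) stop("no stable windows", call. = FALSE)
  data.frame(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(cc)
      100 * mean(ev$peak_change >= cc), numeric(1)),
    specificity = vapply(cutoffs, function(cc)
      100 * mean(stable_windows$change < cc), numeric(1)),
    n_events = nrow(ev), n_stable = nrow(stable_windows)
  )
}

#' Within-subject variability over stable days
#'
#' Sample SD and coefficient of variation (percent) of the daily totals over
#' stable days.
#'
#' @param diary A [patient_diary()].
#' @param stable_mask Logical over `diary$entries` rows (from
#'   [stable_day_mask()]); NULL means all days.
#' @param min_stable_days Minimum stable days required (default 8).
#' @return list with `sd`, `cv_percent`, `n_days`, `computable` (FALSE with a
#'   `reason` when there are too few stable days or a zero mean).
#' @export
within_subject_variability <- function(diary, stable_mask = NULL,
                                       min_stable_days = 8) {
  totals <- diary$entries$total
  if (!is.null(stable_mask)) totals <- totals[stable_mask]
  n <- length(totals)
  if (n < min_stable_days) {
    return(list(sd = NA_real_, cv_percent = NA_real_, n_days = n,
                computable = FALSE, reason = "insufficient stable days"))
  }
  s <- stats::sd(totals)
  m <- mean(totals)
  if (m == 0) {
    return(list(sd = s, cv_percent = NA_real_, n_days = n,
                computable = FALSE, reason = "zero mean"))
  }
  list(sd = s, cv_percent = 100 * s / m, n_days = n, computable = TRUE,
       reason = NULL)
}

#' Paired t-test between two timepoints
#'
#' Thin wrapper over the standard paired Student t-test, with a floor on the
#' reported p-value when the differences are constant and nonzero.
#'
#' @param before,after Equal-length paired numeric vectors.
#' @return list with `t`, `p`, `n`, `mean_diff`, `floored` (TRUE when p is
#'   reported at the machine floor).
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- after - before
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, n = length(d), mean_diff = 0,
                  floored = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 1e-15, n = length(d),
                mean_diff = mean(d), floored = TRUE))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  p <- max(tt$p.value, 1e-15)
  list(t = unname(tt$statistic), p = p, n = length(d), mean_diff = mean(d),
       floored = tt$p.value < 1e-15)
}
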