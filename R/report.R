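#' Per-patient baseline BEST estimates for a diary set
#'
#' The study-entry baseline of each patient: the median total over the first
#' diary week ([estimate_baseline()] referenced at day 8). Patients whose
#' diaries are too short get NA.
#'
#' @param diaries A [diary_set()].
#' @return data.frame with `patient_id`, `baseline`, `usable`.
#' @export
cohort_baselines <- function(diaries) {
  rows <- lapply(diaries, function(d) {
    ref <- min(d$entries$date) + 7
    b <- tryCatch(estimate_baseline(d, ref), error = function(e) NULL)
    data.frame(patient_id = d$patient_id,
               baseline = if (is.null(b)) NA_real_ else b$value,
               usable = if (is.null(b)) FALSE else b$usable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

anchor_mcid_points <- function() {
  c(sgrq_total = 4, cat = 2, lcq = 1.3)
}

#' Assemble the full validity report
#'
#' Computes every validation statistic of the instrument on a cohort:
#' convergent-validity regressions of baseline BEST on each anchor, the three
#' MCID estimates (half-SD of per-patient baselines by default, anchor
#' conversions for anchors with |r| > 0.3, exacerbation-onset change), the
#' change-cutoff sensitivity/specificity table, within-subject variability
#' over stable days, and the reported-vs-unreported event summary. Sections
#' that cannot be computed are marked with a reason rather than dropped.
#'
#' @param diaries A [diary_set()].
#' @param anchors Anchor data.frame (baseline visit rows are used).
#' @param events data.frame from [detect_events()].
#' @param cutoffs Change cutoffs to tabulate (default 4, 5, 6).
#' @param half_sd_source "baseline" (default: per-patient baseline scores) or
#'   "all_days" (every diary day of every patient).
#' @return list of class `validity_report`.
#' @export
validity_report <- function(diaries, anchors, events, cutoffs = c(4, 5, 6),
                            half_sd_source = c("baseline", "all_days")) {
  half_sd_source <- match.arg(half_sd_source)
  base_df <- cohort_baselines(diaries)
  anchors_b <- anchors[anchors$visit == "baseline", , drop = FALSE]
  m <- merge(base_df, anchors_b, by = "patient_id")

  anchor_cols <- c("cat", "sgrq_total", "sgrq_symptom", "lcq", "six_mwt_m")
  correlations <- lapply(anchor_cols, function(a) {
    tryCatch(linear_fit(m[[a]], m$baseline, anchor_name = a),
             error = function(e) list(anchor_name = a, error = conditionMessage(e)))
  })
  names(correlations) <- anchor_cols

  mcids <- list()
  hs_scores <- if (half_sd_source == "baseline") base_df$baseline else
    unlist(lapply(diaries, function(d) d$entries$total))
  mcids$half_sd <- tryCatch(half_sd_mcid(hs_scores),
                            error = function(e) list(method = "half_sd",
                                                     error = conditionMessage(e)))
  for (a in names(anchor_mcid_points())) {
    fit <- correlations[[a]]
    mcids[[paste0("anchor_", a)]] <- tryCatch(
      anchor_mcid(fit, anchor_mcid_points()[[a]]),
      error = function(e) list(method = "anchor", anchor_name = a,
                               error = conditionMessage(e)))
  }
  mcids$exacerbation_onset <- tryCatch(
    exacerbation_onset_mcid(events),
    error = function(e) list(method = "exacerbation_onset",
                             error = conditionMessage(e)))

  windows <- stable_change_windows(diaries, events)
  cutoff_table <- tryCatch(cutoff_performance(events, windows, cutoffs),
                           error = function(e) list(error = conditionMessage(e)))

  variability <- do.call(rbind, lapply(diaries, function(d) {
    sm <- stable_day_mask(d, events)
    v <- within_subject_variability(d, sm$mask)
    data.frame(patient_id = d$patient_id, sd = v$sd,
               cv_percent = v$cv_percent, n_stable_days = v$n_days,
               computable = v$computable, stringsAsFactors = FALSE)
  }))
  rownames(variability) <- NULL
  cv_ok <- variability$cv_percent[variability$computable &
                                    is.finite(variability$cv_percent)]
  variability_range <- if (length(cv_ok)) range(cv_ok) else c(NA_real_, NA_real_)

  summarise_kind <- function(k) {
    ev <- events[events$kind == k, , drop = FALSE]
    if (!nrow(ev)) return(list(n = 0L))
    list(n = nrow(ev),
         change_mean = mean(ev$peak_change), change_sd = stats::sd(ev$peak_change),
         peak_mean = mean(ev$peak_score), peak_sd = stats::sd(ev$peak_score),
         duration_mean = mean(ev$duration_days),
         duration_sd = stats::sd(ev$duration_days),
         onset_time_mean = if (k == "reported")
           mean(ev$onset_time_days, na.rm = TRUE) else NA_real_,
         onset_time_sd = if (k == "reported")
           stats::sd(ev$onset_time_days, na.rm = TRUE) else NA_real_,
         n_met_embarc = sum(ev$met_embarc, na.rm = TRUE))
  }

  structure(list(
    n_patients = length(diaries),
    baselines = base_df,
    baseline_mean = mean(base_df$baseline, na.rm = TRUE),
    baseline_sd = stats::sd(base_df$baseline, na.rm = TRUE),
    correlations = correlations,
    mcids = mcids,
    cutoff_table = cutoff_table,
    variability = variability,
    variability_cv_range = variability_range,
    event_summary = list(reported = summarise_kind("reported"),
                         unreported = summarise_kind("unreported")),
    half_sd_source = half_sd_source
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("Validity report: %d patients, baseline BEST %.1f (SD %.1f)\n",
              x$n_patients, x$baseline_mean, x$baseline_sd))
  for (cr in x$correlations) {
    if (!is.null(cr$error)) {
      cat(sprintf("  %s: not computable (%s)\n", cr$anchor_name, cr$error))
    } else if (cr$defined) {
      cat(sprintf("  r(BEST, %s) = %.2f (p = %.3g, n = %d)\n",
                  cr$anchor_name, cr$r, cr$p, cr$n))
    }
  }
  for (mc in x$mcids) {
    if (!is.null(mc$error)) {
      cat(sprintf("  MCID [%s]: not computable (%s)\n", mc$method, mc$error))
    } else {
      lbl <- if (mc$method == "anchor") sprintf("anchor %s", mc$anchor_name)
        else mc$method
      cat(sprintf("  MCID [%s] = %.2f points\n", lbl, mc$value))
    }
  }
  es <- x$event_summary
  cat(sprintf("  events: %d reported, %d unreported\n",
              es$reported$n, es$unreported$n))
  invisible(x)
}

report_to_list <- function(report) {
  # plain-list view for JSON serialisation
  strip <- function(x) {
    if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
    if (is.data.frame(x)) {
      x[] <- lapply(x, strip)
      return(x)
    }
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(report)
}

#' Write a validity report as JSON
#' @param report A [validity_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a human-readable validity report (markdown)
#' @param report A [validity_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_md <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# BEST diary validity report")
  w("")
  w("Patients: %d; baseline BEST %.2f (SD %.2f).", report$n_patients,
    report$baseline_mean, report$baseline_sd)
  w("")
  w("## Convergent validity (baseline BEST vs anchors)")
  w("")
  w("| anchor | n | slope | r | p |")
  w("|---|---|---|---|---|")
  for (cr in report$correlations) {
    if (!is.null(cr$error) || !isTRUE(cr$defined)) {
      w("| %s | - | - | - | not computable |", cr$anchor_name)
    } else {
      w("| %s | %d | %.3f | %.2f | %.3g |", cr$anchor_name, cr$n, cr$slope,
        cr$r, cr$p)
    }
  }
  w("")
  w("## MCID estimates (points on the BEST scale)")
  w("")
  for (mc in report$mcids) {
    lbl <- if (identical(mc$method, "anchor"))
      sprintf("anchor (%s)", mc$anchor_name) else mc$method
    if (!is.null(mc$error)) {
      w("- %s: not computable (%s)", lbl, mc$error)
    } else {
      w("- %s: %.2f", lbl, mc$value)
    }
  }
  w("")
  w("## Change-cutoff performance")
  w("")
  ct <- report$cutoff_table
  if (!is.null(ct$error)) {
    w("Not computable: %s", ct$error)
  } else {
    w("| cutoff | sensitivity %% | specificity %% | events | stable windows |")
    w("|---|---|---|---|---|")
    for (i in seq_len(nrow(ct))) {
      w("| %g | %.0f | %.0f | %d | %d |", ct$cutoff[i], ct$sensitivity[i],
        ct$specificity[i], ct$n_events[i], ct$n_stable[i])
    }
  }
  w("")
  w("## Reported vs unreported exacerbations")
  w("")
  es <- report$event_summary
  fmt <- function(s, f) if (s$n > 0) sprintf("%.1f (SD %.1f)", s[[f]],
                                             s[[sub("_mean", "_sd", f)]])
    else "-"
  w("| quantity | reported | unreported |")
  w("|---|---|---|")
  w("| n | %d | %d |", es$reported$n, es$unreported$n)
  w("| onset time (days) | %s | not applicable |",
    if (es$reported$n) sprintf("%.1f (SD %.1f)", es$reported$onset_time_mean,
                               es$reported$onset_time_sd) else "-")
  w("| change from baseline | %s | %s |", fmt(es$reported, "change_mean"),
    fmt(es$unreported, "change_mean"))
  w("| peak score | %s | %s |", fmt(es$reported, "peak_mean"),
    fmt(es$unreported, "peak_mean"))
  w("| duration (days) | %s | %s |", fmt(es$reported, "duration_mean"),
    fmt(es$unreported, "duration_mean"))
  w("")
  w("## Symptom variability (stable days)")
  w("")
  if (all(is.finite(report$variability_cv_range))) {
    w("Within-subject CV ranged %.1f%% to %.1f%% across patients.",
      report$variability_cv_range[1], report$variability_cv_range[2])
  } else {
    w("Within-subject CV not computable.")
  }
  invisible(path)
}

#' Run the full pipeline: simulate (or load), detect, validate, report
#'
#' Executes the stages in order and writes every artifact into `out_dir`:
#' `diary.csv`, `anchors.csv`, `truth_events.csv` and `config_used.yaml` when
#' simulating, then `events.csv`, `report.json` and `report.md`. Identical
#' config and seed produce byte-identical outputs.
#'
#' @param config A [synth_config()] (used when simulating).
#' @param out_dir Output directory (created if needed).
#' @param diary_csv,anchor_csv Optional paths to existing inputs; when given,
#'   simulation is skipped.
#' @param threshold,min_days Detection rule parameters.
#' @param cutoffs Cutoffs for the sensitivity/specificity table.
#' @return Invisibly, a list with `diaries`, `anchors`, `events`, `report`,
#'   `truth` (NULL when inputs were loaded) and `files`.
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         diary_csv = NULL, anchor_csv = NULL,
                         threshold = 3, min_days = 2, cutoffs = c(4, 5, 6)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(diary_csv)) {
    sim <- generate_cohort(config)
    diaries <- sim$diaries
    anchors <- sim$anchors
    truth <- sim$truth
    write_diary_csv(diaries, file.path(out_dir, "diary.csv"))
    write_anchor_csv(anchors, file.path(out_dir, "anchors.csv"))
    utils::write.csv(truth$events[, c("patient_id", "kind", "onset_date",
                                      "treatment_start_date", "peak_change",
                                      "duration_days")],
                     file.path(out_dir, "truth_events.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    cfg_plain <- unclass(config)
    cfg_plain <- lapply(cfg_plain, function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
    yaml::write_yaml(cfg_plain, file.path(out_dir, "config_used.yaml"))
  } else {
    diaries <- read_diary_csv(diary_csv)
    if (length(diaries) == 0) {
      stop(sprintf("%s contains no diary entries", diary_csv), call. = FALSE)
    }
    anchors <- if (!is.null(anchor_csv)) read_anchor_csv(anchor_csv) else NULL
  }

  events <- detect_events(diaries, threshold = threshold, min_days = min_days)
  write_events_csv(events, file.path(out_dir, "events.csv"))

  report <- NULL
  if (!is.null(anchors)) {
    report <- validity_report(diaries, anchors, events, cutoffs = cutoffs)
    write_report_json(report, file.path(out_dir, "report.json"))
    write_report_md(report, file.path(out_dir, "report.md"))
  }
  message(sprintf("pipeline: %d patients, %d reported / %d unreported events",
                  length(diaries), sum(events$kind == "reported"),
                  sum(events$kind == "unreported")))
  invisible(list(diaries = diaries, anchors = anchors, events = events,
                 report = report, truth = truth,
                 files = list.files(out_dir, full.names = TRUE)))
}
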