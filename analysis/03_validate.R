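#!/usr/bin/env Rscript
# Stage 3 — validity statistics and report.
#
# Computes the instrument-validation statistics on the simulated cohort:
# convergent validity of the baseline score against the anchor questionnaires,
# the three MCID estimates, the 4/5/6-point change-cutoff table, and
# within-subject variability. Writes results/report.json and results/report.md.

library(bestdiary)

diaries <- read_diary_csv("results/cohort/diary.csv")
anchors <- read_anchor_csv("results/cohort/anchors.csv")
events_csv <- utils::read.csv("results/events.csv", stringsAsFactors = FALSE)
# re-detect in memory: events.csv is the exchange format, but the report also
# needs the baseline windows, which detect_events carries internally
events <- detect_events(diaries)
stopifnot(nrow(events) == nrow(events_csv))

report <- validity_report(diaries, anchors, events, cutoffs = c(4, 5, 6))
write_report_json(report, "results/report.json")
write_report_md(report, "results/report.md")

print(report)
ct <- report$cutoff_table
if (is.data.frame(ct)) {
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("cutoff %g points: sensitivity %.0f%%, specificity %.0f%%\n",
                ct$cutoff[i], ct$sensitivity[i], ct$specificity[i]))
  }
}
if (all(is.finite(report$variability_cv_range))) {
  cat(sprintf("within-subject CV range: %.1f%% to %.1f%%\n",
              report$variability_cv_range[1], report$variability_cv_range[2]))
}
cat("report written to results/report.json and results/report.md\n")
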