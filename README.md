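# bestdiary

Scoring, exacerbation detection and validation analysis for the BEST daily
symptom diary in bronchiectasis.

Bronchiectasis exacerbations drive lung-function decline, hospitalisation and
mortality, yet many go unreported and untreated, and clinical trials
routinely under-capture them. The BEST diary (Bronchiectasis Exacerbation and
Symptom Tool) addresses this with six daily self-rated items —
breathlessness, fatigue, sputum volume, sputum colour, cough and cold/flu
symptoms — summing to a 0–26 daily score. This package implements the
instrument and the full analysis pipeline a validation study of such an
instrument needs:

* **Scoring and I/O** — item definitions, per-entry validation (including
  the undefined cold/flu levels 3–4), sputum-volume mapping from millilitres
  to the household-equivalent categories, and CSV readers/writers for diary,
  anchor-questionnaire and event tables.
* **Exacerbation detection** — rolling baselines (median of the prior week,
  `estimate_baseline()`); characterisation of reported, treated events from
  the antibiotic-start day (`characterize_reported()`); and rule-based
  detection of *unreported* events: a rise of ≥ 3 points above baseline
  sustained ≥ 2 consecutive observed days with no treatment
  (`detect_unreported()`), with worsened-domain counting against the 3-of-6
  consensus symptom criterion.
* **Validation statistics** — convergent validity (OLS of baseline score on
  SGRQ, CAT, LCQ, 6-minute-walk anchors), the minimal clinically important
  difference by three methods (half-SD, anchor regression
  `MCID_BEST = |slope| × MCID_anchor`, and mean pre-exacerbation rise),
  change-cutoff sensitivity/specificity, and within-subject variability.
* **A calibrated synthetic cohort generator** — daily series with planted
  reported/unreported events, correlated anchors drawn from a Gaussian
  copula, and full ground truth, so every statistic above is testable as a
  parameter-recovery experiment. See the methods vignette
  (`vignettes/best-diary-methods.Rmd`) for the model and its assumptions.

## Worked example

The `analysis/` directory holds the three-stage workflow: simulate a
study-sized cohort, detect events, compute the validity report.

```sh
Rscript analysis/01_simulate.R   # 21 patients, 180 days -> results/cohort/
Rscript analysis/02_detect.R    # -> results/events.csv
Rscript analysis/03_validate.R  # -> results/report.json, results/report.md
```

Stage 2 prints, for the default seed:

```
reported exacerbations: n = 18
  change from baseline 9.2 (SD 2.6), peak 17.1 (SD 3.1)
  duration 14.9 days (SD 7.8)
  onset 5.3 days before treatment (SD 1.8)
  17 of 18 met the 3-of-6 worsened-domain criterion
unreported exacerbations: n = 9
  change from baseline 5.8 (SD 1.6), peak 14.0 (SD 2.1)
  duration 8.8 days (SD 1.8)
```

Treated events peak ~9 points above baseline and take about two weeks after
treatment to settle; events the patients did not report are roughly half as
tall and shorter — the pattern the diary is designed to expose. Stage 3 then
prints the convergent-validity correlations (on this simulated 21-patient
cohort, r ≈ 0.73 with CAT, 0.75 with SGRQ, −0.60 with LCQ, −0.46 with the
6-minute walk), the three MCID estimates and the 4/5/6-point cutoff table.

The same machinery is available programmatically:

```r
library(bestdiary)
cfg <- synth_config(n_patients = 21, followup_days = 180, seed = 2014)
sim <- generate_cohort(cfg)
events <- detect_events(sim$diaries)
report <- validity_report(sim$diaries, sim$anchors, events)
print(report)
```

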