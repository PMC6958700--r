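---
title: "Scoring, exacerbation detection and validation of a daily bronchiectasis symptom diary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, exacerbation detection and validation of a daily bronchiectasis symptom diary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bestdiary)
```

## The instrument

The BEST diary (Bronchiectasis Exacerbation and Symptom Tool) asks a patient
to rate six symptom domains once a day: breathlessness (an MRC-style 0–4
grading), fatigue (0–4), sputum volume (0–4, anchored to household volume
equivalents — a teaspoon is 5 ml, a tablespoon 15 ml, an egg-cup 45 ml, a cup
about 250 ml), sputum colour (0–5, from no sputum through dark green to
blood-stained), cough (0–4) and cold/flu-like systemic symptoms (defined
levels 0, 1, 2 and 5 only). The daily total $S_t$ is the plain sum of the six
items and ranges 0–26.

Two scoring conventions deserve a note because the diary card leaves them
open:

* the systemic-symptom item prints no definitions for levels 3 and 4, so the
  validator rejects them by default (`lenient_coldflu = TRUE` remaps them to
  2 with a warning);
* volume-category boundaries are half-open with the boundary assigned to the
  higher category — exactly 5 ml is "teaspoon to an eggcup". The instrument
  only fixes the equivalence points, so an assignment rule had to be chosen;
  lower-inclusive-upward is the convention that keeps the map monotone and
  deterministic at the printed anchors.

## Baselines and event definitions

Everything downstream is built on a rolling baseline $B$: the median daily
total over the 7 calendar days before a reference day (an event onset, or day
8 of the study for the study-entry baseline). Medians over up to 7 integers
resist single bad days and diary gaps; windows with fewer than 4 observed
days walk backwards day-by-day, at most 21 days, before the estimate is
declared unusable. Why a fixed prior-week window rather than a global mean:
symptom levels drift, and events must be measured against the level
immediately preceding them.

Two event kinds are distinguished:

* **Reported (treated) events** are anchored by the day antibiotics were
  commenced. The onset is the earliest day within 14 days of treatment whose
  run of totals above baseline persists to the treatment day (onset and
  baseline are mutually dependent — the week before the onset defines the
  baseline — so the pair is iterated to a fixed point, which converges in
   2–3 rounds). The event ends on the first post-treatment day the total
  returns to, or below, the baseline median; the search is capped at 42 days
  and capped events are flagged truncated. Duration is counted from
  *treatment start* — the clinically reported recovery time.
* **Unreported events** are defined purely by the rule: a run of at least 2
  consecutive *observed* calendar days at least 3 points above the rolling
  baseline, outside (and not within a week after) any reported event, with
  no treatment. The 48-hour requirement is operationalised conservatively on
  daily data: a missing day breaks a run, because interpolating a symptom
  peak would invent data. Runs separated by fewer than 7 days merge — a
  relapse inside a week is the same episode. Duration is counted from onset,
  since these events have no treatment anchor.

For each event the six items are also compared against their own
baseline-week medians; a domain "worsens" when it exceeds its median on two
consecutive days inside the event, and events with at least three worsened
domains satisfy the consensus (EMBARC/BRR-style) symptom criterion.

One property of this detector is worth knowing: raising the threshold does
not strictly reduce the *number* of events. Because baselines roll and nearby
runs merge, a stricter threshold can split one merged episode into two
fragments covering the same days. What does hold — and what the test suite
asserts — is that nothing new appears: higher-threshold events always lie
inside lower-threshold event windows and the total number of event days never
grows.

## The synthetic cohort generator

No patient-level data accompany the instrument, so the package ships a
generator whose defaults emulate the published cohort kinetics, with planted
ground truth so every downstream statistic can be tested as a
parameter-recovery experiment.

Per patient, the latent daily total is

$$S_t = b + e_t + \varepsilon_t + f_t,$$

* $b \sim N(7.1,\,2.2^2)$ truncated to [2, 14]: the between-patient baseline
  distribution;
* $e_t$: the sum of active event-template offsets (below);
* $\varepsilon_t \sim N(0, s_0^2)$: persistent day-to-day noise, $s_0$ capped
  at 0.8 points;
* $f_t$: transient single-day flares — a bad day that does not persist.
  Flares are at least 3 points (3 + Exponential(mean 4)), occur with a
  per-patient daily probability capped at 0.045, never on consecutive days,
  and never during or within a week after an event template.

The latent total is rounded, clamped to [0, 26] and decomposed into six valid
item scores that move at most 2 points per item per day where feasible; the
systemic-symptom item is zero outside events (it rises with event intensity,
and absorbs totals beyond the 21 points the other five items can carry).
Days are dropped independently with probability 0.03, except treatment-start
days (the patient contacted the team that day, so an entry exists).

**Why the flare mixture.** A patient's day-to-day coefficient of variation is
drawn from a right-skewed Beta over the configured 16–98% range, and the
variance exceeding the persistent cap is carried by flares. This shape is
deliberate: sustained Gaussian noise at the upper end of that CV range would
cross the 3-point/48-hour rule almost continuously, which is incompatible
with unreported exacerbations being occasional, discrete episodes. Single-day
flares inflate the variability statistics but are exactly what the 48-hour
persistence requirement exists to filter. The realised stable-day CV on
default cohorts spans roughly 9–56% (median ≈ 20%): the generator
deliberately under-represents the extreme upper CV tail, because day-to-day
variation of that magnitude cannot coexist with the published event
statistics under this rule. Passing tests therefore say nothing about
patients whose diaries are wildly unstable.

**Event templates.** Arrivals are homogeneous Poisson per kind (defaults 1.5
treated and 1.2 untreated events per patient-year), placed with disjoint
occupied windows (template plus baseline week plus a 3-day gap), no earlier
than study day 15 (patients enter clinically stable); events that cannot be
placed after 100 tries are dropped — a patient already in an exacerbation
cannot start another. Reported events rise linearly over the report lag
(≈ 4.8 d, SD 3.5, truncated to 1–14) to the peak on the treatment day, then
decay linearly to baseline over the recovery time (≈ 15.3 d, SD 5.7,
truncated to 5–28). Unreported events have a two-day sub-threshold ramp, a
one-day peak with a shoulder just below it, and a linear decay (duration
≈ 10 d, SD 3.8, truncated to 4–21; peak change SD 1.5, truncated to 3–8
points). All template offsets except the final day stay at or above 1.2
points so that integer rounding never ends an event prematurely on noise-free
data — this is what makes noise-free planted-event recovery *exact*, a
property the tests rely on.

**Measured-scale calibration.** The event amplitude parameters are specified
on the *measured* scale — the scale on which a detector reports them —
because that is the only scale on which such quantities are ever observed:
an unreported exacerbation is, by definition, the output of the detection
rule. Measurement adds a positive offset to planted amplitudes
(maximum-of-noise at the peak, threshold censoring of weak events, selection
of low baseline estimates), so the generator plants latent amplitudes
shifted downward (`latent_shift_reported = -0.1`,
`latent_shift_unreported = -1.55`); the shifts were derived once from the
measurement model by simulation and then frozen. The unreported shift is
large because the latent peak is truncated to [3, 8]: mass piles up at the
3-point threshold and the detectable mean saturates, so reproducing a
measured mean of 4.7 requires a latent population concentrated just above
threshold — which is also the clinically plausible picture for events
patients did not consider worth reporting. A side effect is that the
dispersion of measured unreported changes is somewhat narrower than the
planted SD.

**Anchors.** Baseline questionnaires are drawn from a one-factor Gaussian
copula on the latent baseline: CAT (mean 19.1, SD 6.1, r = 0.61), SGRQ total
(41.5, 17, r = 0.61), SGRQ symptom domain (assumed 55, SD 18, r = 0.52), LCQ
(assumed 14, SD 3, r = −0.52 — its cohort moments are not published; the
assumed values sit centrally in the instrument's 3–21 range) and six-minute
walk distance (439 m, SD 104, r = −0.46), clamped to each instrument's range.
The one-factor construction makes the implied correlation matrix positive
semi-definite by design, and the validator still checks it before sampling.
`plant_anchor_slope()` rescales an anchor's SD so the BEST-on-anchor
regression has a prescribed slope — the anchor-MCID conversion depends only
on that slope, so experiments about the conversion plant it directly rather
than relying on the copula defaults.

## Validation statistics

* **Convergent validity**: ordinary least squares of baseline BEST on each
  anchor (`stats::lm`), Pearson r with the two-sided t-test p-value
  (`stats::cor.test`), pairwise deletion, zero-variance inputs flagged
  rather than fitted.
* **MCID, three ways**: half the sample SD of per-participant baseline
  scores (the distribution-based estimate; a config switch uses all diary
  days instead, since "scores for all participants" is ambiguous);
  |slope| × anchor MCID for each anchor with |r| > 0.3 (SGRQ 4 points,
  CAT 2, LCQ 1.3), with the regression direction BEST-on-anchor so the
  conversion lands on the diary scale; and the mean rise of the
  pre-exacerbation period over baseline across reported events.
* **Cutoff performance**: episodes are the unit of analysis. Sensitivity at
  cutoff c is the share of treated events with peak change ≥ c; specificity
  is the share of *stable windows* with change < c, where stable windows are
  non-overlapping 14-day tiles of non-event diary (a 7-day buffer before
  each onset is censored), each scored by its second-week maximum minus its
  leading-week median — the same change construction the detector applies to
  an event, evaluated where no event occurred. The instrument never states
  the unit of analysis for these statistics; windows of matched construction
  are the choice that makes specificity estimable from the same diaries, and
  the window length and buffers are exposed as arguments.
* **Variability**: per-patient sample SD and CV of stable-day totals,
  requiring at least 8 stable days; a zero mean flags the CV undefined.
* **Paired comparisons**: `stats::t.test(paired = TRUE)`, with constant
  nonzero differences reported at a 1e-15 p-value floor rather than zero.

No multiplicity correction is applied anywhere: the analysis reports raw
p-values with their n, as is conventional for a pilot-scale validation.

## Numerical and degenerate-input choices

* Baselines are medians of integers, so they are integers or half-integers;
  ties at the event-end comparison ("first day at or below baseline")
  resolve to the earlier day.
* A reported event with a flat pre-treatment series degenerates to onset =
  treatment day, an empty pre-period (NA pre-period mean) and zero peak
  change; it is kept, flagged by its zero onset time, and excluded from the
  onset-MCID (which requires a finite pre-period mean).
* Events still elevated at the search cap (42 days for reported events, the
  diary end or a censor boundary for unreported ones) are flagged truncated;
  truncated reported events are excluded from mean-duration summaries.
* All generation is driven by one config seed from which per-patient streams
  are derived, so cohorts are reproducible and patients order-independent.

## Problem sizes used in the checks

The packaged checks run cohort recovery at 500 patients × 180 days (about
40 s), copula recovery at 1000 patients × 56 days (the baseline needs only
the first week, so 8 weeks of diary suffice), the noisy detector-recovery
property at 500 patients, and the brute-force detector-equivalence corpus at
1000 random diaries of 20–60 days. These sizes put Monte Carlo error
comfortably inside the tolerances being checked (about 1% on a detection
rate, under 0.1 point on a cohort mean).

## Known limitations

* The generator models total-score dynamics; item-level trajectories are a
  smoothness-constrained decomposition, not a natural-history model. The
  worsened-domain counts it produces are consequently optimistic — planted
  events spread their rise across items, so nearly all of them meet the
  3-of-6 criterion, which real reported exacerbations do not always do.
* Hospitalised severe exacerbations, treatment response, seasonality and
  adherence decay are not modelled; missingness is independent thinning.
* The extreme upper tail of between-patient variability is deliberately not
  emulated (see above).
* Anchor questionnaires are generated at baseline only; the exacerbation
  start/end visit structure exists in the file format but is not simulated.
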