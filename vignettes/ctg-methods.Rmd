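---
title: "Methods: CTG cleaning, features, fusion and diagnostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTG cleaning, features, fusion and diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgdx)
```

## The problem

Intrapartum cardiotocography records fetal heart rate (FHR, bpm, here at a
fixed 4 Hz) alongside relative uterine-contraction strength (UC). Readers —
and algorithms — judge from a trace whether the newborn is at risk of
asphyxia, defined here from delivery-room observables: Apgar score below 6
at 1 or 5 minutes, or umbilical-artery pH below 7.1, all strict
inequalities. `ctgdx` implements the full chain from raw trace to
diagnostic-accuracy tables, plus a synthetic cohort generator that stands
in for clinical recordings.

## Cleaning model and boundary semantics

Monitor exports encode dropout as exact zeros. The cleaning chain runs in a
fixed order; each rule's boundary follows the printed inequality exactly:

1. **Discontinuation.** A run of consecutive zero samples lasting at least
   15.0 s (60 samples) ends the recording at the run's first sample;
   earlier data are kept. 59 zero samples (14.75 s) do *not* truncate.
   Full-record rejection would contradict the later interpolation of "any
   other" zeros, so truncation is the default reading; a config switch
   (`truncate_at_zero_run = FALSE`) masks instead, for sensitivity
   analysis.
2. **Range mask.** Remaining zeros, values `>= 200` bpm and values
   `<= 50` bpm become missing (inclusive bounds: 200 and 50 are removed,
   199 and 51 kept).
3. **Spike mask.** A sample deviating by strictly more than 25 bpm from
   the mean of its 15 s window is removed; a deviation of exactly 25 is
   kept. The window is centered (the printed rule states only the length),
   spans exactly 15 s — 61 samples, 60 sampling intervals — includes the
   sample itself and excludes already-masked samples. Decisions are made
   in a single pass against pre-pass values, because an iteration order
   for cascading re-evaluation is not defined anywhere; iterating to
   convergence could remove legitimate samples adjacent to spikes.
4. **Interpolation.** Interior gaps are filled linearly between nearest
   observed neighbours. Leading/trailing gaps take the nearest observed
   value: a line is undefined with one anchor, and constant extension is
   the least-assuming completion.
5. **UC smoothing.** Centered moving average spanning 60 s. We use the
   odd 241-sample window (240 intervals = 60.0 s between its endpoints),
   shrunk symmetrically at the edges. The odd window makes the average of
   a linear ramp exactly the identity in the interior, at the cost of a
   unit impulse spreading to 1/241 rather than 1/240 — a 0.4 % difference
   we consider the better trade against the phase bias an even window
   introduces.
6. **Segment extraction.** The analysed window is the half-open
   `[delivery - 50 min, delivery - 20 min)`, exactly 7200 samples.
   Cleaning runs before extraction (the alternative order is unstated;
   cleaning first uses the most context for the window means and
   interpolation anchors).

Cleaning is deterministic and idempotent: a cleaned trace re-enters the
pipeline as a no-op by class dispatch. Re-running the *stages* on cleaned
data removes nothing (tested); the dispatch shortcut exists because UC
smoothing, applied twice, would not be idempotent.

## The 44-feature vector

The feature roster spans the categories a guideline-trained reader scores:
baseline (level, drift, bradycardia/tachycardia fractions at the
conventional 110/160 bpm limits), short-term variability (per-minute mean
absolute successive difference), long-term variability (per-minute
max–min excluding event samples; aggregate = median), accelerations
(`>= baseline + 15` bpm sustained `>= 15` s), decelerations
(`<= baseline - 15` bpm, `>= 15` s) typed by the nadir's lag to the nearest
smoothed-UC peak — early (|lag| ≤ 15 s), late (15 < lag ≤ 60 s, nadir after
the peak), variable (no contraction within 60 s, abrupt onset, or nadir
well before the peak), prolonged (`>= 120` s below threshold, overriding) —
plus uterine context. The exact 44-name order lives in
`inst/extdata/feature_manifest.csv`; the original roster behind the number
44 is not recoverable from the published description, so this manifest is
the package's documented convention, revisable without touching code.

Baseline is the mode of 2.5 bpm-binned values refined by the mean of
samples within ±10 bpm of the modal bin — robust to excursions without
needing event detection first. Consequence: baseline-shift equivariance is
exact for shifts on the 2.5 bpm grid and holds within ~0.05 bpm otherwise
(tested both ways).

## Judgments and fusion

The per-case human score is the *prediction ratio* — the fraction of the
rater panel calling the case positive. The narrative description of the
combined predictor as using the "percentage of correct responses" would
require the truth label at fusion time (leakage); the prediction-ratio
reading is the one consistent with the reported workflow and is the
default, with the literal variant available via
`human_ratio(type = "correct")` for sensitivity analysis.

Model scores binarize at the inclusive 0.50 cutoff. Fusions: additive
(`h + d`, range [0, 2]; rank statistics are scale-invariant) and product
(`h * d`). The product rule has a subset property: at any common cutoff
`t` in (0, 1], `h·d ≥ t` implies `h ≥ t` and `d ≥ t` (both factors are
≤ 1), so false positives are a subset of each input's and specificity is
non-decreasing — the mechanism by which combining a human panel with a
model raises specificity. The cutoffs used for binarizing human-only and
fused channels in the source tables are not stated; all default to 0.50
and are exposed in `decision_params()`, since printed 2×2 counts cannot
disambiguate them.

## Diagnostic evaluation

Percent metrics are computed from 2×2 counts and reported half-up-rounded
to 2 decimals (raw values retained); zero denominators flag the metric
undefined rather than erroring. ROC operating points sit at every distinct
score threshold (positive at `score ≥ t`), so the trapezoidal area equals
the midrank Mann–Whitney AUC identically, ties included — tested against
an exhaustive pair-counting oracle. AUC significance uses the
Hanley–McNeil standard error with a two-sided normal test of AUC = 0.5;
the source's p-value method is unstated, so exact reproduction of its
printed p-values is not claimed. `LR+ = TPR/FPR` per threshold, with an
infinity marker at zero-FPR points; the "likelihood ratio range" notion is
read as the span of finite per-threshold LR+ along the curve, and whether
infinite points may dominate the maximum is a flag.

## The synthetic world

The generator emulates the *statistical shape* the analysis assumes, not
fetal physiology:

* **Traces.** FHR = baseline + band-limited noise (white noise smoothed
  over ~3 s, scaled so a minute's peak-to-peak ≈ the configured
  amplitude) + raised-cosine accelerations + raised-cosine decelerations
  whose nadirs sit at a configured lag after contraction peaks; UC =
  tonus + Gaussian bells at a regular period. Event counts are
  deterministic (`round(rate × duration)`), placement random and
  non-overlapping, so the ground-truth ledger is exact. Defaults
  (baseline 140 bpm, variability 10 bpm, accelerations 25 bpm / 60 s,
  decelerations 30 bpm / 60 s, contractions every 180 s, 3600 s duration)
  are ordinary labour-trace magnitudes.
* **Artifacts.** Dropout zero runs (default 1–8 s, 6/h), out-of-range
  spikes and in-range jumps (12/h combined). Jump magnitudes default to
  35–60 bpm: a jump barely above the 25 bpm rule is indistinguishable
  from variability noise and hence not removable, so the injector — whose
  contract is to inject *removable* artifacts — keeps a margin above the
  noise floor. `long_dropout_prob` (default 0) injects ≥ 15 s runs that
  trigger discontinuation.
* **Outcomes.** Asphyxia probability is logistic in ground-truth risk
  features (late-deceleration count, variability deficit, bradycardia
  fraction; coefficients 0.9 / 2.0 / 5.0), with the intercept calibrated
  so the mean probability matches the target prevalence 31/489. The
  fixed-margin cohort draws *exactly* `n_pos` positives, weighted by risk,
  mirroring the fixed 489/31 evaluation split; `sample_outcome()` remains
  the unconditional Bernoulli draw. Apgar/pH are drawn label-conditionally
  so the labeling rule reproduces the label by construction.
* **Raters and models.** Each rater sees 50 figures (10 positive, 40
  negative) sampled without replacement and judges per-figure Bernoulli at
  the configured sensitivity/specificity; defaults are the observed pooled
  human operating point (22.58 % / 91.92 %), panel 34 obstetricians + 22
  midwives, attrition 0. The score channel draws its binary call at the
  configured operating point (default 22.58 % / 81.88 %) and then a score
  uniform on the matching side of 0.5; the binary channel defaults to
  3.23 % / 93.89 %. Average views per figure default to ~4 (the reported
  response volume over the evaluated cohort), via
  `n_raters = ceiling(4n/50)`.

**What a green test does and does not establish.** The synthetic world has
exactly the structure the cleaner and feature extractor assume: events are
raised cosines, noise is stationary and Gaussian, contraction trains are
regular, artifacts are cleanly separable from signal. Green tests
establish that the *rules as stated* are implemented exactly and that the
pipeline is internally consistent — not that these rules suffice on real
traces, where maternal-heart-rate capture, non-stationary variability and
ambiguous event morphology violate every one of those assumptions. The
"per-gap linear bound" for interpolation is operationalised as: each
restored sample lies within the range of the clean signal over the gap
plus its two anchors (interpolation cannot leave the anchors' span, and
the truth cannot leave the local range).

## Numerical choices

* Percent rounding is half-away-from-zero (commercial), not banker's,
  with a `1e-9` representation guard — the printed tables round that way.
* Degenerate inputs: all-missing FHR, a zero run starting at sample 1,
  segment requests beyond the trace span, and single-class ROC inputs all
  raise typed errors (`ctgdx_*` condition classes); zero-denominator
  metrics flag rather than fail.
* `with_seed()` isolates every generator from the caller's RNG state;
  identical seeds reproduce cohorts bit-for-bit.
* Known limitations: no maternal-heart-rate disambiguation, no sinusoidal
  pattern detection, no paired-ROC method comparison, no emulation of the
  original random-forest/CNN models (their scores enter only as
  configurable operating points), and the published AUC/likelihood-ratio
  extremes are not reproducible without the unpublished per-case scores —
  properties of the machinery stand in for them in the test suite.
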