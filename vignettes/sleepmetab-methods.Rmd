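---
title: "Models, parameters, and design choices in sleepmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters, and design choices in sleepmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmetab)
```

This vignette documents the statistical models the package implements, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design decisions taken
where the methodology left room. It states no empirical result that the
test suite and the acceptance script do not themselves compute.

## 1. The study design being analysed

A randomized crossover sleep study: each subject (13 by default) completes
a **control** block (8 h sleep every night) and a **sleep-deprivation**
block (one night of total sleep deprivation, i.e. 40 consecutive hours of
wakefulness, followed by a recovery night). Oral fluid is sampled at seven
fixed clock times — day 1 20:30 (t1), day 2 22:55 (t2), day 3 08:10 (t3),
13:55 (t4), 21:00 (t5), 22:55 (t6), day 4 08:10 (t7) — with habitual sleep
scheduled 23:30–07:30. t1 and t2 precede the experimental night; t3–t6 fall
inside the window where deprivation effects can exist; t7 follows the
recovery night. `timepoint_schedule()` and `hours_awake()` encode this
arithmetic; in the deprivation arm the hours awake at t3–t6 run from 24.7
to 39.4, versus 0.7–15.4 under control.

The injection sequence mirrors untargeted LC-MS practice: a pooled QC
sample every 5 study injections (and bracketing every block), one process
blank, and a QC dilution series (100/50/20/10 %) at the start and end of
the run.

## 2. Preprocessing

The stage order is fixed: drift correction → feature QC/filtering →
subject filtering → 1/5-LOD imputation → log10 transform. QC metrics are
computed on drift-corrected, pre-log abundances, because correction
precedes filtering in the protocol the pipeline reproduces.

**Drift correction.** Per feature and batch, a tricube-weighted local
linear regression (plain `lowess`, no robustness iterations) of QC
abundances on run order, with span `min(1, window/n_QC)` so that about
`window` QC points (default 8) carry weight. The fitted trend is linearly
interpolated to every injection and clamped to the edge values outside the
first/last QC injection — extrapolating a local fit beyond its anchors
invites wild corrections at the run edges. Every sample type is rescaled
by `median(QC)/trend(r)`. Because a weighted least-squares line through
collinear points reproduces them exactly, noise-free linear drift is
removed to machine precision (asserted at 1e-6 relative in the acceptance
suite). The trend is floored at 1 % of the QC median, capping the
correction factor at 100x, so a positive value can never change sign.
Features with fewer than two usable QC values pass through unchanged and
are flagged rather than silently mangled.

**Feature filter.** Removal criteria are all strict (`>` / `<`), so
boundary values survive: blank presence, QC RSD > 25 %, dilution r² < 0.7,
D-ratio > 50 %, missing-or-zero fraction > 30 % (the same 30 % rule drops
subjects). Two operationalizations were needed where the protocol names no
number:

* *present in process blank* — mean blank abundance (missing read as 0)
  above 5 % of the mean QC abundance (`blank_ratio_max`). Absolute nonzero
  detection is too brittle under simulated noise, and 5 % is a common
  signal-to-blank cutoff.
* *dilution linearity* — squared Pearson correlation of abundance against
  dilution fraction, pooling both series (run start and end), which also
  averages over the drift the series brackets.

Metrics that cannot be computed (fewer than 3 usable points, zero-variance
denominator) are recorded as undefined; the filter resolves them by policy
(default: drop the feature — an unverifiable feature is not a trustworthy
one). The D-ratio uses classical sample standard deviations; dilution and
blank injections are drift-corrected like everything else (uniform
treatment; the alternative — raw dilutions against corrected QCs — would
mix scales within one metric).

**Imputation and transform.** Missing or zero study values are replaced by
one fifth of the feature's smallest positive study value (1/5 LOD), then
study/QC/dilution values are log10-transformed; blanks are excluded from
the log table (zeros are their normal state, not data). Imputation counts
are reported in the run manifest for audit.

## 3. Repeated-measures ANOVA with Greenhouse–Geisser correction

For each feature, the complete-case block over t3–t6 x condition x subject
is decomposed classically (both factors within-subject): sums of squares
for time, sleep, time x sleep, subject, and the three subject-interaction
terms; each fixed effect is tested against its own subject-interaction
mean square. Percent of total variation is `100·SS(effect)/SS(total)`.

Sphericity of the time factor (4 levels at short, unequal intervals) is
handled by the Box/GG epsilon: with `S` the sample covariance of the
within-subject scores and `C` an orthonormal contrast basis,
`epsilon = tr(CSC')² / ((k−1)·tr((CSC')²))`, clamped to `[1/(k−1), 1]`;
both numerator and denominator degrees of freedom are multiplied by
epsilon. Choices made here:

* epsilon for the **time** effect comes from subject-level means over the
  two conditions; for the **interaction**, from the per-subject
  condition-difference scores across time levels — the standard
  construction when the method is named but its multi-way mechanics are
  not spelled out. The sleep factor has two levels (one contrast), so its
  epsilon is identically 1.
* a zero-variance feature reports p = 1, not NaN, keeping downstream
  tabulation total.
* the GG-corrected p is provably ≥ the uncorrected p throughout the
  rejection region (uncorrected p ≤ 0.05) for this design; deep inside the
  acceptance region the ordering can flip (scaling *both* dfs shifts the
  F-distribution's bulk), which affects no call the pipeline makes. The
  test suite asserts exactly the defensible region.

**Subject-wise z-scoring** pools both conditions and all seven time points
per subject (per feature): the profile figures this mirrors place both
conditions on a single per-subject z-scale, and normalizing per condition
would erase genuine condition-level shifts. Zero-spread (subject, feature)
pairs go to missing with a warning. The ANOVA runs in both modes (log10
and z-scored) and both are emitted, since the source analysis reran rather
than replaced.

## 4. Paired testing and profile classification

Per feature and time point, a two-sided paired t-test (deprivation −
control) over complete subject pairs; fewer than 3 pairs makes the cell
undefined (counted non-significant, but flagged). A zero-variance
difference vector is a degenerate limit: p = 1 when all differences are 0,
else p = 0 with a degeneracy flag. The default level is α = 0.01
(untargeted mode; 0.05 targeted), with no further correction across
features — multiplicity is handled by the reduced α plus the gate logic,
and an optional BH flag would change the analysis being reproduced, so it
defaults off.

Classification applies rules in strict order: significant at t1 or t2 →
`non_robust`; else at t7 → `non_adaptive`; else at all of t3–t6 →
`sleep_linear`; else at ≥ 1 of t3–t6 → `sleep_rhythmic`; else
`unaffected`. The same α gates all seven time points. The construction's
compound false-positive rate is `alpha·(1−alpha)³` = 0.009703 at α = 0.01
(`compound_fp_rate()`), and the acceptance suite verifies the empirical
null flag rate against it within binomial Monte-Carlo error.

## 5. The synthetic-data generator

`generate_dataset()` draws, per feature, a log10 model

```
y = mu + u_subject + A·cos(2*pi*(hour_of_day − phi)/24) + effect + e
```

with `raw = 10^y · drift(run_order)`, linear multiplicative drift clipped
at 0.1, QC pools at the rhythm-averaged baseline with lognormal technical
noise, dilutions at `QC x fraction`, blanks at zero except for contaminant
features, and per-feature LOD censoring at a quantile of the study values.
Effect shapes by class: `sleep_linear` scales with hours awake
(`delta·(h−15)/25` over t3–t6, zero at the gates — h runs 24.7→39.4, so
the profile rises roughly linearly through the deprivation day);
`sleep_rhythmic` adds `delta` at t3 only (the suppressed morning trough);
`non_adaptive` persists through t7; `non_robust` is present at every time
point (a pre-existing group difference); `null` and `contaminant` carry no
effect.

Defaults state the emulated world once:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 13 | the crossover cohort size |
| `subject_sd` | 0.35 log10 | between-subject spread must dominate: the observed non-normalized subject effect is the largest variance component by far |
| `residual_sd` | 0.08 log10 | within-subject biological+analytical noise, ~20 % CV |
| `technical_sd_qc` | 0.04 log10 | ~9 % QC RSD, typical for a passing untargeted batch |
| `rhythm_amplitude_range` | 0.05–0.25 log10 | from barely rhythmic to strongly diurnal (cortisone-like) |
| `effect_size_range` | 0.15–0.45 log10 | free parameters (the study never quantifies raw-scale effects); spans subtle to ~3-fold |
| `drift_slope_range` | ±0.2 | up to ±10 % drift across the run, enough to exercise the correction |
| `lod_quantile` | 0.05 | yields ~5.5 % replaced values, the order of the reported 7.1 % |
| `class_mix` | 70 % null, 4x5 % response classes, 10 % contaminant | ~10 % of features sleep-altered in at least one time point, as observed |

The rhythm is a cosinor — the minimal standard form for a process known
only to show a morning trough; acrophases are uniform, so the morning
trough is a property of individual features, not the panel. LOD censoring
is quantile-based per feature (not an absolute threshold) so the
missingness rate is controlled by one parameter; it is applied to study
injections only, because the threshold is defined from study values and
the missingness/imputation rules act on study cells — censoring the
dilution series as well would couple the linearity filter to biological
abundance in a way that cannot be disentangled at desk scale. Drift is
linear within the (single, by default) batch: sufficient to exercise a
local smoother whose claim is generic trend removal.

**What a green test establishes — and does not.** The generator produces
clean cosinor rhythms, Gaussian log-scale noise, exactly linear drift and
exactly proportional dilutions. Real data add retention-time instability,
correlated features (adducts/isotopologues of one metabolite), heavy
tails, batch discontinuities and nonlinear saturation, none of which are
modelled. Green acceptance tests therefore certify the *statistical
machinery* (decompositions, calibration, rule logic, recovery under the
stated noise model), not instrument-level robustness. The published
dataset-scale counts (thousands of retained features, specific
per-timepoint hit counts, Table-style medians) depend on raw spectra and
proprietary peak picking upstream of this package's scope and are not
reproduction targets; the one analytic printed number reproduced exactly
is the 0.97 % compound false-positive rate.

## 6. Numerical conventions

* CSV, comma-separated, UTF-8, header mandatory; missing = empty cell on
  output, with "NA"/"NaN" also accepted on input. Numbers are written with
  15 significant digits, making write→read→write byte-stable and
  round-trips exact to well below 1e-9 relative.
* All sample standard deviations use ddof = 1.
* Seeded determinism end to end: one seed drives simulation and every
  downstream artifact; reruns are byte-identical.
* Epsilon uses a normalized Helmert contrast basis; any orthonormal basis
  gives the same traces (the tests cross-check against the eigenvalue
  form).

## 7. Known limitations

* Balanced complete-case ANOVA only: subjects with incomplete t3–t6 cells
  are dropped per feature (counted, not imputed). Mixed-model (REML)
  alternatives are out of scope.
* The classifier is a fixed decision list on marginal p-values; it does
  not model profile shape jointly and inherits the per-timepoint tests'
  power profile.
* Circadian phase is not estimated (no constant-routine data exists in
  this design); "rhythmic" is an inference from the gate pattern, not a
  cosinor fit.
* Single-batch default; multi-batch correction is supported by the same
  code path (per-batch fits) but the generator plants only one batch.
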