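# sleepmetab

Reusable analysis pipeline for crossover sleep-deprivation metabolomics
time-course studies in oral fluid (or any matrix with the same design):
QC-pool-anchored run-order drift correction, quality filtering, missing-value
imputation, transformation and normalization, repeated-measures variance
decomposition, per-timepoint paired testing, and a rule-based classification
of each molecular feature's time-course profile. A synthetic-data generator
emulates the full study design with known ground truth, so every stage is
testable without any instrument data.

## The scientific problem

Untargeted LC-MS metabolomics of oral fluid in a within-subject crossover
design — every subject sampled at seven time points (t1..t7) under both a
control condition (repeated 8-h sleep) and a total-sleep-deprivation
condition (40 h of sustained wakefulness, then recovery sleep) — poses two
coupled questions:

1. **Variance decomposition.** How much of each metabolite's total variation
   is attributable to sampling time of day, to the sleep intervention, and
   to stable between-subject differences? This is a two-way repeated-measures
   ANOVA (both factors within-subject) over the deprivation-sensitive window
   t3–t6, with the Greenhouse–Geisser (GG) correction guarding the time
   factor against sphericity violations, and each effect summarized as
   percent of total variation, `100·SS(effect)/SS(total)`.

2. **Profile classification.** Which features respond to sleep loss itself?
   Per time point *t*, a paired t-test contrasts deprivation against control
   across subjects. A feature is only credibly *sleep-related* if it is
   significant somewhere in t3–t6 while **non-significant** at t1 and t2
   (sampled before the experimental night) and at t7 (after the recovery
   night — the proof-of-concept control). Significance at t1/t2 marks a
   feature *non-robust*; at t7, *non-adaptive*. Significance at all of
   t3–t6 suggests a *linear* wakefulness-tracking response; at a subset
   (typically the morning sample t3, where sleep loss abolishes the usual
   morning trough), a *rhythm-mediated* response. With per-test level
   α = 0.01, the probability that a null feature passes one deprivation
   time point while clearing all three gates is

   α(1−α)³ = 0.01·0.99³ = 0.009703 ≈ **0.97 %**,

   the compound false-positive rate of the whole construction.

Upstream preprocessing follows standard untargeted-QC practice: a locally
weighted (LOWESS) fit of QC-pool intensities against injection order
removes multiplicative drift; features are dropped if present in the
process blank, QC RSD > 25 %, dilution-series linearity r² < 0.7, D-ratio
(technical/biological spread) > 50 %, or more than 30 % missing/zero study
values (subjects likewise at 30 %); remaining missing values are replaced
by one fifth of the feature's lowest detected value (1/5 LOD) and the
table is log10-transformed. Subject-wise z-scoring (auto-scaling per
subject) removes between-subject location/scale differences before the
normalized ANOVA pass.

## Worked example

```r
library(sleepmetab)

cfg <- pipeline_config(out_dir = "demo_run", seed = 42,
                       sim = sim_config(n_features = 200))
res <- run_all(cfg)

res$manifest$n_features_kept   # 180  (20 of 200 removed by the QC filter)
res$manifest$n_values_imputed  # 1800 (5.5% of study cells, LOD-censored)

res$summary$category_counts
#>     non_robust   non_adaptive   sleep_linear sleep_rhythmic     unaffected
#>             10             10              3             23            134

res$summary$per_timepoint_significant
#> t3 t4 t5 t6
#> 36 27 31 30

attr(res$anova_log10, "summary")    # percent of total variation, raw log10
#>    factor      median          min      max
#> 1    time  7.56634903 3.048432e-01 36.20390
#> 2   sleep  0.06345706 9.662619e-06 31.76164
#> 3 subject 80.58268986 3.398969e+01 95.28244

attr(res$anova_zscore, "summary")   # after subject-wise z-scoring
#>    factor     median          min       max
#> 1    time 49.7166799 1.856424e+00 86.403785
#> 2   sleep  0.4188729 6.692363e-06 79.212562
#> 3 subject  1.9465761 3.191325e-01  9.355466

compound_fp_rate(0.01) * 100
#> [1] 0.970299
```

Reading the output: the simulator plants 70 % null features, 10 % blank
contaminants (caught by the filter: 180 kept), and 5 % of each response
class. On the log10 scale the subject effect dominates (median 80.6 % of
total variation); after z-normalization it collapses to 1.9 % and time of
day becomes the major influence (49.7 %) — the motivation for within-subject
normalization. The classifier recovers the planted sleep-responsive
features and quarantines pre-existing group differences (`non_robust`)
and non-recovering ones (`non_adaptive`); most alterations land at the
morning sample t3.

All artifacts (corrected table, QC report, log10/z-score tables, ANOVA
table in both modes, p-value matrix in features x t1..t7 layout,
classification and summary, JSON manifest) are written under `out_dir` as
plain CSV; identical config + seed reproduce them byte-identically.

The same stages are scriptable via the CLI
(`inst/cli/sleepmetab.R`):

```sh
Rscript inst/cli/sleepmetab.R simulate --out sim --seed 3 --n-features 200
Rscript inst/cli/sleepmetab.R run-all --stem sim --out run_dir
```

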