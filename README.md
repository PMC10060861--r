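# painsegr

Brain system segregation and the longitudinal progression of chronic pain:
a tested, reproducible implementation of the full analysis chain, for
researchers studying how resting-state network organization and pain
catastrophizing relate to pain outcomes over time.

## What it computes

**System segregation.** From parcellated resting-state BOLD time series
(100 nodes, 7 canonical cortical networks) the package builds
nuisance-cleaned functional connectivity — Pearson correlations, Fisher-z
transformed, negatives zeroed, diagonal excluded — and, per network,

```
SyS_net = (W_net − B_net) / W_net
```

where `W_net` is the mean z-connectivity over node pairs within the
network and `B_net` the mean over pairs joining the network to the rest of
the cortex. Motion QC uses framewise displacement,
`FD_t = Σ|Δtrans| + 50·Σ|Δrot|` (mm), excluding subjects with FD > 0.5 mm
on at least half of the volumes.

**Pain outcomes.** Brief Pain Inventory interference is scored into
affective and activity composites, the Pain Catastrophizing Scale into its
total and rumination / magnification / helplessness subscales, and *pain
experience* is the mean of intensity and affective interference at each of
two surveys; its T2 − T1 difference (positive = worsening) is the
longitudinal outcome.

**Inference.** Welch t and chi-square group contrasts (plus pooled-F
recomputation from summary statistics), covariate-adjusted ANCOVA per
network, partial correlations by the residual method, standardized-beta
regressions with VIF diagnostics, and moderation models with 5,000-sample
percentile-bootstrap CIs and Johnson–Neyman regions of significance
(`(b1 + b3·w)² = t²·Var(b1 + b3·w)`, solved as a quadratic in the
moderator).

**Synthetic cohorts.** A generator with known ground truth — block-
covariance BOLD (within-network r = 0.5 vs between 0.1, whose population
segregation is analytically `(atanh 0.5 − atanh 0.1)/atanh 0.5 ≈ 0.817`),
AR(1) motion at per-group FD targets, and item-level phenotypes with a
planted standardized model including a helplessness × DMN-segregation
interaction — so every stage has a parameter-recovery test.

## Worked example

```r
library(painsegr)

co  <- simulate_cohort(sim_config(n_subjects = 300, seed = 7),
                       generate_timeseries = FALSE)
run <- run_pipeline(pipeline_config(cohort = co, seed = 7))
tidy(run$results$regression)
```

```
  term                    estimate std.error statistic p.value   vif
1 helplessness               0.238    0.0783      3.04 3.08e-3  1.07
2 sys_default                0.223    0.0776      2.88 5.02e-3  1.06
3 sys_dorsoattention        -0.102    0.0776     -1.32 1.92e-1  1.05
4 intensity_t1              -0.382    0.0779     -4.90 4.14e-6  1.06
5 affective_interference…   -0.471    0.0786     -5.99 4.10e-8  1.08
6 activity_interference_…    0.290    0.0771      3.76 2.95e-4  1.04
```

Standardized betas on the simulated pain group (n = 99): higher
helplessness and DMN segregation predict worsening pain experience, higher
baseline intensity/affective interference predict regression toward
improvement, and all VIFs near 1 confirm the regressors are not collinear
— the directions the generator planted. The moderation stage reports the
interaction with its bootstrap CI and the Johnson–Neyman boundary:

```
interaction b = 3.682, p = 0.0219, 95% bootstrap CI [0.483, 7.033] (5000 resamples)
Johnson-Neyman boundary at moderator = 9.854
```

i.e. the conditional effect of DMN segregation on pain progression is
significant for helplessness scores above ~9.9 in this simulated cohort.
`autoplot(run$results$johnson_neyman)` draws the region of significance;
`make_report(run)` renders the full plain-text summary.

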