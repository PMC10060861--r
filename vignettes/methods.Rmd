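---
title: "Brain system segregation and chronic-pain progression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain system segregation and chronic-pain progression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painsegr)
```

## The scientific question

Chronic pain — pain persisting or recurring for more than three months — is
shaped not only by nociception but by cognition and emotion. Pain
catastrophizing, and in particular its helplessness component, is thought to
entrench maladaptive pain processing, and resting-state fMRI work has
repeatedly implicated the default-mode (DMN) and dorsal-attention (DAN)
networks. `painsegr` implements a longitudinal analysis of this interplay:
it quantifies how cleanly the cortex decomposes into its canonical
functional networks (system segregation), scores the pain instruments into a
composite pain-experience outcome measured at two surveys roughly ten months
apart, and asks whether baseline segregation and catastrophizing predict —
and interact in predicting — the change in pain experience.

## System segregation

For each subject, parcel-averaged BOLD time series (100 nodes, 7 canonical
networks) are cleaned by regressing out nuisance signals, correlated
node-by-node, Fisher-z transformed (`z = atanh r`, which makes correlations
averageable), negative values set to zero, and autocorrelations discarded.
For a network `net`,

- `W_net` is the mean z over all unordered node pairs inside the network,
- `B_net` is the mean z over all pairs joining the network to the rest of
  the cortex, and
- `SyS_net = (W_net - B_net) / W_net`.

`SyS = 1` means no external connectivity at all; `SyS = 0` means the network
is no better connected internally than externally. Two reading choices are
worth making explicit because the verbal definition admits both:

- `B_net` pools all network-by-rest node pairs rather than averaging the six
  per-network means; "the rest of the cortex" is a single set of nodes.
- Pairs truncated to zero stay in both denominators: truncation substitutes
  a value, it does not remove an observation.

Correlations are clipped to `±(1 - 1e-7)` before `atanh` so numerically
perfect correlations cannot produce infinities while the ordering of values
is preserved. A network with `W = 0` has no defined ratio; the profile flags
it (`sys_defined = FALSE`) rather than reporting 0 or infinity.

## Motion quality control

Framewise displacement follows the conventional rigid-body formulation:
`FD_t = Σ|Δtranslation| + r·Σ|Δrotation|` with the sphere radius `r = 50`
mm, the standard constant converting radians of head rotation into
millimetres of cortical displacement. Subjects are excluded when at least
half of their volumes exceed 0.5 mm ("at least" read as ≥, so exactly 50%
already excludes). Motion parameters enter nuisance regression as the six
parameters plus backward-difference derivatives (first row zero-padded),
alongside a discrete-cosine drift basis retaining every component strictly
below 0.01 Hz — `K = floor(2·T·TR·0.01)` columns, 11 for the default
740-volume, TR = 0.8 s acquisition — and, when supplied, white-matter and
CSF signals. The first 10 volumes of raw-length inputs are dropped before
anything else (magnetization equilibrium); simulated series are generated
at the post-dummy length, so the pipeline default is `n_dummy = 0`.

## Instrument scoring

The Brief Pain Inventory interference items are averaged into an affective
subdimension (relations with others, enjoyment of life, sleep, mood) and an
activity subdimension (walking, general activity, work); sleep is kept in
the affective domain, with the item map exposed for the three-domain
alternative. The Pain Catastrophizing Scale sums 13 items rated 0–4 into a
0–52 total with rumination (items 8–11, max 16), magnification (6, 7, 13,
max 12) and helplessness (1–5, 12, max 24) subscales; the keying follows the
original instrument and is configurable because translated forms sometimes
reorder items. No missing-item imputation is performed anywhere.

The composite outcome, *pain experience*, is the mean of pain intensity and
affective interference at a timepoint, and its longitudinal version is the
T2 − T1 difference (positive = worsening). The mean is the intended
definition; a `variant = "difference"` flag computes `(intensity −
affective)/2` instead, retained because the subtraction form appears in some
write-ups of this composite and the flag makes the two comparable. Subjects
reporting chronic pain at both surveys form the pain group, at neither the
no-pain group; switchers (recovered/developed) are labelled and excluded
from the two-group analysis.

## Inferential chain

Group contrasts use Welch t tests and the 2×2 Pearson chi-square without
continuity correction; the uncorrected form is what the pooled
summary-statistic fixtures reproduce. A pooled-variance one-way ANOVA F
(the square of the pooled t) is provided alongside Welch because published
group tables of this design report the pooled form; recomputing those
tables from printed means/SDs is one of the package's validation fixtures.
Segregation differences between groups are tested per network by ANCOVA
(partial F of the group factor) adjusting for age, sex, head motion, and
the questionnaire-to-scan delay.

Associations between segregation and pain variables use partial correlation
by the residual method (both variables regressed on the covariates, Pearson
correlation of the residuals, t reference with `n − k − 2` df). Regression
models report standardized betas (all variables z-scored) with variance
inflation factors `1/(1 − R²_j)`; VIF above 10 is flagged.

Moderation fits `outcome ~ focal + moderator + focal×moderator +
covariates` with focal and moderator mean-centered before the product (the
PROCESS convention; a flag disables it — the interaction coefficient is
unaffected either way). The interaction's confidence interval is a
case-resampling percentile bootstrap, 5,000 resamples by default, fully
determined by the supplied seed; BCa was deliberately not used so the
interval matches the convention of the moderation-macro literature this
analysis follows. The Johnson–Neyman region solves `(b1 + b3·w)² =
t²_crit·Var(b1 + b3·w)` — a quadratic in the moderator `w` — and reports
real roots inside the observed moderator range plus the significance and
sign of each segment; every root is cross-checked in the test suite against
a dense grid scan of conditional-effect t tests. No multiple-comparison
correction is applied by default, matching the analysis this package
operationalizes; `stats::p.adjust` composes naturally with the tidy outputs
when correction is wanted.

## The synthetic cohort: what it emulates and what it does not

Because the motivating cohort's raw data are not deposited, validation
rests on a generator with known ground truth.

**Connectivity.** Each subject's time series is multivariate Gaussian with
a block correlation structure: `r_within` (default 0.5, jittered per
subject with SD 0.04 to create true between-subject variance) inside each
network, `r_between` (default 0.1) elsewhere. The population segregation of
this design is analytic, `(atanh r_w − atanh r_b)/atanh r_w ≈ 0.817` at the
defaults, which gives every estimator stage an exact target. The default
acquisition matches the emulated protocol: 740 analyzed volumes (750 minus
10 dummy scans) at TR = 0.8 s, 100 nodes, 7 networks.

**Motion.** Frame-to-frame increments follow a stationary AR(1) process
(coefficient 0.3) scaled so the expected mean FD equals the per-group
targets (0.163 mm no-pain, 0.179 mm pain); rotations and translations
contribute equally. Only the FD consequences matter downstream, so no
richer generative model is attempted.

**Phenotypes.** Demographics and questionnaire totals are drawn from the
reference group summaries. Instruments are generated at the *item* level so
the scoring layer is genuinely exercised: PCS items are integer 0–4
compositions distributed uniformly subject to the target subscale sums;
BPI interference items are continuous 0–10 values with exactly the target
subdimension mean. The longitudinal pain-experience change of each pain
subject equals a planted standardized linear model — helplessness 0.325,
DMN segregation 0.193, DAN segregation −0.215, baseline intensity −0.428,
affective interference −0.678, activity interference 0.255 — plus a
helplessness×DMN interaction and Gaussian noise (SD 1). The interaction
default is 0.4, a package choice: the motivating cohort reports its
moderation interval on raw scales, which does not transfer to the
generator's standardized model. The T2 intensity and affective ratings are
shifted by the planted change plus a cancelling split drawn inside the
interval that keeps both ratings in bounds, so the composite change is
exact whenever that interval is nonempty; infeasible cases are clipped and
reported via the `clip_rate` attribute (warning above 20%). The pain-group
prevalence is 133/347.

Known infidelities, hence what passing tests do *not* show about real
data: BOLD autocorrelation, physiological noise, and spatial structure are
absent (samples are temporally iid); BPI items are continuous where the
real instrument is an integer rating scale; the planted betas come from a
many-covariate model but are used in a reduced model, so the generator
emulates effect sizes, not the published fit; and clipping at instrument
bounds attenuates large planted effects, which is reported rather than
hidden.

## Numerical and design choices

- Problem sizes in the test suite (e.g. 50 subjects at 740 volumes for the
  analytic-recovery check; 100 bootstrap-coverage replicates at n = 300
  with 5,000 resamples) were chosen as the smallest sizes at which the
  binomial/sampling tolerances quoted in the tests are meaningful.
- All simulation and bootstrap code takes explicit integer seeds and
  restores the caller's RNG state; identical config + seed reproduce every
  artifact bit-for-bit.
- Bootstrap resamples with rank-deficient designs are redrawn (count
  reported) rather than silently dropped.
- Collinear confound or covariate columns are dropped with a warning;
  exactly duplicated regressors in the standardized regression are an
  error, since a silent drop would misattribute the shared coefficient.
- Degenerate inputs are flagged, not coerced: zero-variance nodes error in
  `compute_fc()`, `W = 0` networks yield `NA` segregation with a flag, a
  constant outcome gives ANCOVA `F = 0`.
- The QoL pain-group SD is not available in the reference summaries; the
  generator assumes 7.0 and the QoL row is not used as a recomputation
  fixture.

## A worked example

```{r example, eval = FALSE}
library(painsegr)

co <- simulate_cohort(sim_config(n_subjects = 300, seed = 7),
                      generate_timeseries = FALSE)
run <- run_pipeline(pipeline_config(cohort = co, seed = 7))

tidy(run$results$regression)       # standardized betas with VIF
tidy(run$results$moderation)       # interaction with bootstrap CI
run$results$johnson_neyman         # region of significance
autoplot(run$results$johnson_neyman)
cat(make_report(run), sep = "\n")
```

Per-subject imaging runs the same way with `generate_timeseries = TRUE`
(the default), in which case segregation is estimated from the simulated
BOLD data rather than taken from the ground truth.

## Limitations

The package validates the *method*, not the published coefficients: without
the original data, the regression and moderation estimates can only be
checked for recovery of planted effects and for agreement with independent
oracles. The recomputation fixtures cover exactly those published
statistics that are functions of printed summaries (group sizes,
proportions, means, SDs); statistics requiring subject-level data are out
of reach by construction.
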