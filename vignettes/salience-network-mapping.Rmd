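---
title: "Personalized salience-network mapping and the sex-moderated violence–depression battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized salience-network mapping and the sex-moderated violence-depression battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package estimates

Adolescents exposed to interpersonal violence are at elevated risk of
depression, and the risk appears to differ by sex. One candidate mechanism is
the salience network — the large-scale cortical network that detects
behaviorally relevant stimuli. `salnet` implements, end to end, an analysis
that asks whether two individual-specific properties of that network —

* **expansion**: the proportion of all cortical vertices that are significant
  members of a person's salience network, and
* **within-network connectivity**: the mean Pearson correlation of the BOLD
  time series over all unordered pairs of member vertices —

moderate and/or transmit the association between past-year violence exposure
and depression, separately by sex.

Because subject-level data of this kind are rarely shareable, the package is
built around a synthetic cohort generator that reproduces the statistical
structure every downstream stage assumes. All stages are ordinary exported
functions; `run_pipeline()` ties them together.

# The processing model, stage by stage

## Nuisance regression (`surface_preprocess` stage)

Input is a dense vertex × time matrix (`bold_run`) with its repetition time.
A single joint least-squares projection removes:

* the 6 motion parameters and the global signal (mean over vertices), each
  expanded into raw, backward-difference derivative (leading zero), square,
  and squared derivative — 28 columns;
* a discrete-cosine high-pass basis: `floor(2 * T * TR * f_c)` unit-norm
  columns `cos(pi * j * (t + 1/2) / T)`; at the acquisition scale
  (T = 1110, TR = 0.555 s) the 0.01 Hz cutoff yields exactly 12 bases;
* one one-hot spike regressor per DVARS-flagged frame.

White-matter and CSF regressors are deliberately absent: they duplicate the
global signal. Each vertex's temporal mean is removed together with the
projection (the design carries no constant column), which guarantees that
per-vertex residual variance can never exceed input variance.

**DVARS dual cutoff.** We compute `Dvar_t = mean_v (y_v(t) - y_v(t-1))^2` and
flag a frame only when *both* a practical and a statistical criterion are
exceeded: the percent excursion over the median baseline must exceed 5%, and
the one-sided p-value from a moment-matched chi-square reference (robust
variance via the IQR) must fall below 0.05 after Bonferroni correction over
the T − 1 frame differences. Both thresholds are configurable; the dual
requirement means neither slow drifts (practically large but statistically
unsurprising) nor microscopic but "significant" fluctuations produce flags.
Flagged frames are spike-regressed rather than deleted, preserving
time-series length for the later half-split; the alternative (censoring)
changes the pseudo test-retest bookkeeping and is not offered.

## Parcel-seeded dual regression and the population prior

Stage 1 averages the cleaned time series over the vertices of each of K = 17
parcels; stage 2 regresses every vertex's time series jointly on those K
seed time courses. The coefficients are the vertex's engagement in each
network; their OLS variances are kept as vertex-wise sampling variances. A
parcel whose seed time course is identically zero is dropped (engagement 0,
infinite sampling variance); collinear seeds are an error naming the parcels.

Dual-regression engagement has a per-network scale indeterminacy (the seed
amplitude is arbitrary), so maps that enter any cross-session computation
are first rescaled to unit SD across vertices (`normalize_engagement()`);
the same rule is applied to half-session and full-session maps so prior and
data live on one scale.

**Pseudo test-retest variance decomposition.** Each contributing session is
split down the middle. With half-maps `a` and `b` per session, per vertex
and network:

* prior mean = grand mean of `(a + b) / 2`;
* half-map noise variance `w = mean((a - b)^2 / 2)`;
* between-subject variance = sample variance of `(a + b) / 2` minus `w / 2`,
  floored at zero (the floored fraction is logged in the object).

The decomposition is method-of-moments and unbiased before flooring; the
recovery test drives it with known between-subject SD 1 and half-map noise
SD 0.7 across 500 sessions.

## Empirical-Bayes individual maps and vertex inference

For each subject the raw engagement estimate is combined with the population
prior by the conjugate-normal update

    post_mean = (prior_mean / tau2 + raw / s2) / (1 / tau2 + 1 / s2)
    post_var  = 1 / (1 / tau2 + 1 / s2)

so the degree of shrinkage is set automatically by the prior variance `tau2`
and the data precision `1 / s2` — no tuning parameter. Degenerate corners
are defined explicitly: `tau2 = 0` collapses to the prior mean, infinite
`tau2` returns the raw estimate, infinite `s2` (a dropped network) falls
back on the prior.

**Posterior SE floor.** Where the posterior variance degenerates toward
zero, the reported SE is floored at 0.05 (on the unit-SD normalized map
scale). The floor encodes that the posterior can never be more certain than
the prior mean itself, which is estimated from finitely many sessions;
without it, vertices with a floored between-subject variance produce
arbitrarily large z statistics from pure estimation noise in the prior mean.

**Membership.** A vertex belongs to the salience network iff its posterior
mean is positive *and* the one-sided normal p-value of `mean / se` falls
below `alpha / V`, with `alpha = 0.01` Bonferroni-corrected across all V
vertices (V = 20484 at acquisition scale — the denominator counts all
vertices, not just the positive ones). Negative engagements are never
members. A two-sided-then-drop-negatives variant is available behind
`two_sided = TRUE`; the one-sided test is the default because the scientific
hypothesis at each vertex is directional (positive engagement). Expansion is
the member fraction; connectivity is the average pairwise correlation of
member vertices' time series, computed on the full-length cleaned session
(not the pseudo-halves) because the halves exist only to price measurement
noise. Subjects with a low-variance vertex (variance below 1e-10 after
regression, configurable) or with fewer than two member vertices at either
timepoint have no usable connectivity and are excluded from analysis, the
package's own exclusion cascade.

# The regression battery

With `Y` depression, `X1` the female indicator, `X2` the past-year violence
count, `M1` expansion and `M2` connectivity, the battery fits eight
fixed-effects equations by OLS:

1. `X2 ~ X1`
2. `Y ~ X1 + X2 + X1:X2`
3. `M1 ~ X1 + X2 + X1:X2`
4. `M2 ~ X1 + X2 + X1:X2`
5. `Y ~ X1 + M1 + X1:M1`
6. `Y ~ X1 + M2 + X1:M2`
7. `Y ~ X1 + X2 + M1 + X1:M1`
8. `Y ~ X1 + X2 + M2 + X1:M2`

each under four covariate sets: none; demographic (age, Black, White,
Hispanic, BMI percentile, puberty category, income-to-poverty ratio);
lagged (the dependent variable two years earlier); and both — 32 fits in
all, with no multiple-testing correction across the battery (the report
carries the count). All non-indicator variables are z-scored on the analysis
sample *before* interactions are formed (scale-then-multiply); indicators
are untouched. Coefficients are labelled `beta0` (intercept), `beta1` (sex),
`beta2` (violence), `beta3` (sex × violence), `beta4` (network metric),
`beta5` (sex × metric). Missing time-1 network metrics are imputed by OLS on
time-1 predictors only (complete cases, at least 10 required); time-2
columns never enter the imputation models. Mediation is intentionally
absent from the battery. Two further design notes:

* puberty category enters numerically (and is z-scored); a categorical
  coding is a one-line change in `battery_covariates()` but was not adopted
  because the category scale is ordinal with roughly even spacing;
* the lagged covariate for equation 1 is the time-1 violence count, so that
  every equation has a well-defined lagged set and the report is uniformly
  8 × 4.

Supporting decompositions: sex-stratified Pearson correlations with the
exact identity `t = r * sqrt(n - 2) / sqrt(1 - r^2)` (usable directly on
printed correlations), and a two-group one-way ANOVA recoverable from group
sizes, means and SDs alone — algebraically the square of the pooled-variance
two-sample t.

# What the synthetic cohort emulates

The generator's defaults are the study conditions the analysis assumes.

**Phenotypes** (`simulate_phenotypes()`): sex is Bernoulli(141/220);
violence is negative-binomial with sex-specific means (1.16 female, 2.95
male) and dispersion matched by method of moments to the sex-specific SDs
(2.37 and 5.05), giving size parameters of roughly 0.30 and 0.39 — the
counts are strongly overdispersed, as real past-year exposure counts are.
Depression, expansion and connectivity follow the battery's own generating
equations on the standardized coefficient scale on which estimates are
reported; the default interaction coefficient for depression is 0.337 with
a female main effect of 0.399, and connectivity carries a negative female
main effect (−0.30) — values of the magnitude the analysis is designed to
detect. Because the synthetic outcome lives on the model scale, it is
continuous and unbounded; the 0–33 questionnaire range applies to real
data only. Demographic covariates are drawn around the cohort's published
moments and have correlated time-1 variants.

**Imaging** (`simulate_bold_session()`): `y_v(t) = sum_k s_k(v) a_k(t) +`
drift + motion-coupled artifact + spikes + white noise. Network drives are
AR(1)-smoothed Gaussian noise, orthogonalized across networks and scaled to
amplitude 2 against unit noise — the signal-to-noise regime of
surface-smoothed resting data, and the level at which the Bonferroni vertex
test detects a graded network core without saturating. True engagement maps
taper linearly from the parcel core (1.0) to its boundary (0.2), because
real engagement is graded, and between-subject variation (SD 0.2) is split
half-and-half between a network-level factor — one person's network is
coherently larger or smaller — and independent vertex noise
(`shared_frac = 0.5`). The network-level component is what makes expansion
genuinely variable across individuals rather than a fixed core count.

Desk-scale defaults are V = 2000 vertices, T = 400 frames, n = 40 subjects,
two sessions each (an end-to-end run takes well under a minute); the
acquisition scale (V = 20484, T = 1110, n = 220) is reached by overriding
three config fields. The parcel atlas is index-contiguous blocks with
jittered sizes — network metrics depend only on vertex labels, so no
surface geometry is represented.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: cortical geometry and spatial smoothness
(parcels are index blocks, so no spatially structured artifact can straddle
a boundary the way real motion artifact does); hemodynamic response and
autocorrelation structure beyond AR(1) smoothing; physiological
(cardiac/respiratory) noise; any true coupling between violence exposure
and the brain maps (exposure–brain associations in the synthetic cohort are
null by construction, matching the study's empirical result but not
guaranteed by it); and real missingness mechanisms (synthetic missingness
is completely at random).

# Numerical choices and degenerate inputs

* Variance floors: between-subject variance at 0 (fraction logged);
  posterior SE at 0.05 (see above); low-variance vertex guard at 1e-10.
* The first frame has no DVARS statistic and is never flagged; constant
  runs produce no flags.
* All-zero or collinear nuisance columns are dropped with a warning rather
  than erroring, because zero motion is legal (and common in synthetic
  runs); collinear *seed time courses* in dual regression are an error
  because they make engagement unidentifiable.
* Backward differences with a leading 0 are the derivative convention.
* Splitting an odd-length run puts the extra frame in the second half.
* Determinism: every stochastic function takes a seed and restores the
  caller's RNG state; identical configs and seeds reproduce identical
  outputs bit for bit.
* Problem sizes in the test suite (Monte-Carlo replicate counts of 600–1000
  at n = 220, 500 sessions for the variance-estimator recovery, desk-scale
  end-to-end runs) were chosen so the full suite completes in about a
  minute while keeping Monte-Carlo error well inside the asserted 3-SE
  bands.

# Known limitations

* The empirical-Bayes model is vertex-wise: no spatial smoothing or
  between-vertex borrowing, which full spatial Bayesian machinery would
  add. The posterior SE treats the prior as known, which is optimistic for
  small session counts (the SE floor is the guard).
* The prior's between-subject variance absorbs session-level artifact
  variance that survives nuisance regression (it is really a
  between-session variance); with two or more sessions per subject a
  subject-level decomposition would separate the two.
* Expansion is a count divided by V, so at desk scale it moves in steps of
  1/V; analyses that difference expansion across small groups should use
  the acquisition-scale V.
* The published participant-flow arithmetic (257 minus the listed
  exclusions, and the two counts of incomplete baseline data) does not
  reconcile to a single n; the pipeline does not attempt to reproduce that
  cascade and instead logs its own exclusions in the provenance record.
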