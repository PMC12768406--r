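---
title: "Models and design choices in ovichoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ovichoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovichoice)
```

## The scientific setting

A two-alternative forced-choice oviposition assay places a cohort of mated
female moths in an arena split into two sides, one carrying an acoustic
playback of the ultrasonic clicks a drought-stressed plant emits, and scores
each night's egg clusters by side. Each cluster is one oviposition decision,
so the cluster count — not the egg count — is the response of record. Two
companion designs sharpen the question: a 150 cm gradient arena in which a
single moth chooses a continuous position between a clicking speaker
(−75 cm) and a silent resistor (+75 cm) with a feeder at 0, and continuous
infrared tracking of the moths' movement at 12-s resolution during the
decision night. A deafening experiment (tympanal puncture) validates that
the response is auditory.

This package implements the full statistical chain for these designs, and a
simulator for each data type so the chain can be validated end to end
against known truths.

## The cluster-count model

One arena-night yields counts on the treatment and the control side. The
inference model is Poisson with log link:

$$\log \lambda = \beta_0 + \beta_1\,\mathrm{treatment} +
  \beta_2\,\mathrm{females} + u_{\mathrm{arena}} + u_{\mathrm{rep}} +
  u_{\mathrm{night}}$$

with independent normal random intercepts. Nights are nested in repetitions
(a repetition is one cohort of moths observed about three consecutive
nights), which the night grouping encodes as `repetition × night`. The
number of females enters as a fixed covariate, not an offset: cohort sizes
vary by a single moth or two, and the covariate (centred internally for
conditioning) lets the data decide its weight rather than forcing
proportionality. Estimation is Laplace-approximate maximum likelihood via
`lme4::glmer`; a boundary fit with a random-effect SD of zero is reported as
converged with `sigma_u = 0`, which at these sample sizes is common and
correct. With `glmm_spec(character(0))` the model is a plain Poisson GLM,
and for the balanced two-group design its treatment estimate is the
closed-form `log(sum_treatment / sum_control)` — one of the package's
standing cross-checks.

Arena-nights with zero clusters on both sides carry no choice information
under this model and are excluded exactly once, in the analysis stage, with
the count reported. The simulator *generates* such nights and flags them,
so the exclusion stays auditable.

## The Bayesian choice posterior

Treating each cluster as a Bernoulli-style decision coded 0/1, the package
fits a Gaussian model *literally on the binary codes*: the stated prior
N(0.5, 0.1²) lives on the outcome scale, so the likelihood must too. The
model is

$$y_i = \mu + b_{g(i)} + \varepsilon_i,\qquad
  \mu \sim N(0.5, 0.1^2),\quad b_g \sim N(0, \tau^2),\quad
  \varepsilon_i \sim N(0, \sigma^2),$$

with the grouping $g$ taken as the experiment's female count — the reading
adopted for the ambiguous instruction to incorporate the number of females
as a random effect. A random *slope* in the female count would be the main
alternative; with the handful of distinct cohort sizes that occur, the
grouping-factor reading is the identifiable one. Both SDs get half-normal(0, 1)
priors. $\mu$ and the $b_g$ have exact conjugate normal full conditionals
and are Gibbs-updated; the half-normal scale priors are *not* conditionally
conjugate, so $\sigma$ and $\tau$ are updated by tuning-free slice sampling
within the Gibbs sweep. With the random effect disabled and $\sigma$ fixed,
the sampler draws iid from the closed-form conjugate posterior, which the
test suite exploits as an exact oracle. The default draw count is 16,000
after a 1,000-sweep burn-in; an empty choice set returns the prior, by
construction rather than by error.

The binary-outcome Gaussian likelihood is a deliberate simplification: it
buys conjugacy and an interpretable probability-scale posterior at the cost
of positive density outside [0, 1]. For the shrinkage summaries it is used
for, this is immaterial; a beta-binomial variant is intentionally out of
scope.

## The gradient permutation test

Under acoustic indifference, the egg-position distribution in the gradient
arena is mirror-symmetric about the centre, because the speaker and the
resistor ends are exchangeable (and are in fact physically swapped between
nights; the reader normalises all positions so the speaker is at −75). The
null is therefore generated by flipping the sign of each analysis unit's
position with probability ½ — the feeder at 0 is a fixed point.

Two p-value constructions are provided:

* **pooled** (default): all shuffle replicates are pooled into one large
  null sample and compared with the observed sample by the asymptotic
  two-sample Kolmogorov–Smirnov test. This is the headline construction in
  gradient playback studies, and with thousands of pooled null points its
  p-values hit the `2.2e-16` floor on strongly asymmetric data. Because the
  null sample is built from the observed data, however, the two samples are
  dependent, and measurement under mirror-symmetric truth shows the
  construction is strongly *conservative* (rejection well below nominal).
* **permutation**: the observed D is computed against the balanced
  symmetrised reference $\{|x_i|\} \cup \{-|x_i|\}$, which is invariant to
  sign flips; each shuffle replicate supplies one null D; the Monte-Carlo
  p-value $(1 + \#\{D_r \ge D_{obs}\})/(R+1)$ is exactly calibrated under
  the mirror null. The test suite verifies calibration (rejection inside
  the binomial 95% band at the 5% level over 500 symmetric replicates) and
  power above 95% on bimodal data.

Analysis units can be clusters or individual eggs (each cluster replicated
by its egg count); both are reported in the pipeline since the
cluster-vs-egg choice is a genuine degree of freedom. The first-night
restriction — keeping each female's first night with laying — removes
between-night dependence. D itself uses the right-continuous ECDF
convention for ties, and is cross-checked in the tests against exhaustive
enumeration over all sample pairs of size ≤ 6 on a 5-point grid.

Kernel densities of positions (`spatial_density`) use a Gaussian kernel on
a fixed grid over the arena and are renormalised so the curve integrates to
one over [−75, 75]; truncation at the walls shifts a wall-hugging peak
inward by roughly one bandwidth, which the tests account for.

## Trajectory analysis

Tracks are labelled by the sign of $x$ relative to the midline, mapped onto
the playback side. Samples exactly on the midline inherit the previous
label; leading midline samples are neutral and excluded from bins. Crossing
counts are adjacent label changes. Occupancy is summarised in 30-min bins;
a partial final bin keeps its true sample count, and the bin table satisfies
the exact identity `sum(prop × n) = total playback-side samples`.

The published description of the time-trend model — a logistic model of the
*accumulated* time on the playback side — is internally inconsistent
(continuous response, logistic link). The package's primary trend model
therefore uses the per-sample binary occupancy as the logistic response,
with time in hours as the fixed effect and random intercepts for trial and
moth; the accumulated-time reading is served by a secondary weighted linear
trend on the per-bin proportions, returned alongside. Consecutive 12-s
samples are autocorrelated, so model-based Wald standard errors understate
sampling variability; slope *estimates* remain consistent for the
stationary log-odds drift (the recovery test checks the mean estimate over
100 replicates against the generative slope), but per-replicate interval
coverage is not asserted, and published p-values from such models share
this caveat.

## What the simulators emulate — and what they do not

The generators' defaults are the study conditions the analyses assume:

* **Two-choice counts**: control baseline `beta0 = log(0.40)` clusters per
  side-night and treatment log rate ratio `beta1 = 1.0`, the combined
  playback-versus-silence condition (treatment ≈ 1.08 vs control ≈ 0.40
  clusters per laying night); 15 repetitions × 3 nights ≈ 45 arena-nights,
  matching the condition's observation count; up to 4 arenas; 10.9 females
  per arena with a small (SD 0.5) jitter, since the observed cohort spread
  was tiny. Random-intercept SDs default to 0.3/0.2/0.2 (arena/repetition/
  night) — moderate heterogeneity on the log scale, not stated by the
  design and chosen once as realistic.
* **Gradient positions**: equal-weight normal mixture at the speaker and
  feeder (`w_speaker = 0.5`, SDs 8 cm), truncated to the arena *by
  rejection* — clipping would pile probability atoms on the walls that the
  K-S stage would misread as structure. Eggs per cluster are 1 + negative
  binomial with mean 67 and size 0.26, putting the cluster-size SD near 134
  — the observed 68 ± 134 overdispersion; the distributional form is a
  stand-in, as only the first two moments are known.
* **Tracks**: a two-state Markov chain whose stationary playback log-odds
  rise linearly at `bias_slope = 5e-5`/s (occupancy drifting 0.5 → ~0.75
  over 6 h), with per-moth switching propensity lognormal around
  `switch_prob0 = 0.00256` (log-SD 1.0). These values were calibrated
  analytically so the per-night crossing count has mean 4.2 and SD ≈ 5.7,
  the observed regime in which a third of moths never cross while a few
  cross dozens of times.
* **Deafening**: Bernoulli responders per moth, defaults 25 intact at
  p = 0.2 versus 20 deafened at p = 0 — the regime of the observed 5/25 vs
  0/20 table.

Real nights differ from the Poisson mirror in one visible way: moths often
lay nothing at all in plant-free arenas, more often than the fitted Poisson
rates predict. The simulator reproduces the *model's* zero-night rate, not
the behavioural one, so passing tests validate the inferential machinery
rather than any claim that the generative model captures moth motivation.
Identity of tracked moths is taken as given; re-identification from
proximity is upstream of this package.

## Seeds and reproducibility

One master seed drives the pipeline; each stage consumes a child seed
derived by a fixed polynomial hash of the stream name
(`derive_stream_seed`), so adding a stage never perturbs the draws of
another, and all derived seeds stay below 2³¹. Identical seed and
configuration give bit-identical tables; every pipeline report embeds the
configuration, seed and schema version needed to rerun it.

## Problem sizes used in validation

The test suite runs the heavy checks at sizes chosen to make Monte-Carlo
error small relative to the tolerances: 200 simulate-and-fit experiments
for treatment-effect recovery (mean within 10% of truth, Wald coverage in
[0.90, 0.98]); 500 symmetric and 200 bimodal replicates for the permutation
calibration and power; 100 replicates for trend-slope recovery; 4,000–
10,000 draws for moment checks of the generators. `scripts/acceptance.R`
reruns the headline quantities at the same study-scale configurations under
a user-supplied seed.

## Known limitations

* The Gaussian-on-binary choice model is a pragmatic reading of an
  ambiguous published description; its posterior is a shrinkage summary,
  not a calibrated probability model for extreme data.
* The pooled-null K-S p-value is conservative under the null (by
  construction, as measured); use `method = "permutation"` when calibrated
  error rates matter.
* Trend-model standard errors ignore within-track autocorrelation.
* The two-proportion laying comparison is implemented as Fisher's exact
  test and labelled as such, since the exact construction of the published
  "binomial test" between experiments is not recoverable from its
  description.
* Table 1-style session effects are supported only as grouping labels; no
  model selection across random-effect structures is attempted.
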