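---
title: "Normative modelling with npmap: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling with npmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmap)
```

## The model

npmap charts variation across a reference cohort instead of contrasting
groups. For each response location \(j\) (a voxel, vertex, region, or any
mass-univariate target) it fits an independent Gaussian process regression

\[ y_{ij} = f_j(\mathbf{x}_i) + \epsilon_{ij}, \qquad
   \epsilon_{ij} \sim \mathcal{N}(0, \sigma_{nj}^2), \]

linking the clinical covariates \(\mathbf{x}_i\) of subject \(i\) to the
biological response \(y_{ij}\). The GP prior over \(f_j\) uses a
squared-exponential kernel with one length-scale per covariate (automatic
relevance determination), optionally summed with a linear kernel. The
length-scales express covariate relevance — an irrelevant covariate is
down-weighted by a large fitted length-scale — and the signal variance sets
the scale of the function. Hyperparameters are estimated per location by
type-II maximum likelihood.

A held-out prediction for subject \(i\) yields an expected response
\(\hat y_{ij}\) and a function variance \(\sigma_{ij}^2\) that grows away
from the training data, so predictive confidence degrades coherently when
extrapolating. The deviation of the observed response from the normative
expectation is the Z-score

\[ z_{ij} = \frac{y_{ij} - \hat y_{ij}}
                {\sqrt{\sigma_{ij}^2 + \sigma_{nj}^2}}, \]

combining the prediction error, the predictive uncertainty of the test
point, and the noise variance learned from the normative cohort. The
subjects-by-locations matrix of these scores is the normative probability
map (NPM). Because \(\sigma_{ij}^2\) (per-subject, noise-free posterior
variance) and \(\sigma_{nj}^2\) (per-location noise) enter the denominator
as an explicit sum, the two are kept strictly separate in the code
(`cvVar` and `cvNoise` assays of a `NormativeFit`).

Centiles of predictive confidence double as cohort centiles: the `c`-th
centile surface is \(\hat y + \Phi^{-1}(c)\sqrt{\sigma_{ij}^2 +
\sigma_{nj}^2}\) (`centileSurface()`), non-crossing by construction — the
growth-chart reading of the normative model.

## Cross-validation and leakage

Z-scores are only meaningful if a subject's own response never informs its
prediction. `estimateNormative()` therefore uses grouped k-fold
cross-validation (default `k = 10`): all members of a family share a fold
(`groupedKFold()`), since within-family correlation would otherwise leak
into held-out predictions through relatives. Responses are centred and
covariates standardised *within each training fold only*. The engine's
tests verify a strong form of the leakage guard: corrupting the responses
of a held-out fold leaves that fold's predictions bit-identical.

Model quality per location is summarised by the standardized mean squared
error (SMSE): cross-validated MSE divided by the variance of the test
targets, averaged across folds. SMSE < 1 means the covariates carry
predictive signal; SMSE ≈ 1 is a pure-noise location.

## From maps to subject-level inference

A cohort-sized NPM is too rich for subject-level decisions, so each
subject's map is reduced by a block-maxima device: the subject is the
block, and their summary is a robust (90% trimmed) mean of the top 1% of
their Z values (`summarizeDeviance()`). Three modes are computed — positive
(top tail of Z), negative (top tail of −Z, reported on the Z scale, i.e.
with its sign restored), and absolute (top tail of |Z|). The trimming
convention: with `m = ceiling(tailFraction * nLocations)` tail cells,
`floor(trimTotal * m / 2)` cells are removed from each end of the sorted
tail block, always retaining at least one value. The alternative reading of
a "90% trimmed mean" (keep 90%) is one configuration change
(`trimTotal = 0.1`). Note that for a subject whose whole map is positive,
the negative deviance is a positive number — the summary reports the Z
values of the lower tail, wherever that tail sits.

Deviance summaries across the cohort are then fitted with an extreme value
distribution (`fitEVD()`): generalized extreme value (GEV) by default, as
block-maxima theory motivates, with a Gumbel fallback for small samples
(n < 30) or non-convergence. Negative-mode deviances are flipped to
magnitudes before fitting, since the EVD models maxima. A subject's
deviance converts to an upper-tail probability (`evdPValue()`); `p <
alpha` is an outlier call. The EVD is fitted to the full cohort including
the subject under test, matching cohort-level usage; fitting is per mode,
since positive, negative and absolute deviations carry different
information. Because the EVD is fitted to the same cohort it scores, the
null outlier rate self-calibrates near `alpha` even when the Z variance is
mildly inflated.

Deviating locations within a subject are localised by converting Z-scores
to two-sided normal p-values and applying Benjamini–Hochberg FDR control
per subject (`fdrMap()`). Two-sided testing is deliberate: both over- and
under-responses relative to the norm are phenomena of interest.

Finally, `tailCorrelation()` relates deviance to symptoms among the most
deviating subjects: subjects are ranked by deviance magnitude and the
Pearson correlation between deviance and symptom score is computed within
the top 1, 5, 10, 15 and 20% of the cohort (subset size
`ceiling(fraction * n)`). For the negative mode both the ranking and the
correlation use the magnitude (−deviance), so symptoms that grow with
deviation yield positive correlations. Pearson (not rank) correlation is
used because the quantities of interest are linear trends in small tails
where rank correlations are degenerate.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `k` | 10 | cross-validation folds |
| `tailFraction` | 0.01 | fraction of locations in the tail block |
| `trimTotal` | 0.90 | fraction of the tail block trimmed before averaging |
| `family` | `"gev"` | EVD family (`"gumbel"` forced for n < 30) |
| `alpha` | 0.05 | outlier call threshold on the EVD tail probability |
| `q` | 0.05 | FDR level for per-subject deviation maps |
| `topFractions` | 1–20% | cohort fractions for tail correlations |
| `restarts` | 5 (`fitGP`), 2 (engine) | optimiser restarts per location |

## Numerical choices

* **Standardisation.** Covariates are standardised before kernel
  evaluation and responses centred per training fold; the constants are
  stored in each model and undone at prediction. This makes length-scales
  comparable across covariates and the optimiser scale-free.
* **Initialisation.** Length-scales start at 1 (one covariate SD), signal
  variance at var(y), noise variance at 0.1 var(y). A second deterministic
  start assumes a noise-dominated location (signal 0.1 var(y), noise
  0.9 var(y)); without it, type-II ML can stall in a signal-absorbing local
  optimum at pure-noise locations, deflating \(\sigma_{nj}^2\) and
  inflating the Z-scores. Additional restarts perturb the first start with
  seeded log-normal noise (sd 0.5 in log space); the best marginal
  likelihood wins, so fits are deterministic given the seed.
* **Bounds.** Length-scales are bounded below at 0.1 covariate SD:
  normative trends are smooth, and shorter scales only let the optimiser
  memorise chance agreement among near-duplicate covariate values. The
  noise variance is floored at 1% of the response variance: biological
  responses are never noise-free, and without the floor small training
  folds can reach interpolating optima whose near-zero denominators
  explode held-out Z-scores.
* **Stability.** Covariance factorisations use a Cholesky with a jitter
  ladder from 1e-10 to 1e-4 (decade steps); exhausting the ladder is an
  error, never silent. Predictions change by far less than 1e-6 across one
  ladder step.
* **EVD fitting.** Moment-based initial values (Gumbel moments; a fixed
  grid of GEV shape starts at −0.1, ~0, 0.1) make the fit a deterministic
  function of the data. GEV failure falls back to Gumbel with a warning;
  Gumbel failure is an error.
* **Failed locations** are flagged and excluded from the NPM and the
  deviance tails rather than imputed — imputation would manufacture
  deviations. A run with more than 5% failed locations aborts.

## The synthetic cohort generator

`simulateCohort()` generates cohorts with exactly the structure the method
assumes, so every stage is testable without any external data:

* **Covariates:** two correlated Beta-distributed scores in [0, 1]
  mimicking delay-discounting AUC at a small and a large reward (skewed
  low and near-symmetric respectively, rank-correlated ≈ 0.5).
* **Signal:** a random 30% of locations carry a smooth low-order
  polynomial surface of the covariates (unit SD by default) plus unit-SD
  Gaussian noise; the rest are pure noise.
* **Families:** sizes 1–3; members share a per-location random intercept
  (SD 0.3), so grouped cross-validation demonstrably matters.
* **Outliers:** a fraction (default 5%) of subjects receive additive
  shifts at a sparse idiosyncratic location set (default 1% of locations),
  sized in SD units of that location's total normative variation (default
  4). An optional heavy-tailed (Pareto, shape 1.5) magnitude spread keeps
  the most extreme subjects mutually distinguishable — with constant
  magnitudes the top tail would have no between-subject ordering and tail
  correlations would be inestimable by construction, and lighter-tailed
  spreads let the top order statistics bunch together too often.
* **Symptoms:** a Gamma baseline (mean ≈ 2.4, range-like 0–14) plus one of
  two mechanisms. *Extreme-of-normal* ties symptoms to the subject's
  position along the covariate principal axis — severe but normatively
  well-fitted subjects. *Deviance-linked* gives outlier subjects a high
  baseline shifted by their injected magnitude with small noise — for
  these subjects the abnormality mechanism dominates the symptom, which is
  the regime in which a five-subject tail can exhibit a correlation near
  0.9 at all. *Mixture* applies the first mechanism to non-outliers and
  the second to outliers.

What the generator does **not** emulate: spatial correlation between
locations, non-Gaussian or heteroscedastic noise, covariate measurement
error, longitudinal structure, and artifact processes such as head motion.
Passing tests on these cohorts therefore demonstrate the statistical
machinery under the model's own assumptions, not robustness to the full
complexity of real imaging data.

## Problem sizes used by the test suite

GP estimation is exact (dense Cholesky), so the package's automated checks
run on deliberately desk-scale cohorts, chosen to preserve the *structure*
of each statistic rather than the raw data volume:

* Null-calibration checks pool 150 subjects over 30 locations across a few
  seeds — the pooled Z moments are estimated to well under the width of
  their acceptance band at that size.
* Outlier-calibration and power checks use 120 subjects over 400
  locations with 20-cell tail blocks (20 planted locations, 5% analysis
  tail). The tail-block size, not the cohort size, drives the power of the
  trimmed-tail statistic, so the block is kept at full scale while the
  null location count shrinks.
* The qualitative tail-correlation reproduction uses 520 subjects — the
  smallest cohort whose top 1% contains six subjects, at which a tight
  deviance-symptom coupling is statistically detectable — over 80
  locations with two folds and 8-cell tail blocks (10% analysis tail).
  At scale, a 1% tail of tens of thousands of locations spans hundreds of
  cells and the deviance summary is nearly noise-free; a desk cohort's 1%
  tail of one or two cells would add estimation noise the full-scale
  statistic does not have, so the block size is scaled up with the
  location count scaled down.

Each size is stated in the corresponding test. Larger cohorts sharpen
every check but change nothing structurally; the fitting cost per location
grows cubically in subjects.

## Known limitations

* Type-II ML point estimates ignore hyperparameter uncertainty; predictive
  variances are slightly anti-conservative at small n (pooled Z variance
  ~5% above 1 at 120 training subjects, shrinking with n). Full Bayesian
  integration over hyperparameters is out of scope.
* Exact GP solves scale as O(n³) per location; cohorts beyond a few
  thousand subjects need sparse approximations, which are out of scope.
* Locations are modelled independently; no spatial smoothing or shared
  hyperparameters across locations.
* The EVD is an asymptotic law applied to finite trimmed-tail summaries;
  with very few locations the block maxima are far from the limit and the
  Gumbel/GEV calibration degrades.

## A worked desk-scale example

```{r example, eval = FALSE}
sim <- simulateCohort(cohortSpec(nSubjects = 100, nLocations = 300,
                                 outlierFraction = 0.05,
                                 outlierSign = "negative",
                                 symptomModel = "deviance-linked",
                                 outlierMagnitudeSpread = 2, seed = 7))
res <- runNormativePipeline(sim$cohort, k = 5, seed = 7,
                            topFractions = c(0.05, 0.1, 0.2))
res$fit                      # SMSE, pooled Z moments
head(res$inference)          # per-subject deviances, EVD p, outlier calls
res$tailCorrelations         # r, p, n per mode and fraction
```
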