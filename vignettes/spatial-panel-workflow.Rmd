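---
title: "Methods: spatiotemporal analysis of regional attention panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of regional attention panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatpanel)
```

This vignette documents the statistical models behind `spatpanel`, the
choices made where the methodology was genuinely open, and what the
package's synthetic-data experiments do and do not establish about real
data.

## The setting

The package targets balanced region-by-year panels of an attention or
burden index — the motivating case is a per-capita web search-volume
index (a daily-average search index divided by year-end population)
observed for 31 provinces over 8 years, together with monthly
within-year series and a handful of demographic/economic covariates
(sex ratio, dependency ratio, urbanization rate, education share, log
per-capita gross regional product; the log is taken to tame
heteroscedasticity). Three questions structure the workflow: seasonal
concentration in time, spatial clustering across regions, and covariate
effects that may spill over between neighbouring regions.

## Spatial weights

Adjacency follows the rook rule: two regions are neighbours if and only
if they share a boundary segment of positive length; point (corner)
contact does not count. `build_rook_from_polygons()` enforces this with
a coordinate tolerance of `1e-9` when deriving adjacency from polygons;
`build_rook_from_edges()` takes a curated edge list directly. Island
regions have no land border and are patched by an explicit pair list
(`patch_islands()`); the packaged China fixture links Hainan to its
geographically closest province, Guangdong. The pairing is deliberately
explicit rather than automatic — `suggest_island_patches()` computes
centroid-distance candidates, but the analyst confirms them — because
island assignments are substantive modelling decisions. The packaged
31-province edge list was reconstructed from public provincial
geography and is a convenience fixture, not an official boundary
product.

All Moran and panel computations use the row-standardized matrix `W`
(each row of the binary contiguity matrix divided by its row sum), so
the spatial lag `W x` is a neighbour average. Row standardization is
the convention assumed by the closed-form total effect
`beta / (1 - rho)` and by the interpretation of `rho` as a fraction of
the neighbour average; binary weights remain available behind a flag
for the Moran statistics.

## Seasonal concentration

For a year with monthly shares `r_1..r_12`, the package defines

* dispersion `R = sqrt(sum_i (r_i - 1/12)^2)`, the Euclidean deviation
  from a uniform calendar, and
* concentration `M = R / sqrt(11/12)`.

The normalization anchors the two extremes: `M = 0` exactly at the
uniform distribution and `M = 1` exactly when all annual volume falls
in a single month (the all-in-one-month share vector has
`R = sqrt(11/12)`). `M` is scale-invariant (it sees only shares) and
lies in `[0, 1]` for every valid input. The conventional reading keeps
a threshold at 0.3: below it a year is labelled "uniform". The
threshold is configurable; 0.3 is the default because it is the
customary cut in the concentration-ratio literature. Years with missing
months are excluded from the summary with a warning — imputing seasonal
structure would beg the very question the statistic asks. The exact
algebraic form of published concentration ratios varies between
sources; `concentration()` isolates the definition in one function so
an alternative form can be swapped in without touching the rest of the
pipeline.

## Moran statistics and inference

Global Moran's *I* uses the standard cross-product form with
`E[I] = -1/(n-1)` under the null. Three inference modes are available:

* `analytic_randomization` (default): the permutation-moment variance,
  which conditions on the observed attribute values;
* `analytic_normality`: the iid-normal variance;
* `permutation`: a pseudo p-value `(1 + exceedances)/(1 + n_perm)` with
  999 permutations by default, two-sided by folding around `E[I]`.

Analytic and permutation p-values are reported side by side because
desktop GIS tools differ in which they print, and the two can disagree
noticeably at n = 31. A seed is required whenever permutations run;
nothing in the package draws random numbers without one.

Local Moran's `I_i` uses conditional permutation (hold region i's
value, permute the rest into its neighbour positions). Quadrant labels
come from the signs of the centred value and its spatial lag; a region
whose value equals the mean exactly (`z_i = 0`) gets `I_i = 0`, the
lag sign decides the neighbour axis, the own axis defaults to "L", and
the case is flagged — it has probability zero under continuous data
but must be deterministic when it happens. Significance defaults to
0.05 per unit with no multiple-testing correction, matching common
LISA practice; Bonferroni/FDR corrections are available through
`classify_clusters(p_adjust =)`. Non-significant units are never
dropped from the result structure — only the reporting view filters
them. The pipeline-level decision threshold is 0.1 two-sided, the
convention the cascade uses for every test; both levels are
configurable.

## Spatial panel models

The estimators cover, for `y_t` the n-vector at time t:

* SAR: `y_t = rho W y_t + X_t beta + effects + eps_t`
* SEM: `y_t = X_t beta + effects + u_t`, `u_t = lambda W u_t + eps_t`
* SDM: `y_t = rho W y_t + X_t beta + W X_t theta + effects + eps_t`

SDM nests both: `theta = 0` gives SAR, the common-factor restriction
`theta = -rho beta` gives SEM.

Estimation is concentrated ML: slopes and the error variance are
profiled out, leaving a scalar criterion in `rho` (or `lambda`)
maximized on the eigenvalue-bounded interval
`(1/omega_min, 1/omega_max)`, shrunk by `1e-6` at each end. A 50-point
coarse grid brackets the optimum before `optimize()` refines it to
`1e-9`, guarding against local optima; an estimate within `1e-4` of an
interval end raises a `boundary` flag. The log-determinant
`T log|I - rho W|` is evaluated through the eigenvalues of `W`, which
are real because the row-standardized matrix is similar to a symmetric
one.

### Fixed effects and the incidental-parameter problem

Unit effects are removed by demeaning over time, time effects by
demeaning over regions. Naively plugging demeaned data into the
NT-observation likelihood is known to bias the estimates: removing
unit means costs one effective period, and removing time means
interacts with the spatial lag because the row-stochastic `W` has a
unit eigenvalue whose log-determinant term then penalizes `rho`
spuriously. The package's own replication experiments showed the
naive likelihood leaves a clear bias in the spatial-lag-covariate
coefficients at n = 100, T = 10, while the corrected likelihood is
unbiased to Monte Carlo precision, so the correction is the default.

`fit_spatial_panel(bias_correct = TRUE)` therefore evaluates the
likelihood in the transformed space: T − 1 effective periods after unit
demeaning; an orthonormal rotation of the cross-section onto the
complement of the constant vector after time demeaning, under which `W`
reduces to an (n−1)-dimensional matrix whose spectrum is `W`'s with one
unit eigenvalue removed; and effective sample `(n-1)(T-1)` for two-way
effects. `sigma2` is ML on the effective sample (this is precisely the
incidental-parameter variance correction); `sigma2_adj` additionally
removes slope degrees of freedom and feeds the standard errors.

`bias_correct = FALSE` retains the classical NT-observation demeaned
likelihood. The cascade uses it for one purpose: the likelihood-ratio
comparison of effects specifications (two-way vs space-only, df = T;
two-way vs time-only, df = n), where the three models must be evaluated
on identical data for the statistics to be exactly nested and
non-negative. Transformed likelihoods live on different effective
samples and are not comparable across effects specifications.

Standard errors come from the analytic information matrix over
`(slopes, rho, sigma2)`, using the trace identities of
`G = W (I - rho W)^{-1}` on the transformed space.

### Random effects and the Hausman contrast

`effects = "random"` (SAR/SDM) places a normal random intercept on
units and estimates by full ML, profiling slopes and variance while
jointly maximizing over `rho` and the quasi-demeaning weight
`phi = 1 - sigma_eps / sqrt(sigma_eps^2 + T sigma_mu^2)` with a 12x12
coarse grid plus L-BFGS-B refinement. Its covariance matrix is a
numerical Hessian of the full likelihood (the quasi-demeaned model has
no convenient closed information matrix once `phi` is free). SEM random
effects are not implemented; when the cascade's selected model is SEM,
the fixed-versus-random contrast runs on the nested SAR specification
and says so in the trace.

`hausman_test()` contrasts the slope vector of the fixed-effects fit
with the random-effects one, excluding the spatial coefficient. The
contrast variance uses the conditional GLS-form slope covariances
`sigma2 (Z'Z)^{-1}` of each estimator, as in the classical panel
construction: the quasi-demeaned moment matrix dominates the within
moment matrix, which keeps `V_FE - V_RE` positive definite where the
difference of full ML covariances is routinely indefinite (its
negative eigenspace can swallow exactly the contrast direction,
destroying power). Should the difference still fail positive
definiteness, the statistic falls back to a pseudo-inverse on the
positive eigenspace with df equal to its rank, and flags it.

### The test battery and the selection cascade

`lm_spatial_tests()` computes the pooled-panel Lagrange-multiplier
statistics on the within-OLS residuals — LM-lag, LM-error and their
robust variants, each referred to chi-square(1) — using
`T_W = tr(W'W + WW)` and the standard `J` term built from `W X b`.
`wald_reduction_tests()` tests `theta = 0` (SDM to SAR) and the
delta-method common-factor restriction `theta + rho beta = 0` (SDM to
SEM), both chi-square(k). `lr_test()` compares nested fits with a hard
error if the "full" likelihood falls below the restricted one by more
than `1e-6` — a symptom of non-nesting or optimizer failure that should
never be silently clamped.

`run_selection_cascade()` executes the stages in the conventional
order: LM battery (any spatial effect at all?); SDM fit; Wald and LR
reduction tests — a reduction is accepted only when *both* its Wald and
LR tests fail to reject, since either rejection is evidence the SDM
terms are real; Hausman (a keep-H0 result returns the random-effects
fit); and finally the two effects LR tests, keeping two-way effects
only when both reject, falling back to the one-way specification that
the data support. Every decision is recorded in a trace whose rows
reproduce exactly what manual stage-by-stage invocation yields. All
decisions default to the 0.1 two-sided level.

### Effect decomposition

For SAR/SDM fits, the impact of covariate k runs through
`S_k(W) = (I - rho W)^{-1} (I beta_k + W theta_k)`: the direct effect
is the mean diagonal of `S_k`, the total effect the mean row sum, and
the indirect effect their difference, so `total = direct + indirect`
holds identically. Two anchors pin the implementation: at `rho = 0`
direct equals `beta_k` and indirect equals `theta_k` exactly, and for
SAR with row-standardized weights the total is `beta_k / (1 - rho)`.
Uncertainty comes from 1000 seeded draws of `(slopes, rho)` from the
fit's normal approximation, recomputing the decomposition per draw;
the table reports the draw standard deviation, percentile confidence
limits, and a normal-approximation p-value from the draw mean and
standard deviation. A drawn `rho` that lands at or beyond the
singularity of the multiplier is pulled just inside the admissible
interval.

`vif()` closes the regression diagnostics: `1/(1 - R^2)` per covariate
from the auxiliary regressions, infinite values with a named flag under
exact collinearity, and the conventional alarm at 10.

## The synthetic-data generator

`simulate_sdm_panel()` draws from the SDM reduced form
`y_t = (I - rho W)^{-1}(alpha + X_t beta + W X_t theta + mu + nu_t 1 +
eps_t)`. Its design choices:

* Covariates are Gaussian around unit-level means; an AR(1) option
  (`x_ar1 = 0.8`) mimics slow-moving regional covariates.
* `fe_x_corr` is the correlation between the unit effect and *each*
  covariate's unit mean — the channel that biases pooled OLS and makes
  fixed effects necessary. With k independent covariates this
  correlation cannot exceed `1/sqrt(k)`, and the constructor enforces
  that.
* Default dimensions mirror the motivating study (n = 31 on the China
  fixture, T = 8); the test suite mostly uses 10x10 lattices (n = 100,
  T = 10), where the asymptotic properties under test are cleanly
  visible.
* Demonstration parameter values echo the sign structure of the
  motivating application (positive sex-ratio/education/GRDP-type
  effects, negative urbanization-type effect, positive spatial
  dependence around 0.45) without claiming its magnitudes.

`simulate_monthly_series()` modulates a base level by a circular
(von-Mises-shaped) bump at a chosen peak month; `kappa = 0` makes
months exchangeable and the concentration `M` increases monotonically
in `kappa`. `make_blocky_attribute()` builds two-block attribute maps
for LISA recovery checks. Every generator is fully determined by its
seed and returns a truth record for recovery tests.

What the generator does *not* emulate: the heavy-tailed, bounded and
serially irregular character of real search indices, measurement
error in covariates, unbalanced panels, boundary changes, or spatially
heterogeneous coefficients. Passing the package's experiments
establishes that the estimators and tests behave correctly *when the
model is true* — calibrated sizes, advertised power, unbiased recovery
— not that the SDM is the right model for any particular real dataset.

## Problem sizes and runtime choices

The replication experiments in the test suite use: 50 random graphs
(n = 5–20) for the Moran oracle; 500 replicates of 999 permutations at
n = 31 for permutation calibration; 200 replicates at n = 100, T = 10
for SDM recovery, the LM/Wald batteries and the Hausman contrast; and
100 replicates for the end-to-end cascade. These sizes were chosen so
that Monte Carlo error is small relative to the properties being
asserted while the whole suite stays comfortably interactive.

## Known limitations

* No dynamic spatial panels, GMM/IV estimation, heteroskedasticity-
  robust inference, or spatially varying coefficients.
* SEM random effects are unavailable (the Hausman stage substitutes the
  nested SAR specification, flagged in the trace).
* The effects-specification LR tests use the classical NT-observation
  likelihoods; their null calibration is approximate, as it is in the
  applied literature they mirror.
* Rook derivation from polygons assumes exactly matching boundary
  coordinates between neighbours (tolerance `1e-9`), as produced by a
  clean topological source; sliver gaps will break adjacency.
* Unbalanced panels are rejected rather than accommodated.
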