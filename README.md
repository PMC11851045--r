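# spatpanel

Spatiotemporal analysis of regional panel data — seasonal concentration
statistics, global and local Moran's *I*, and maximum-likelihood spatial
Durbin panel models with a formal model-selection cascade.

The package is built for infodemiology-style studies in which a
region-by-year attention index (for example a per-capita web search-volume
index, PBI = search index / year-end population) is analysed in three
stages:

1. **When** does attention concentrate? Monthly shares
   `r_i = searches in month i / annual searches` are summarised by the
   dispersion `R = sqrt(sum_i (r_i - 1/12)^2)` and the concentration ratio
   `M = R / sqrt(11/12)` in `[0, 1]` (0 = uniform across months, 1 = all
   volume in one month; values below 0.3 are labelled uniform).
2. **Where** does it cluster? Rook-contiguity weight matrices (edge lists,
   polygon derivation, GAL interchange, a packaged 31-province mainland
   China fixture with the island province Hainan linked to Guangdong),
   global Moran's
   `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`
   with analytic (randomization or normality) and permutation inference,
   and local Moran's `I_i = (z_i/m2) * sum_j w_ij z_j` with HH/LL/HL/LH
   cluster labels and conditional-permutation pseudo p-values.
3. **Why**? Spatial panel econometrics: ML estimation of SAR, SEM and SDM
   models

   `y_t = rho W y_t + X_t beta + W X_t theta + mu + nu_t 1 + eps_t`

   with pooled, one-way, two-way or random effects; the Lagrange
   multiplier / Wald / likelihood-ratio / Hausman selection battery
   (`run_selection_cascade()`); and the LeSage–Pace decomposition of
   covariate impacts into direct, indirect (spillover) and total effects
   through the spatial multiplier `(I - rho W)^{-1}`.

A seed-deterministic synthetic-data module (`simulate_sdm_panel()`,
`simulate_monthly_series()`, `make_blocky_attribute()`) generates panels
with the exact statistical structure the analysis assumes, so every stage
is testable end to end without any external download.

## Worked example

```r
library(spatpanel)

w <- china_provinces()           # rook adjacency, Hainan patched, row-std.
#> <spatial_weights> n = 31  links = 69  standardized: TRUE

cfg <- sdm_dgp_config(
  n_units = 31, T_periods = 8, rho = 0.45,
  beta  = c(0.5, -0.1, -0.6, 0.4, 0.3),
  theta = c(0.2, -0.1, -0.3, -0.5, -0.1),
  fe_x_corr = 0.4, x_ar1 = 0.8,
  x_names = c("sex_ratio", "dependency", "urbanization",
              "education", "ln_grdp"))
sim <- simulate_sdm_panel(w, cfg, seed = 7)

global_moran(sim$panel$y[, 1], w, n_perm = 999, seed = 101)
#> <moran_global> I = 0.3586  E[I] = -0.0333  z = 3.252
#>   p (analytic_randomization) = 0.001148   p_perm(999) = 0.004

tr <- run_selection_cascade(sim$panel, w, alpha = 0.1)
tr
#> <selection_trace> selected: SDM with both effects
#>              test statistic df        p  decision
#>            LM-lag    29.833  1 4.71e-08 reject H0
#>          LM-error    28.588  1 8.95e-08 reject H0
#>     robust LM-lag     1.597  1 2.06e-01   keep H0
#>   robust LM-error     0.352  1 5.53e-01   keep H0
#>     Wald SDM->SAR    11.549  5 4.15e-02 reject H0
#>     Wald SDM->SEM    10.896  5 5.35e-02 reject H0
#>       LR SDM->SAR    11.873  5 3.66e-02 reject H0
#>       LR SDM->SEM    11.204  5 4.75e-02 reject H0
#>  Hausman FE vs RE    16.131 10 9.60e-02 reject H0
#>  LR both vs space    53.412  8 8.97e-09 reject H0
#>   LR both vs time   115.279 31 1.25e-11 reject H0
```

The positive first-year Moran's *I* (0.36 against a null expectation of
−1/30) says neighbouring provinces have similar outcome levels. The
cascade finds a spatial effect (LM battery), refuses to reduce the SDM to
SAR or SEM at the 0.1 level (Wald and LR), prefers fixed over random
effects (Hausman), and keeps both unit and time effects (the two LR
tests) — so a two-way fixed-effects SDM is returned. Its impacts
decompose as:

```r
eff <- decompose_effects(tr$fit, w, n_draws = 1000, seed = 202)
#> <effects_result> SDM decomposition, 1000 simulation draws
#>     covariate   effect estimate     sd   lower   upper        p
#>     sex_ratio   direct   0.6790 0.1131  0.4610  0.9008 2.29e-09
#>     sex_ratio indirect   0.6144 0.3744 -0.0757  1.4309 9.86e-02
#>     sex_ratio    total   1.2934 0.4475  0.4543  2.2420 3.82e-03
#>  urbanization   direct  -0.6655 0.1296 -0.9201 -0.4135 1.92e-07
#>  urbanization indirect  -0.8281 0.4475 -1.7473 -0.0227 6.18e-02
#>  urbanization    total  -1.4935 0.5230 -2.5565 -0.5398 3.87e-03
#>  ...
```

`direct` is the average own-region impact of a covariate (including
feedback through neighbours), `indirect` the average impact transmitted
to other regions, and `total = direct + indirect` exactly. Here the
generating process used a negative urbanization effect and positive
sex-ratio effect, both recovered with the right signs.

`run_study()` wraps all stages (per-year Moran and LISA tables, cascade,
effect decomposition, VIF diagnostics, seasonal concentration summary)
into one config-driven call that writes CSV tables plus a JSON run log;
`inst/cli/spatpanel.R` exposes the same stages as shell subcommands
(`simulate | weights | temporal | moran | lisa | fit | select | report`).

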