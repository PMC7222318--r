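# fmdlag

Distributed-lag and polygenic mixed-model analysis of long-term
particulate air pollution exposure and brachial-artery flow-mediated
dilation (FMD), for family-based cohort studies.

## Who this is for

Environmental-epidemiology and cardiovascular researchers who have (a) a
cohort of related participants (a pedigree, or at least family labels),
(b) monthly residence-specific PM2.5/PM10 concentration estimates, and
(c) brachial-artery reactivity measurements, and who want to ask: *over
what averaging period does long-term PM exposure affect endothelial
function, and is the effect constant over that period or does it decay?*
Because no individual-level data of this kind are publicly shareable, the
package ships a first-class synthetic cohort generator with the same
statistical structure, so the entire pipeline is testable end to end.

## The models

**Vascular metrics.** From raw measurements:
`FMD = (MaxAD − BAD)/BAD × 100%`; shear stress ∝ V/BAD and response to
shear ∝ V/MaxAD (cm s⁻¹ mm⁻¹), with blood viscosity an absorbed constant.

**Exposure metrics.** Date-indexed moving averages over 1/6/12/24/36/60/84
months strictly before each exam month (lag 1 = the month before the
exam), monthly lag matrices, per-SD normalization, and polynomial
distributed-lag (PDL) bases of orders 0–5 in which the order-0 regressor
is *literally* the moving average.

**Polygenic mixed model.** y ~ N(Xβ, σ²_g·A + σ²_e·I), with A the
additive relationship matrix from the pedigree (tabular method;
parent–offspring 0.5) or an exchangeable family block matrix. Fitted by
REML after one eigendecomposition of A, with a deterministic 1-D profile
search over σ²_g/σ²_e; ML log-likelihood and BIC are recorded for model
averaging. Inference is two-sided Wald with 95% CIs β ± 1.96·se. The
fully adjusted model includes age, sex, age×sex, smoking, BMI, season,
year, hypertension and baseline diameter.

**Window scan + PDL/BMA.** One adjusted model per averaging window; the
window with the largest |β| is selected. Six PDL mixed models (orders
0–5, 12 lags) are combined by BIC-weighted Bayesian model averaging:
P(Mₖ|y) ∝ exp(−BICₖ/2). The averaged monthly lag coefficients and their
cumulative 12-month effect are exported as a plottable profile, and per-SD
effects can be rescaled to a 10 µg/m³ increment: β·(10/SD).

## Worked example

```r
library(fmdlag)

sim    <- simulate_cohort(sim_config(seed = 42))   # ~630 related adults
cohort <- add_vascular_metrics(sim$cohort)          # FMD %, shear metrics
ke     <- kinship_eigen(sim$A)                      # decompose once, reuse

window_scan(cohort, sim$panel, ke, "PM2.5")
#> Moving-average window scan for PM2.5
#>  window estimate    se        p  ci_lo  ci_hi
#>       1    0.118 0.233 6.12e-01 -0.338  0.574
#>       6   -0.654 0.263 1.28e-02 -1.169 -0.139
#>      12   -1.018 0.212 1.61e-06 -1.434 -0.602
#>      24   -0.987 0.214 3.90e-06 -1.406 -0.568
#>      36   -0.835 0.217 1.18e-04 -1.260 -0.410
#>      60   -0.807 0.218 2.19e-04 -1.235 -0.379
#>      84   -0.748 0.219 6.35e-04 -1.177 -0.319
#> selected window (largest |beta|): 12 months

lagz <- normalize_lag_matrix(build_lag_matrix(sim$panel, cohort, 12, "PM2.5"))
bma_average(fit_pdl_set(cohort, lagz, ke))
#> Bayesian model averaging over PDL orders (bic weights)
#>  order   loglik     bic posterior_prob
#>      0 -1928.23 3972.51         0.8899
#>      1 -1927.15 3976.79         0.1043
#>      2 -1926.89 3982.73         0.0054
#>      3 -1926.28 3987.95         0.0004
#>      4 -1925.32 3992.48         0.0000
#>      5 -1925.26 3998.80         0.0000
#> cumulative effect over 12 lags: -1.0183 (SE 0.2122)
```

Reading the output: each window row is the fully adjusted association of
FMD (%) with a one-SD increase in that window's PM2.5 moving average —
here the 12-month window is strongest (−1.02% FMD per SD, p ≈ 2×10⁻⁶),
as it should be, since this cohort was generated with a constant effect
over exactly lags 1–12 summing to −1% per SD. The BMA table shows 89% of
the posterior on the zero-order (moving-average-equivalent) lag model,
i.e. no evidence that the effect decays within the year, and the
cumulative 12-lag effect reproduces the moving-average coefficient.
`rescale_per_increment(-1.018, sd = 1.06)` converts this to −9.6% FMD
per 10 µg/m³ for cross-study comparison.

The whole pipeline (simulate → metrics → scan → PDL/BMA → report tables →
manifest) can be run as one reproducible unit with `run_pipeline()`, or
from a shell via `inst/scripts/fmdlag-pipeline.R`.

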