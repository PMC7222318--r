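---
title: "Distributed-lag and polygenic mixed-model analysis of particulate exposure and flow-mediated dilation"
author: "fmdlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed-lag and polygenic mixed-model analysis of particulate exposure and flow-mediated dilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmdlag)
```

## The scientific problem

Chronic exposure to particulate air pollution (PM2.5, PM10) is an
established cardiovascular risk factor, and endothelial dysfunction is one
of its earliest measurable manifestations. Brachial-artery flow-mediated
dilation (FMD) — the percent increase in arterial diameter after
post-occlusion hyperemia — is the standard non-invasive probe of
endothelial function. Two methodological questions arise in family-based
cohorts followed with residence-specific monthly exposure estimates:

1. **Over what averaging period does long-term PM exposure act on FMD?**
   Exposure can be summarized as a moving average of the months preceding
   each participant's exam, but the window (1, 6, 12, 24, 36, 60 or 84
   months) is an empirical choice.
2. **Is the effect constant over the chosen window, or does it decay?**
   A moving average assumes each month contributes equally. Polynomial
   distributed-lag (PDL) models relax this, and Bayesian model averaging
   (BMA) over PDL orders quantifies how much support the data give to
   constant, linearly decaying, or higher-order lag structures.

Participants in family studies are related, so ordinary regression
understates uncertainty. The package therefore fits *polygenic*
linear mixed models: the random effect has covariance proportional to the
additive relationship matrix derived from the pedigree.

## Vascular metrics

From raw ultrasound measurements (baseline diameter BAD, maximum
post-occlusion diameter MaxAD, post-occlusive velocity $V$):

$$\mathrm{FMD} = \frac{\mathrm{MaxAD}-\mathrm{BAD}}{\mathrm{BAD}}\times 100\%,
\qquad
\text{shear stress} \propto \frac{V}{\mathrm{BAD}}, \qquad
\text{response to shear} \propto \frac{V}{\mathrm{MaxAD}},$$

the shear quantities in cm s$^{-1}$ mm$^{-1}$ with blood viscosity treated
as an absorbed constant (the proxies omit it, so no viscosity parameter is
exposed). FMD is negative when the artery constricts; whenever
MaxAD > BAD the response to shear is strictly below the shear stimulus.

## Exposure metrics and the lag convention

Monthly concentrations are indexed on a continuous integer month scale.
**Lag 1 is the calendar month immediately before the exam month; the exam
month itself is never included.** An $L$-month moving average is the mean
of lags $1..L$. Coverage must be complete: a missing month is a hard
error naming the participant and month — no imputation, because the
emulated population is residentially stable and the method assumes
complete monthly histories.

### Normalization

Exposures are normalized (centered by the sample mean, scaled by the
sample SD, denominator $n-1$) so effects are per SD of exposure.
For the lag matrix feeding the PDL models, all 12 columns are scaled by a
*single* pair of constants — the mean and SD of the participants' 12-month
moving average — rather than column-wise. Two identities follow that
column-wise z-scoring would destroy:

* the row mean of the normalized lag matrix is exactly the normalized
  moving average, so the order-0 PDL regressor *is* the moving-average
  term and the two models agree to machine precision in coefficient,
  standard error and likelihood; and
* the sum of the 12 monthly lag coefficients is exactly the effect of a
  one-SD increase in the 12-month moving average, which is what the
  cumulative row of the lag profile reports.

### PDL basis

A PDL of order $k$ constrains the lag weights to
$\beta_\ell = \sum_{j=0}^k \theta_j p_j(\ell)$. The basis uses
$p_0(\ell) = 1/L$ (so the order-0 regressor is the moving average
literally) and raw powers $p_j(\ell) = ((\ell-1)/(L-1))^j$ rescaled to
$[0,1]$ for numerical balance. Raw polynomials are the default because
BMA posterior weights and fitted values are invariant to the within-order
parameterization while the order-0/moving-average identity must be
literal; an orthogonal variant (`type = "orthogonal"`) is available and
leaves fitted values unchanged. Raw powers above order 5 on 12 lags
would be ill-conditioned, but orders 0–5 (the analysis set) are safe.

## The polygenic linear mixed model

For outcome $y$ (FMD%, shear, or response to shear),

$$y \sim N\!\big(X\beta,\; \sigma^2_g A + \sigma^2_e I\big),$$

where $A$ is the additive (numerator) relationship matrix built from the
pedigree by the tabular method: $A_{ii} = 1 + \tfrac12 A_{f(i),m(i)}$ and
$A_{ij} = \tfrac12(A_{j,f(i)} + A_{j,m(i)})$, processing parents before
children. Parent–offspring and full-sib entries are 0.5; the diagonal
exceeds 1 under inbreeding (1.25 for the offspring of full sibs). When
only family labels are available, a block-diagonal matrix of ones gives
the exchangeable-family special case, identical to a random intercept per
family (this equivalence is verified against `lme4` in the test suite).

### Estimation

Writing $A = U D U'$ (one symmetric eigendecomposition, reusable across
every model on the same pedigree), the rotated model has diagonal
covariance $\sigma^2_e(\delta D + I)$ with variance ratio
$\delta = \sigma^2_g/\sigma^2_e$. $\beta$ and $\sigma^2_e$ are profiled
out in closed form and $\delta$ is found by a deterministic 1-D search:
a 61-point log-spaced grid on $[10^{-4}, 10^{4}]$ plus the $\delta = 0$
boundary, followed by golden-section refinement (`stats::optimize`,
tolerance $10^{-10}$). No random starts, so fits are exactly
reproducible.

* **Variance components and fixed-effect SEs** come from REML (the field
  default, unbiased in the fixed effects).
* **Log-likelihood and BIC** come from a parallel ML profile, because the
  PDL orders differ in their fixed effects and only ML likelihoods are
  comparable across such models. BIC counts $p + 2$ parameters (fixed
  effects plus two variance components).

Inference is large-sample Wald: $z = \hat\beta/\mathrm{se}$,
$p = 2\Phi(-|z|)$, and 95% intervals $\hat\beta \pm 1.96\,\mathrm{se}$.
The degrees-of-freedom question is deliberately left at the normal
reference — with ~600 observations and ~20 coefficients the distinction
from a $t$ reference is negligible, and it matches how effect sizes,
SEs and CIs are conventionally reported in this literature.

### Adjustment set, interactions, strata

The fully adjusted model includes age, sex, age-by-sex, smoking
(never/ever/current), BMI, season of exam (four seasons by calendar
month), calendar year of exam (categorical), hypertension, and baseline
brachial artery diameter. Any factor that is constant within the
analysis subset is dropped automatically with a message — this is what
removes smoking from women-only strata, where all women are
never-smokers by construction. Effect modification is scanned with
exposure-by-age, exposure-by-sex and exposure-by-sex-by-age-group terms;
a failed augmented fit is recorded and the scan continues. Stratified
fits subset the relationship matrix (relatedness is a property of the
pedigree, never re-derived) and unestimable strata are skipped with a
warning.

## Window scan and BMA

The averaging-period scan fits one fully adjusted model per window
(1, 6, 12, 24, 36, 60, 84 months) with the normalized window average as
exposure, and selects the window with the largest $|\hat\beta|$; exact
ties go to the shorter window (parsimony; windows are scanned in
ascending order so the first maximum wins).

The six PDL fits (orders 0–5, 12 lags) are combined with
BIC-approximated posterior model probabilities under equal priors,

$$P(M_k \mid y) = \frac{e^{-\mathrm{BIC}_k/2}}{\sum_j e^{-\mathrm{BIC}_j/2}},$$

computed after subtracting the minimum BIC (log-sum-exp), so the weights
are invariant to shifting all BICs and immune to overflow. The averaging
reference does not pin down prior weights; BIC weighting with equal
priors is the standard surrogate in distributed-lag air-pollution work,
and an AIC variant is available (`weights = "aic"`). Averaged lag
coefficients are the probability-weighted mixture; their variance adds
the between-model spread to the within-model variance (the usual BMA
mixture variance). The exported lag profile has 13 rows: 12 monthly
coefficients plus the cumulative effect, whose point estimate equals the
column sum exactly and, under pure order-0 dominance, equals the
moving-average coefficient with each lag at 1/12 of it.

## The synthetic cohort generator

No individual-level data from family studies of this kind are public, so
the generator is a first-class module producing data with the exact
structure the analysis assumes. Defaults emulate a rural, multi-
generation family cohort examined 2003–2006:

| quantity | default | rationale |
|---|---|---|
| families / cohort size | 65 / ≈615 adults | founder couple + Poisson(3) children, half with spouse and Poisson(2) grandchildren |
| % women | 43.7 | descendant sex probability solved so the expectation hits the target despite 1F/1M founder couples |
| smoking (men) | 20.5% current, 25.7% ever | women never smoke, deterministically |
| BMI (kg/m²) | M 25.5 (3.2), F 27.3 (4.8) | sex-specific normals |
| hypertension | 13.3% | a config knob: study sources report both a 13.3% diagnosed count and a 3.7% narrative figure, so prevalence is exposed rather than resolved |
| BAD (mm) | M 4.1 (0.4), F 3.1 (0.4) | sex-specific; MaxAD back-computed |
| PM2.5 MA12 | mean 18.2, SD 1.1 µg/m³ | calibration target |
| PM10 MA12 | mean 15.0, SD 1.2 µg/m³ | calibration target (PM2.5 > PM10 reflects the documented exposure-model artifact) |
| polygenic / residual variance | 10 / 20 FMD%² | with covariate variance gives total SD ≈ 5.8–6% |
| true lag weights | constant, sum −1 FMD% per SD | order-0 generative truth |

**Exposure series.** Each participant's monthly series is a
residence-level mean (family deviate + individual jitter, shared across
pollutants), an annual sinusoid (amplitude 3 µg/m³, July peak), and
monthly noise correlated 0.8 between pollutants (fine particles are most
of PM10 mass). A sinusoid with a 12-month period cancels exactly in any
12-month average, so the MA12 calibration depends only on the mean and
the residence/jitter/noise SDs. The variance split is deliberately
temporal-dominant (residence SD 0.3–0.35 vs monthly noise SD 3.6–3.9):
the emulated study area is a single compact county, where spatial
gradients are small and month-to-month variation large. This choice is
load-bearing: if residence-level variance dominated, the moving averages
of all windows would be nearly collinear and no windowing analysis (here
or in a real study of such data) could distinguish averaging periods.

**Outcomes.** FMD is generated as fixed effects + $\sum_\ell w_\ell
z_\ell$ (normalized lags, so a constant $w$ summing to $S$ makes the
per-SD MA12 effect exactly $S$) + polygenic effect
$g \sim N(0, \sigma^2_g A)$ + residual noise. BAD is drawn around
sex-specific means and MaxAD back-computed by inverting the FMD formula,
so the analysis pipeline always starts from raw vascular measurements.
Velocities are sex-specific truncated normals.

**Determinism.** Every stage derives its own seed from the master seed
by a fixed affine rule (`stage_seed`), so a configuration reproduces the
cohort byte-identically and single stages can be rerun in isolation.

### What the generator does *not* emulate

Spatio-temporal exposure-model error (exposures are taken as given),
long-term concentration trends, residential moves, measurement error in
the ultrasound reads, assortative mating and inbreeding (generated
pedigrees are outbred, though the kinship code handles inbred input),
non-normal FMD tails, and missing data. Passing tests therefore show
correctness of the statistical machinery under the stated generative
assumptions, not robustness to these real-data complications.

## Validation experiments and their sizes

The test suite validates the machinery at the study's own scale; the
sizes below were chosen as the smallest runs whose Monte-Carlo error is
comfortably below the margins being asserted.

* **Oracle checks** — OLS at $\delta = 0$ and closed-form GLS at known
  $\delta$ agree to $10^{-8}$; the exchangeable-family fit agrees with
  `lme4::lmer` to $10^{-6}$; tabular kinship agrees with a $10^5$-replicate
  gene-dropping estimate within 0.02.
* **Parameter recovery** — 200 replicates of ≈650 participants with a
  true per-SD effect of −0.5 ($\sigma^2_g = 10$, $\sigma^2_e = 20$):
  mean bias within 3 Monte-Carlo SEs and 95% CI coverage in [0.92, 0.98].
* **Lag-shape recovery** — 50 replicates each: constant truth (sum −1)
  gives median zero-order posterior > 0.9; linear-decay truth
  ($w_\ell = -(12-\ell)/11$, chosen by an a-priori power analysis so the
  slope contrast is comfortably detectable at this sample size) makes
  order 1 modal.
* **Window recovery** — 20 strong-signal replicates (constant truth,
  sum −6): the 12-month window is selected in ≥90%.

## Known limitations

* Wald/normal inference only; no small-sample df correction or
  likelihood-ratio intervals.
* The BIC weight is a large-$n$ approximation to the marginal
  likelihood; with ~600 observations it is adequate for separating lag
  shapes but the posterior percentages should not be over-read.
* $\delta$ is searched on $[0, 10^4]$; heritabilities above
  $\approx 0.9999$ would hit the bound (not a realistic regime here).
* The generator's family structure is three generations deep with
  in-marrying founders; deeper or loopy pedigrees are accepted by the
  kinship code but never generated.
* One exposure drives the simulated outcome; simulating joint causal
  effects of both pollutants is out of scope.
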