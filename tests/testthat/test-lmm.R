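# Shared small analysis data for the mixed-model tests.
lmm_data <- function() {
  sim <- small_sim()
  coh <- add_vascular_metrics(sim$cohort)
  ma <- moving_average(sim$panel, coh, 12, "PM2.5")
  coh$pm_z <- normalize_exposure(ma)$z
  list(coh = coh, A = sim$A, sim = sim)
}

test_that("zero polygenic variance reduces the fit to OLS", {
  d <- lmm_data()
  sp <- model_spec(exposure = "pm_z")
  fit <- fit_polygenic_lmm(sp, d$coh, d$A, fix_delta = 0)
  X <- fmdlag:::build_design(sp, d$coh)
  ols <- lm(d$coh$fmd_pct ~ X - 1)
  expect_equal(unname(fit$coef$estimate), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$coef$se),
               unname(coef(summary(ols))[, "Std. Error"]), tolerance = 1e-8)
  expect_equal(fit$sigma2_g, 0)
})

test_that("a fixed variance ratio reproduces closed-form GLS", {
  d <- lmm_data()
  sp <- model_spec(exposure = "pm_z")
  delta <- 0.8
  fit <- fit_polygenic_lmm(sp, d$coh, d$A, fix_delta = delta)
  X <- fmdlag:::build_design(sp, d$coh)
  V <- delta * d$A + diag(nrow(d$coh))  # up to the common sigma2_e factor
  or <- gls_oracle(d$coh$fmd_pct, X, V)
  expect_equal(unname(fit$coef$estimate), unname(or$beta), tolerance = 1e-8)
  # oracle SEs are per unit sigma2_e; rescale by the profiled estimate
  expect_equal(unname(fit$coef$se),
               unname(or$se * sqrt(fit$sigma2_e)), tolerance = 1e-8)
})

test_that("exchangeable-family fits match a random-intercept oracle", {
  set.seed(42)
  n_fam <- 40
  fam <- rep(seq_len(n_fam), each = 5)
  n <- length(fam)
  x <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 0.5 * x - 0.3 * x2 + rnorm(n_fam, 0, 2)[fam] + rnorm(n, 0, 1.5)
  d <- data.frame(id = as.character(seq_len(n)), y = y, x = x, x2 = x2,
                  fam = fam)
  A <- family_matrix(fam, d$id)
  sp <- model_spec(outcome = "y", exposure = c("x", "x2"),
                   covariates = character(), include_bad = FALSE)
  fit <- fit_polygenic_lmm(sp, d, A)
  lf <- lme4::lmer(y ~ x + x2 + (1 | fam), d, REML = TRUE)
  expect_equal(unname(fit$coef$estimate), unname(lme4::fixef(lf)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coef$se),
               unname(coef(summary(lf))[, "Std. Error"]), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma2_g, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  lf_ml <- lme4::lmer(y ~ x + x2 + (1 | fam), d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(lf_ml)), tolerance = 1e-6)
})

test_that("Wald inference follows the normal reference", {
  d <- lmm_data()
  fit <- fit_polygenic_lmm(model_spec(exposure = "pm_z"), d$coh, d$A)
  w <- wald_test(fit, "pm_z")
  expect_equal(w$p, 2 * pnorm(-abs(w$estimate / w$se)))
  expect_equal(w$ci_lo, w$estimate - 1.96 * w$se)
  expect_equal(w$ci_hi, w$estimate + 1.96 * w$se)
  expect_error(wald_test(fit, "nope"), "not in fit")

  # the printed-pattern check: beta -0.09, se 0.03 gives the familiar
  # CI (-0.149, -0.031) and p about 0.003
  fake <- fit
  fake$coef <- data.frame(term = "x", estimate = -0.09, se = 0.03,
                          z = -3, p = 2 * pnorm(-3),
                          ci_lo = -0.09 - 1.96 * 0.03,
                          ci_hi = -0.09 + 1.96 * 0.03)
  w <- wald_test(fake, "x")
  expect_equal(round(c(w$ci_lo, w$ci_hi), 2), c(-0.15, -0.03))
  expect_lt(w$p, 0.05)
})

test_that("rank-deficient designs fail with the aliased column named", {
  d <- lmm_data()
  d$coh$pm_dup <- d$coh$pm_z
  sp <- model_spec(exposure = c("pm_z", "pm_dup"))
  expect_error(fit_polygenic_lmm(sp, d$coh, d$A), "pm_dup")
})

test_that("REML profile deviance is unimodal-sane and converged", {
  d <- lmm_data()
  sp <- model_spec(exposure = "pm_z")
  fit <- fit_polygenic_lmm(sp, d$coh, d$A)
  X <- fmdlag:::build_design(sp, d$coh)
  ke <- kinship_eigen(d$A)
  yt <- crossprod(ke$U, d$coh$fmd_pct)
  Xt <- crossprod(ke$U, X)
  at_opt <- fmdlag:::profile_deviance(yt, Xt, ke$d, fit$delta, "reml")$crit
  for (mult in c(0.8, 1.25)) {
    near <- fmdlag:::profile_deviance(yt, Xt, ke$d, fit$delta * mult,
                                      "reml")$crit
    expect_gte(near, at_opt - 1e-8)
  }
})

test_that("interaction scan augments the base model and survives failures", {
  d <- lmm_data()
  sp <- model_spec(exposure = "pm_z")
  sc <- interaction_scan(sp, d$coh, d$A)
  expect_true(all(c("exposure_by_age", "exposure_by_sex") %in%
                  sc$interaction))
  ok <- !is.na(sc$estimate)
  expect_true(any(ok))
  expect_equal(sc$p[ok], 2 * pnorm(-abs(sc$z[ok])))

  # a duplicated main effect masquerading as an interaction is reported as
  # a rank error for that row while the scan continues
  sc2 <- interaction_scan(sp, d$coh, d$A,
                          terms = c(dup_main = "I(age)",
                                    exposure_by_sex = "pm_z:sex"))
  dup <- sc2[sc2$interaction == "dup_main", ]
  expect_true(is.na(dup$estimate))
  expect_match(dup$error, "rank|alias")
  ok <- sc2[sc2$interaction == "exposure_by_sex", ]
  expect_false(is.na(ok$estimate))
})

test_that("stratified fits partition the cohort and drop smoking in women", {
  d <- lmm_data()
  sp <- model_spec(exposure = "pm_z")
  # the small fixture leaves some age-by-sex cells unestimable; those are
  # skipped with a warning rather than failing the whole analysis
  st <- suppressMessages(suppressWarnings(stratified_fits(sp, d$coh, d$A)))
  expect_true(all(c("all", "men", "women") %in% names(st$fits)))

  # sex strata partition the cohort
  expect_equal(st$fits$men$n + st$fits$women$n, st$fits$all$n)
  # age-by-sex strata partition it too
  four <- c("men_lt50", "men_ge50", "women_lt50", "women_ge50")
  if (all(four %in% names(st$fits)))
    expect_equal(sum(vapply(st$fits[four], function(f) f$n, numeric(1))),
                 st$fits$all$n)

  # women are all never-smokers, so no smoking column can appear
  expect_false(any(grepl("smoking", st$fits$women$coef$term)))
  expect_true(any(grepl("smoking", st$fits$men$coef$term)))

  # homogeneous simulation: stratum estimates near the pooled one
  pooled <- wald_test(st$fits$all, "pm_z")$estimate
  men <- wald_test(st$fits$men, "pm_z")
  expect_lt(abs(men$estimate - pooled), 4 * men$se)
})

test_that("excluding baseline diameter leaves the exposure effect stable", {
  # BAD is simulated independently of exposure, so dropping it from the
  # adjustment set must not move the exposure coefficient materially
  d <- lmm_data()
  f_with <- fit_polygenic_lmm(model_spec(exposure = "pm_z"), d$coh, d$A)
  f_without <- fit_polygenic_lmm(model_spec(exposure = "pm_z",
                                            include_bad = FALSE),
                                 d$coh, d$A)
  b1 <- wald_test(f_with, "pm_z")
  b2 <- wald_test(f_without, "pm_z")
  expect_lt(abs(b1$estimate - b2$estimate), 0.5 * b1$se)
  expect_false("bad_mm" %in% f_without$coef$term)
})
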