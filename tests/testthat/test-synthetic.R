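test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(n_families = 6, seed = 314)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$panel, s2$panel)
  s3 <- simulate_cohort(sim_config(n_families = 6, seed = 315))
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(polygenic_variance = -1), "variances")
  expect_error(sim_config(true_lag_weights = rep(0, 5)), "length")
  expect_error(sim_config(family_structure = list(mean_children = -1,
                                                  marry_prob = 0.5,
                                                  mean_grandchildren = 1)),
               "family-size")
  expect_error(sim_config(history_months = 6), "history_months")
})

test_that("degenerate exposure settings give exactly the configured mean", {
  cfg <- sim_config(n_families = 4, seed = 9)
  for (p in names(cfg$pollutants)) {
    cfg$pollutants[[p]]$residence_sd <- 0
    cfg$pollutants[[p]]$jitter_sd <- 0
    cfg$pollutants[[p]]$seasonal_amplitude <- 0
    cfg$pollutants[[p]]$monthly_noise_sd <- 0
  }
  ped <- generate_pedigree(cfg)
  panel <- simulate_exposures(ped, cfg)
  for (p in names(cfg$pollutants))
    expect_true(all(panel$conc[panel$pollutant == p] ==
                    cfg$pollutants[[p]]$mean))
})

test_that("exposure panels cover 84 months before any exam and stay positive", {
  sim <- small_sim()
  cfg <- sim$config
  expect_true(all(sim$panel$conc > 0))
  first_exam <- month_index(cfg$exam_start[1], cfg$exam_start[2])
  last_exam <- month_index(cfg$exam_end[1], cfg$exam_end[2])
  rng <- range(sim$panel$month)
  expect_lte(rng[1], first_exam - 84)
  expect_equal(rng[2], last_exam - 1)
  # contiguous coverage per participant and pollutant
  one <- sim$panel[sim$panel$id == sim$cohort$id[1] &
                   sim$panel$pollutant == "PM2.5", ]
  expect_equal(sort(one$month), rng[1]:rng[2])
})

test_that("cohort marginals match their configured targets (3 SE)", {
  cfg <- sim_config(seed = 2718)  # default scale: ~600 participants
  sim <- simulate_cohort(cfg)
  coh <- sim$cohort
  n <- nrow(coh)
  expect_gt(n, 400)

  # sex ratio
  pf <- mean(coh$sex == "F")
  expect_lt(abs(pf - cfg$p_female), 3 * sqrt(0.25 / n))

  # smoking: confined to men, rates near config
  expect_true(all(coh$smoking[coh$sex == "F"] == "never"))
  men <- coh[coh$sex == "M", ]
  p_cur <- mean(men$smoking == "current")
  expect_lt(abs(p_cur - cfg$smoking_male[["current"]]),
            3 * sqrt(0.25 / nrow(men)))

  # 12-month moving-average exposure moments
  for (pol in c("PM2.5", "PM10")) {
    ma <- moving_average(sim$panel, coh, 12, pol)
    target <- cfg$pollutants[[pol]]$mean
    expect_lt(abs(mean(ma) - target), 3 * sd(ma) / sqrt(n))
  }

  # season is determined by the exam calendar month
  expect_equal(coh$season, month_season(coh$exam_month))
  # baseline diameters positive with sex-specific centers
  expect_true(all(coh$bad_mm > 0) && all(coh$maxad_mm > 0))
  expect_gt(mean(coh$bad_mm[coh$sex == "M"]),
            mean(coh$bad_mm[coh$sex == "F"]))
})

test_that("a null configuration collapses FMD to the intercept", {
  cfg <- sim_config(n_families = 3, seed = 5,
                    true_lag_weights = rep(0, 12),
                    covariate_effects = c(intercept = 9),
                    polygenic_variance = 0, residual_variance = 0)
  sim <- simulate_cohort(cfg)
  coh <- add_vascular_metrics(sim$cohort)
  expect_equal(coh$fmd_pct, rep(9, nrow(coh)), tolerance = 1e-10)
})

test_that("polygenic effects carry the parent-offspring correlation", {
  # with only the polygenic component active, cov(parent, child) = 0.5 vg
  cfg <- sim_config(n_families = 30, seed = 77,
                    polygenic_variance = 10, residual_variance = 0,
                    true_lag_weights = rep(0, 12),
                    covariate_effects = c(intercept = 0))
  ped <- generate_pedigree(cfg)
  A <- kinship_matrix(ped)
  pairs <- which(upper.tri(A) & A == 0.5, arr.ind = TRUE)
  expect_gt(nrow(pairs), 50)
  reps <- 150
  prods <- matrix(NA_real_, reps, nrow(pairs))
  vars <- numeric(reps)
  set.seed(123)
  for (r in seq_len(reps)) {
    g <- fmdlag:::draw_polygenic(A, cfg$polygenic_variance)
    prods[r, ] <- g[pairs[, 1]] * g[pairs[, 2]]
    vars[r] <- mean(g^2)
  }
  cov_po <- mean(prods)
  se <- sd(rowMeans(prods)) / sqrt(reps)
  expect_lt(abs(cov_po - 0.5 * cfg$polygenic_variance), 3 * se)
  expect_lt(abs(mean(vars) - cfg$polygenic_variance),
            3 * sd(vars) / sqrt(reps))
})

test_that("simulated exposures feed a recoverable constant lag effect", {
  # strong constant truth: the fitted normalized 12-month MA coefficient
  # estimates the sum of the lag weights
  cfg <- sim_config(seed = 99, true_lag_weights = rep(-6 / 12, 12))
  sim <- simulate_cohort(cfg)
  coh <- add_vascular_metrics(sim$cohort)
  ma <- moving_average(sim$panel, coh, 12, cfg$outcome_pollutant)
  coh$pm_z <- normalize_exposure(ma)$z
  fit <- fit_polygenic_lmm(model_spec(exposure = "pm_z"), coh, sim$A)
  w <- wald_test(fit, "pm_z")
  expect_lt(abs(w$estimate - sum(cfg$true_lag_weights)), 4 * w$se)
})
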