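#' Simulation configuration for the synthetic family cohort
#'
#' Bundles every knob of the synthetic-data generator.  Defaults are
#' calibrated to the structure of a rural family-based endothelial-function
#' study: roughly 615 adults in extended families examined over 2003-2006,
#' 43.7% women, smoking confined to men, sex-specific baseline brachial
#' artery diameters, and residential monthly particulate-matter series whose
#' 12-month moving averages have mean (SD) 18.2 (1.1) ug/m^3 for PM2.5 and
#' 15.0 (1.2) ug/m^3 for PM10.  Because the emulated study area is
#' geographically compact, most exposure variance is temporal (seasonal
#' cycle plus month-to-month fluctuation) and the between-residence
#' component is comparatively small; this is what makes moving averages of
#' different windows statistically distinguishable.
#'
#' Flow-mediated dilation (FMD, in percent) is generated as
#' `intercept + covariate effects + sum_l w_l z_l + g + e`, where `z_l` are
#' the monthly lag exposures on the normalized (per-SD-of-12-month-moving-
#' average) scale, `w` is `true_lag_weights`, `g` is a polygenic effect with
#' covariance `polygenic_variance * A` (A the additive relationship matrix)
#' and `e` is iid residual noise.  The default lag weights are constant,
#' summing to -1 FMD% per SD of exposure, so the generative truth is an
#' order-0 (moving-average-equivalent) distributed lag structure.
#'
#' @param n_families number of independent extended families.
#' @param family_structure list with `mean_children` (Poisson mean number of
#'   children per founder couple), `marry_prob` (probability a child has an
#'   in-marrying spouse and offspring), `mean_grandchildren` (Poisson mean
#'   grandchildren per married child).
#' @param p_female target proportion of women in the cohort; the sex
#'   probability for descendants is solved internally so the expected
#'   cohort-wide proportion (founder couples are always one man, one woman)
#'   matches this target.
#' @param exam_start,exam_end `c(year, month)` bounds of the exam window;
#'   exam months are drawn uniformly between them.
#' @param pollutants named list (one entry per pollutant) of generative
#'   parameters in ug/m^3: `mean` (long-run residence-level mean),
#'   `residence_sd` (between-family SD), `jitter_sd` (within-family
#'   between-individual SD), `seasonal_amplitude` (annual sinusoid
#'   amplitude), `monthly_noise_sd` (iid monthly noise), `peak_month`
#'   (calendar month of the seasonal peak).
#' @param cross_pollutant_cor correlation of the monthly noise deviates
#'   between pollutants (the fine fraction makes up most of PM10 mass, so
#'   their series track each other closely).
#' @param history_months months of exposure history generated before the
#'   earliest possible exam month (must cover the longest averaging window).
#' @param lag_window number of monthly lags entering the outcome model.
#' @param true_lag_weights numeric vector of length `lag_window`: effect of
#'   each monthly lag (FMD% per normalized exposure unit).
#' @param outcome_pollutant pollutant whose lags drive the simulated FMD.
#' @param covariate_effects named vector of fixed-effect coefficients on the
#'   FMD% scale (see Details in the package vignette).
#' @param age_means,age_sds,min_age generation-specific age distributions
#'   (years), truncated below at `min_age`.
#' @param smoking_male probabilities `c(current, ever)` for men; women are
#'   never-smokers by construction.
#' @param hypertension_prev prevalence of diagnosed hypertension.
#' @param bmi_mean,bmi_sd,bad_mean,bad_sd,post_vel_mean,post_vel_sd,
#'   pre_vel_mean,pre_vel_sd sex-specific (`M`, `F`) distribution parameters
#'   for BMI (kg/m^2), baseline brachial artery diameter (mm) and pre/post
#'   occlusive blood velocity (cm/s).
#' @param polygenic_variance,residual_variance variance components of FMD%
#'   (FMD%^2 units).
#' @param seed integer master seed; every generator stage derives its own
#'   stream from it, so a fixed config reproduces the cohort exactly.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(n_families = 65,
                       family_structure = list(mean_children = 3,
                                               marry_prob = 0.5,
                                               mean_grandchildren = 2),
                       p_female = 0.437,
                       exam_start = c(2003, 1),
                       exam_end = c(2006, 12),
                       pollutants = list(
                         PM2.5 = list(mean = 18.2, residence_sd = 0.3,
                                      jitter_sd = 0.2, seasonal_amplitude = 3,
                                      monthly_noise_sd = 3.6, peak_month = 7),
                         PM10 = list(mean = 15.0, residence_sd = 0.35,
                                     jitter_sd = 0.2, seasonal_amplitude = 3,
                                     monthly_noise_sd = 3.9, peak_month = 7)),
                       cross_pollutant_cor = 0.8,
                       history_months = 84,
                       lag_window = 12,
                       true_lag_weights = rep(-1 / 12, 12),
                       outcome_pollutant = "PM2.5",
                       covariate_effects = c(intercept = 25.8, age = -0.05,
                                             sexF = 2.5, age_sexF = -0.02,
                                             smoking_ever = -0.5,
                                             smoking_current = -1,
                                             bmi = -0.1, hypertension = -1,
                                             bad = -3, season_spring = 0.3,
                                             season_summer = 0.5,
                                             season_autumn = 0.2,
                                             year2004 = 0, year2005 = 0,
                                             year2006 = 0),
                       age_means = c(founder = 63, child = 44, grandchild = 27),
                       age_sds = c(founder = 9, child = 8, grandchild = 5),
                       min_age = 20,
                       smoking_male = c(current = 0.205, ever = 0.257),
                       hypertension_prev = 0.133,
                       bmi_mean = c(M = 25.5, F = 27.3),
                       bmi_sd = c(M = 3.2, F = 4.8),
                       bad_mean = c(M = 4.1, F = 3.1),
                       bad_sd = c(M = 0.4, F = 0.4),
                       post_vel_mean = c(M = 82.9, F = 74.9),
                       post_vel_sd = c(M = 21.5, F = 25.3),
                       pre_vel_mean = c(M = 9.5, F = 5.6),
                       pre_vel_sd = c(M = 6.7, F = 5.5),
                       polygenic_variance = 10,
                       residual_variance = 20,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_families < 1) stop("n_families must be >= 1")
    fs <- family_structure
    if (fs$mean_children < 0 || fs$mean_grandchildren < 0 ||
        fs$marry_prob < 0 || fs$marry_prob > 1)
      stop("invalid family-size parameters: mean_children and ",
           "mean_grandchildren must be >= 0 and marry_prob in [0, 1]")
    if (p_female < 0 || p_female > 1) stop("p_female must be in [0, 1]")
    if (polygenic_variance < 0 || residual_variance < 0)
      stop("variances must be >= 0")
    if (length(true_lag_weights) != lag_window)
      stop("true_lag_weights must have length lag_window (", lag_window, ")")
    for (p in names(pollutants)) {
      pp <- pollutants[[p]]
      if (pp$mean <= 0) stop("pollutant mean must be > 0 (", p, ")")
      if (any(unlist(pp[c("residence_sd", "jitter_sd", "seasonal_amplitude",
                          "monthly_noise_sd")]) < 0))
        stop("pollutant variability parameters must be >= 0 (", p, ")")
    }
    if (cross_pollutant_cor < -1 || cross_pollutant_cor > 1)
      stop("cross_pollutant_cor must be in [-1, 1]")
    if (history_months < lag_window)
      stop("history_months must cover at least the lag window")
    if (month_index(exam_end[1], exam_end[2]) <
        month_index(exam_start[1], exam_start[2]))
      stop("exam_end precedes exam_start")
    if (abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  })
  invisible(cfg)
}

# Deterministic per-stage seed derivation from the master seed, so each
# generator stage can be rerun in isolation with the same stream.
stage_seed <- function(seed, stage) {
  offsets <- c(pedigree = 101L, covariates = 211L, exposures = 307L,
               outcomes = 401L, analysis = 503L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  families:", x$n_families,
      "| target p(female):", x$p_female,
      "| seed:", x$seed, "\n")
  cat("  exam window:", sprintf("%04d-%02d", x$exam_start[1], x$exam_start[2]),
      "to", sprintf("%04d-%02d", x$exam_end[1], x$exam_end[2]), "\n")
  cat("  pollutants:", paste(names(x$pollutants), collapse = ", "),
      "| history:", x$history_months, "months\n")
  cat("  lag window:", x$lag_window,
      "| sum of true lag weights:", sum(x$true_lag_weights), "\n")
  cat("  variance components: polygenic", x$polygenic_variance,
      "residual", x$residual_variance, "\n")
  invisible(x)
}
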