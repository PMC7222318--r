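#' Generate a multi-generation synthetic pedigree
#'
#' Each family starts from a founder couple; children are drawn from a
#' Poisson distribution, and each child may acquire an in-marrying founder
#' spouse and grandchildren.  Sexes of descendants are Bernoulli with a
#' probability solved so the expected cohort-wide proportion of women
#' matches `config$p_female` despite founder couples being exactly one man
#' and one woman.
#'
#' @param config a [sim_config()] object.
#' @return pedigree data frame (`id`, `father`, `mother`, `sex`, `family`,
#'   `generation`), parents before children.
#' @export
generate_pedigree <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "pedigree"))
  fs <- config$family_structure
  q <- descendant_female_prob(config)

  rows <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("fam%03d", f)
    nid <- 0L
    new_id <- function() {
      nid <<- nid + 1L
      sprintf("%s_i%02d", fam, nid)
    }
    dad <- new_id(); mom <- new_id()
    rec <- data.frame(id = c(dad, mom), father = "0", mother = "0",
                      sex = c("M", "F"), family = fam, generation = 1L,
                      stringsAsFactors = FALSE)
    n_child <- stats::rpois(1, fs$mean_children)
    for (k in seq_len(n_child)) {
      child <- new_id()
      child_sex <- if (stats::runif(1) < q) "F" else "M"
      rec <- rbind(rec, data.frame(id = child, father = dad, mother = mom,
                                   sex = child_sex, family = fam,
                                   generation = 2L))
      if (stats::runif(1) < fs$marry_prob) {
        spouse <- new_id()
        spouse_sex <- if (child_sex == "F") "M" else "F"
        rec <- rbind(rec, data.frame(id = spouse, father = "0", mother = "0",
                                     sex = spouse_sex, family = fam,
                                     generation = 2L))
        n_gc <- stats::rpois(1, fs$mean_grandchildren)
        for (g in seq_len(n_gc)) {
          gc_sex <- if (stats::runif(1) < q) "F" else "M"
          rec <- rbind(rec, data.frame(
            id = new_id(),
            father = if (child_sex == "M") child else spouse,
            mother = if (child_sex == "F") child else spouse,
            sex = gc_sex, family = fam, generation = 3L))
        }
      }
    }
    rows[[f]] <- rec
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  validate_pedigree(ped)
  ped
}

# Solve the descendant sex probability q so that the expected proportion of
# women in the whole pedigree equals the target, given that founder couples
# contribute exactly one woman each and in-marrying spouses take the
# opposite sex of the child they marry.
descendant_female_prob <- function(config) {
  fs <- config$family_structure
  c_ <- fs$mean_children
  m <- fs$marry_prob
  g <- fs$mean_grandchildren
  members <- 2 + c_ + c_ * m + c_ * m * g
  # E[female] = 1 + c q + c m (1 - q) + c m g q
  denom <- c_ - c_ * m + c_ * m * g
  if (denom <= 0) return(0.5)
  q <- (config$p_female * members - 1 - c_ * m) / denom
  min(max(q, 0), 1)
}

#' Simulate participant covariates
#'
#' Assigns exam dates (uniform over the configured window), ages by
#' generation, smoking status (men only), BMI, and hypertension.  Season and
#' calendar year are derived from the exam month.
#'
#' @param ped pedigree from [generate_pedigree()].
#' @param config a [sim_config()] object.
#' @return data frame with one row per pedigree member: `id`, `family`,
#'   `sex`, `exam_month` (integer index, see [month_index()]), `age`,
#'   `smoking`, `bmi`, `hypertension`, `season`, `year`.
#' @export
simulate_covariates <- function(ped, config = sim_config()) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "covariates"))
  n <- nrow(ped)
  first <- month_index(config$exam_start[1], config$exam_start[2])
  last <- month_index(config$exam_end[1], config$exam_end[2])
  exam_month <- sample(first:last, n, replace = TRUE)

  gen_name <- c("founder", "child", "grandchild")[pmin(ped$generation, 3L)]
  age <- stats::rnorm(n, config$age_means[gen_name], config$age_sds[gen_name])
  age <- pmax(age, config$min_age)

  smoking <- rep("never", n)
  men <- ped$sex == "M"
  u <- stats::runif(n)
  pc <- config$smoking_male[["current"]]
  pe <- config$smoking_male[["ever"]]
  smoking[men & u < pc] <- "current"
  smoking[men & u >= pc & u < pc + pe] <- "ever"

  data.frame(
    id = ped$id,
    family = ped$family,
    sex = factor(ped$sex, levels = c("M", "F")),
    exam_month = exam_month,
    age = round(age, 1),
    smoking = factor(smoking, levels = c("never", "ever", "current")),
    bmi = round(stats::rnorm(n, config$bmi_mean[ped$sex],
                             config$bmi_sd[ped$sex]), 1),
    hypertension = as.integer(stats::runif(n) < config$hypertension_prev),
    season = month_season(exam_month),
    year = factor(month_year(exam_month)),
    stringsAsFactors = FALSE)
}

#' Simulate monthly residential exposure series
#'
#' Generates, for every pedigree member and pollutant, a contiguous monthly
#' concentration series from `history_months` before the first possible exam
#' month through the month before the last possible exam month.  Each series
#' is a residence-level mean (shared within family up to individual jitter;
#' the underlying spatial deviate is shared across pollutants), plus an
#' annual sinusoid, plus independent monthly noise:
#' \deqn{x_{im} = \mu + \sigma_r z_{fam} + \sigma_j z_i +
#'       a \cos(2\pi (m - m_{peak})/12) + \epsilon_{im}.}
#' Because the sinusoid has a 12-month period it cancels exactly in any
#' 12-month moving average, so the moving-average mean and SD are governed
#' by `mean` and by `residence_sd`, `jitter_sd` and `monthly_noise_sd`.
#'
#' @param ped pedigree data frame.
#' @param config a [sim_config()] object.
#' @return long-format exposure panel: `id`, `month` (integer index),
#'   `pollutant`, `conc` (ug/m^3).
#' @export
simulate_exposures <- function(ped, config = sim_config()) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "exposures"))
  first_exam <- month_index(config$exam_start[1], config$exam_start[2])
  last_exam <- month_index(config$exam_end[1], config$exam_end[2])
  months <- (first_exam - config$history_months):(last_exam - 1L)
  n <- nrow(ped)
  nm <- length(months)

  fam <- factor(ped$family)
  z_fam_raw <- stats::rnorm(nlevels(fam))[as.integer(fam)]
  z_ind_raw <- stats::rnorm(n)
  # shared monthly deviate: pollutant series are correlated because fine
  # particles make up most of the coarse-fraction mass
  rho <- config$cross_pollutant_cor
  z_shared <- matrix(stats::rnorm(n * nm), n, nm)

  out <- vector("list", length(config$pollutants))
  for (j in seq_along(config$pollutants)) {
    pol <- names(config$pollutants)[j]
    pp <- config$pollutants[[j]]
    res_mean <- pp$mean + pp$residence_sd * z_fam_raw + pp$jitter_sd * z_ind_raw
    seas <- pp$seasonal_amplitude *
      cos(2 * pi * (month_of_year(months) - pp$peak_month) / 12)
    z_own <- matrix(stats::rnorm(n * nm), n, nm)
    noise <- pp$monthly_noise_sd *
      (rho * z_shared + sqrt(1 - rho^2) * z_own)
    conc <- outer(res_mean, seas, `+`) + noise
    conc <- pmax(conc, 0.01)
    out[[j]] <- data.frame(
      id = rep(ped$id, times = nm),
      month = rep(months, each = n),
      pollutant = pol,
      conc = as.vector(conc),
      stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  panel
}

#' Simulate vascular outcomes on a covariate table
#'
#' Draws the FMD-determining linear predictor from the configured fixed
#' effects, the true monthly lag weights applied to normalized lag
#' exposures, a polygenic effect `g ~ N(0, polygenic_variance * A)` (A from
#' [kinship_matrix()]) and residual noise, then back-computes raw vascular
#' measurements: baseline diameter `bad_mm` is drawn around sex-specific
#' means and the maximum post-occlusion diameter `maxad_mm` is set so that
#' [fmd_percent()] reproduces the simulated FMD exactly.  Pre/post occlusive
#' velocities are drawn from sex-specific truncated normals.
#'
#' @param ped pedigree data frame.
#' @param panel exposure panel from [simulate_exposures()].
#' @param covariates covariate table from [simulate_covariates()].
#' @param config a [sim_config()] object.
#' @param A optional precomputed [kinship_matrix()] of `ped`, useful when
#'   simulating many outcome replicates on one pedigree.
#' @return `covariates` with added columns `bad_mm`, `maxad_mm`,
#'   `pre_velocity`, `post_velocity`, plus the latent `true_fmd` and
#'   polygenic effect `g` (kept for validation; the analysis pipeline never
#'   reads them).
#' @export
simulate_outcomes <- function(ped, panel, covariates, config = sim_config(),
                              A = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "outcomes"))
  stopifnot(identical(as.character(covariates$id), as.character(ped$id)))
  n <- nrow(covariates)

  lm_raw <- build_lag_matrix(panel, covariates, L = config$lag_window,
                             pollutant = config$outcome_pollutant)
  z <- normalize_lag_matrix(lm_raw)
  expo_term <- as.vector(z %*% config$true_lag_weights)

  be <- config$covariate_effects
  eff <- function(nm) if (nm %in% names(be)) be[[nm]] else 0
  female <- as.integer(covariates$sex == "F")
  eta <- eff("intercept") +
    eff("age") * covariates$age +
    eff("sexF") * female +
    eff("age_sexF") * covariates$age * female +
    eff("smoking_ever") * (covariates$smoking == "ever") +
    eff("smoking_current") * (covariates$smoking == "current") +
    eff("bmi") * covariates$bmi +
    eff("hypertension") * covariates$hypertension +
    eff("season_spring") * (covariates$season == "spring") +
    eff("season_summer") * (covariates$season == "summer") +
    eff("season_autumn") * (covariates$season == "autumn")
  for (yr in levels(covariates$year)) {
    nm <- paste0("year", yr)
    if (nm %in% names(be)) eta <- eta + be[[nm]] * (covariates$year == yr)
  }

  bad <- stats::rnorm(n, config$bad_mean[as.character(covariates$sex)],
                      config$bad_sd[as.character(covariates$sex)])
  bad <- pmax(bad, 1.5)
  eta <- eta + eff("bad") * bad

  if (is.null(A)) A <- kinship_matrix(ped)
  g <- draw_polygenic(A, config$polygenic_variance)
  e <- stats::rnorm(n, 0, sqrt(config$residual_variance))
  fmd <- eta + expo_term + g + e

  maxad <- bad * (1 + fmd / 100)
  if (any(maxad <= 0))
    stop("simulated FMD below -100% produced non-positive MaxAD; ",
         "check covariate_effects and variance settings")
  post_v <- truncnorm(n, config$post_vel_mean[as.character(covariates$sex)],
                      config$post_vel_sd[as.character(covariates$sex)], 1)
  pre_v <- truncnorm(n, config$pre_vel_mean[as.character(covariates$sex)],
                     config$pre_vel_sd[as.character(covariates$sex)], 0)

  out <- covariates
  out$bad_mm <- bad
  out$maxad_mm <- maxad
  out$pre_velocity <- pre_v
  out$post_velocity <- post_v
  out$true_fmd <- fmd
  out$g <- g
  out
}

# Multivariate normal draw with covariance v * A via Cholesky; adds a tiny
# diagonal jitter when A is numerically rank deficient (e.g. exchangeable
# family blocks).
draw_polygenic <- function(A, v) {
  n <- nrow(A)
  if (v == 0) return(numeric(n))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(A + diag(1e-8, n)), error = function(e) NULL)
    if (is.null(ch))
      stop("polygenic covariance is not positive semidefinite; ",
           "add diagonal jitter to the relationship matrix")
  }
  sqrt(v) * as.vector(crossprod(ch, stats::rnorm(n)))
}

truncnorm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
    bad <- x < lower
  }
  x
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper running [generate_pedigree()],
#' [simulate_covariates()], [simulate_exposures()] and
#' [simulate_outcomes()] in sequence.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `pedigree`, `cohort` (covariates + vascular
#'   measurements), `panel` (monthly exposures), `A` (additive relationship
#'   matrix) and `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_families = 4, seed = 7))
#' head(sim$cohort[, c("id", "sex", "age", "bad_mm", "maxad_mm")])
#' @export
simulate_cohort <- function(config = sim_config()) {
  ped <- generate_pedigree(config)
  cov <- simulate_covariates(ped, config)
  panel <- simulate_exposures(ped, config)
  cohort <- simulate_outcomes(ped, panel, cov, config)
  list(pedigree = ped, cohort = cohort, panel = panel,
       A = kinship_matrix(ped), config = config)
}
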