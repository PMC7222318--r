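#' Model specification for the polygenic mixed model
#'
#' Describes one regression: the outcome column, the exposure term(s)
#' (a moving-average z-score or the reduced PDL regressors), the covariate
#' adjustment set, and optional interaction terms.  The default adjustment
#' set is the fully adjusted specification used throughout the package:
#' age, sex, age-by-sex, smoking, BMI, season of exam, calendar year of
#' exam, hypertension, and baseline brachial artery diameter.
#'
#' Factor covariates that are constant within the analysis data (e.g.
#' smoking in a women-only stratum, where everyone is a never-smoker) are
#' dropped automatically at fit time.
#'
#' @param outcome outcome column name (`"fmd_pct"`, `"shear"`, or
#'   `"shear_response"`).
#' @param exposure character vector of exposure design column names present
#'   in the data at fit time.
#' @param covariates character vector of adjustment terms (formula syntax).
#' @param interactions optional character vector of extra interaction terms.
#' @param include_bad include baseline diameter `bad_mm` in the adjustment
#'   set?
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome = "fmd_pct",
                       exposure = character(),
                       covariates = default_covariates(),
                       interactions = NULL,
                       include_bad = TRUE) {
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, interactions = interactions,
                 include_bad = include_bad),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_covariates <- function() {
  c("age", "sex", "age:sex", "smoking", "bmi", "season", "year",
    "hypertension", "bad_mm")
}

# Assemble the fixed-effects design matrix for a spec on given data.
# Constant factors/columns are dropped (with a message) so stratified fits
# remain estimable; a genuinely rank-deficient design is an error naming
# the offending columns.
build_design <- function(spec, data) {
  covs <- spec$covariates
  if (!spec$include_bad) covs <- setdiff(covs, "bad_mm")
  data <- droplevels(data)

  base_vars <- unique(unlist(strsplit(covs, ":", fixed = TRUE)))
  miss <- setdiff(base_vars, names(data))
  if (length(miss)) stop("data lacks covariate column(s): ",
                         paste(miss, collapse = ", "))
  constant <- vapply(base_vars, function(v) {
    x <- data[[v]]
    if (is.factor(x)) nlevels(x) < 2 else length(unique(x)) < 2
  }, logical(1))
  if (any(constant)) {
    dropped <- base_vars[constant]
    covs <- covs[!vapply(covs, function(tr) {
      any(strsplit(tr, ":", fixed = TRUE)[[1]] %in% dropped)
    }, logical(1))]
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  }

  miss <- setdiff(spec$exposure, names(data))
  if (length(miss)) stop("data lacks exposure column(s): ",
                         paste(miss, collapse = ", "))
  rhs <- c(covs, spec$exposure, spec$interactions)
  form <- if (length(rhs)) stats::reformulate(rhs) else ~1
  X <- stats::model.matrix(form, data)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Precompute the eigendecomposition of a relationship matrix
#'
#' [fit_polygenic_lmm()] works in the eigenbasis of the additive
#' relationship matrix A, where the covariance
#' \eqn{\sigma^2_g A + \sigma^2_e I} becomes diagonal and the restricted
#' likelihood can be profiled down to a one-dimensional search over the
#' variance ratio.  When many models are fitted on the same pedigree (a
#' window scan, the six PDL orders, simulation replicates) the
#' decomposition should be computed once and reused.
#'
#' @param A symmetric positive semidefinite relationship matrix with
#'   individual ids as dimnames.
#' @return object of class `kinship_eigen` with elements `U` (eigenvectors),
#'   `d` (eigenvalues, clamped at zero) and `ids`.
#' @export
kinship_eigen <- function(A) {
  if (inherits(A, "kinship_eigen")) return(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("A must be symmetric")
  ed <- eigen(A, symmetric = TRUE)
  if (min(ed$values) < -1e-6 * max(abs(ed$values)))
    stop("relationship matrix is not positive semidefinite ",
         "(most negative eigenvalue ", signif(min(ed$values), 3), ")")
  structure(list(U = ed$vectors, d = pmax(ed$values, 0), ids = rownames(A)),
            class = "kinship_eigen")
}

# Profiled deviance for the variance ratio delta = sigma2_g / sigma2_e,
# computed in the eigenrotated basis.  criterion = "reml" or "ml".
profile_deviance <- function(yt, Xt, d, delta, criterion) {
  v <- delta * d + 1
  w <- 1 / v
  Xw <- Xt * w
  G <- crossprod(Xt, Xw)
  cG <- tryCatch(chol(G), error = function(e)
    stop("design matrix singular at delta = ", signif(delta, 3)))
  b <- backsolve(cG, forwardsolve(t(cG), crossprod(Xw, yt)))
  r <- yt - Xt %*% b
  rss <- sum(w * r^2)
  n <- length(yt)
  p <- ncol(Xt)
  ldv <- sum(log(v))
  crit <- if (criterion == "reml") {
    (n - p) * log(rss) + ldv + 2 * sum(log(diag(cG)))
  } else {
    n * log(rss) + ldv
  }
  list(crit = crit, beta = drop(b), rss = rss, cG = cG, ldv = ldv)
}

# Deterministic 1-D optimization of the profiled deviance: coarse log grid
# (plus the delta = 0 boundary) followed by golden-section refinement.
optimize_delta <- function(yt, Xt, d, criterion) {
  grid <- c(0, exp(seq(log(1e-4), log(1e4), length.out = 61)))
  crit <- vapply(grid, function(dl)
    profile_deviance(yt, Xt, d, dl, criterion)$crit, numeric(1))
  i <- which.min(crit)
  if (i == 1) {
    # boundary: compare against a refinement just above zero
    op <- stats::optimize(function(ld)
      profile_deviance(yt, Xt, d, exp(ld), criterion)$crit,
      interval = log(c(1e-8, grid[2])), tol = 1e-10)
    if (op$objective < crit[1]) exp(op$minimum) else 0
  } else {
    lo <- grid[max(i - 1, 2)]
    hi <- grid[min(i + 1, length(grid))]
    op <- stats::optimize(function(ld)
      profile_deviance(yt, Xt, d, exp(ld), criterion)$crit,
      interval = log(c(lo, hi)), tol = 1e-10)
    best <- exp(op$minimum)
    if (op$objective <= crit[i]) best else grid[i]
  }
}

#' Fit a polygenic linear mixed model
#'
#' Fits \eqn{y \sim N(X\beta,\; \sigma^2_g A + \sigma^2_e I)} where A is the
#' pedigree-derived additive relationship matrix (or an exchangeable family
#' block matrix).  After a single rotation into the eigenbasis of A the
#' covariance is diagonal in the variance ratio
#' \eqn{\delta = \sigma^2_g/\sigma^2_e}; \eqn{\beta} and \eqn{\sigma^2_e}
#' are profiled out and \eqn{\delta} is found by a deterministic
#' one-dimensional search (log-spaced grid plus refinement, no random
#' starts).  Variance components are estimated by REML; a parallel ML fit
#' supplies the maximized log-likelihood and BIC used for Bayesian model
#' averaging across distributed-lag orders (ML, not REML, because BMA
#' compares models with different fixed effects).
#'
#' Inference on the fixed effects is large-sample Wald: `p = 2 * pnorm(-|z|)`
#' and 95% intervals `beta +/- 1.96 se`.
#'
#' @param spec a [model_spec()].
#' @param data cohort data frame; must contain the outcome, covariate and
#'   exposure columns.  If the outcome column is absent but the raw
#'   vascular columns are present, [add_vascular_metrics()] is applied
#'   first.
#' @param A relationship matrix aligned to (or subsettable by) `data$id`,
#'   or a precomputed [kinship_eigen()] object for repeated fits.
#' @param se_variance which variance-component estimates to use for the
#'   fixed-effect covariance; REML (default) is standard.
#' @param fix_delta optionally fix the variance ratio
#'   \eqn{\delta = \sigma^2_g/\sigma^2_e} instead of estimating it:
#'   `fix_delta = 0` constrains the polygenic variance to zero (the fit
#'   then reduces to ordinary least squares), and any positive value gives
#'   the generalized least squares fit at that known ratio.
#' @return an object of class `lmm_fit`: coefficient table (`coef`),
#'   variance components, ML/REML log-likelihoods, BIC, sample size, and
#'   the REML covariance of the coefficients (`vcov`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_families = 8, seed = 3))
#' coh <- add_vascular_metrics(sim$cohort)
#' ma <- moving_average(sim$panel, coh, 12, "PM2.5")
#' coh$pm_z <- normalize_exposure(ma)$z
#' fit <- fit_polygenic_lmm(model_spec(exposure = "pm_z"), coh, sim$A)
#' wald_test(fit, "pm_z")
#' @export
fit_polygenic_lmm <- function(spec, data, A,
                              se_variance = c("reml", "ml"),
                              fix_delta = NULL) {
  se_variance <- match.arg(se_variance)
  if (!spec$outcome %in% names(data) &&
      all(c("bad_mm", "maxad_mm", "post_velocity") %in% names(data)))
    data <- add_vascular_metrics(data)
  if (!spec$outcome %in% names(data))
    stop("outcome column '", spec$outcome, "' not found")

  ke <- align_kinship(A, data)
  y <- data[[spec$outcome]]
  if (anyNA(y)) stop("outcome contains missing values")
  X <- build_design(spec, data)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("more coefficients (", p, ") than observations (", n, ")")

  yt <- crossprod(ke$U, y)
  Xt <- crossprod(ke$U, X)

  delta_reml <- if (is.null(fix_delta)) optimize_delta(yt, Xt, ke$d, "reml")
                else fix_delta
  fr <- profile_deviance(yt, Xt, ke$d, delta_reml, "reml")
  sigma2_e <- fr$rss / (n - p)
  sigma2_g <- delta_reml * sigma2_e

  delta_ml <- if (is.null(fix_delta)) optimize_delta(yt, Xt, ke$d, "ml")
              else fix_delta
  fm <- profile_deviance(yt, Xt, ke$d, delta_ml, "ml")
  s2_ml <- fm$rss / n
  loglik_ml <- -0.5 * (n * log(2 * pi * s2_ml) + fm$ldv + n)
  loglik_reml <- -0.5 * ((n - p) * log(2 * pi * sigma2_e) + fr$ldv +
                           2 * sum(log(diag(fr$cG))) + (n - p))
  k_par <- p + 2  # fixed effects + two variance components
  bic <- -2 * loglik_ml + k_par * log(n)

  use <- if (se_variance == "reml") list(f = fr, s2 = sigma2_e)
         else list(f = fm, s2 = s2_ml)
  Ginv <- chol2inv(use$f$cG)
  vc <- use$s2 * Ginv
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(use$f$beta, colnames(X))
  se <- sqrt(diag(vc))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  coef_tab <- data.frame(term = colnames(X), estimate = beta, se = se,
                         z = z, p = pval,
                         ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                         row.names = NULL, stringsAsFactors = FALSE)

  structure(list(coef = coef_tab, vcov = vc,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 delta = delta_reml, delta_ml = delta_ml,
                 sigma2_g_ml = delta_ml * s2_ml, sigma2_e_ml = s2_ml,
                 loglik = loglik_ml, loglik_reml = loglik_reml,
                 bic = bic, n = n, p = p, spec = spec),
            class = "lmm_fit")
}

# Reorder/subset a relationship matrix (or check a kinship_eigen) to match
# the data rows.
align_kinship <- function(A, data) {
  ids <- as.character(data$id)
  if (inherits(A, "kinship_eigen")) {
    if (!is.null(A$ids) && !is.null(ids) &&
        !identical(as.character(A$ids), ids))
      stop("precomputed kinship_eigen does not match data rows; ",
           "pass the relationship matrix itself for subsetting")
    if (length(A$d) != nrow(data))
      stop("kinship_eigen dimension (", length(A$d),
           ") does not match data rows (", nrow(data), ")")
    return(A)
  }
  if (!is.null(rownames(A)) && !is.null(data$id)) {
    miss <- setdiff(ids, rownames(A))
    if (length(miss)) stop("relationship matrix lacks individuals: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  } else if (nrow(A) != nrow(data)) {
    stop("relationship matrix dimension does not match data rows")
  }
  kinship_eigen(A)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Polygenic linear mixed model (", x$spec$outcome, "), n = ", x$n,
      "\n", sep = "")
  cat(sprintf("  variance components (REML): polygenic %.3f, residual %.3f (h2 = %.3f)\n",
              x$sigma2_g, x$sigma2_e,
              x$sigma2_g / (x$sigma2_g + x$sigma2_e)))
  cat(sprintf("  logLik (ML) %.2f | BIC %.2f\n", x$loglik, x$bic))
  printCoefmat(
    data.frame(Estimate = x$coef$estimate, `Std.Err` = x$coef$se,
               z = x$coef$z, `p` = x$coef$p, row.names = x$coef$term,
               check.names = FALSE),
    P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Wald test for one fixed-effect term
#'
#' Two-sided large-sample Wald inference: `z = estimate/se`,
#' `p = 2 * pnorm(-|z|)`, 95% CI `estimate +/- 1.96 se`.
#'
#' @param fit an [fit_polygenic_lmm()] result.
#' @param term coefficient name as it appears in `fit$coef$term`.
#' @return one-row data frame with `term`, `estimate`, `se`, `z`, `p`,
#'   `ci_lo`, `ci_hi`.
#' @export
wald_test <- function(fit, term) {
  i <- match(term, fit$coef$term)
  if (is.na(i)) stop("term '", term, "' not in fit; available: ",
                     paste(fit$coef$term, collapse = ", "))
  fit$coef[i, , drop = FALSE]
}

#' Scan effect-modification interaction terms
#'
#' Refits the base model augmented, one at a time, with each candidate
#' interaction: exposure-by-age, exposure-by-sex, and
#' exposure-by-sex-by-age-group (age dichotomized at `age_cut`); the
#' age-by-sex interaction is already part of the adjustment set.  Fit
#' failures for individual terms are recorded and the scan continues.
#'
#' @param spec base [model_spec()] whose first exposure term is scanned.
#' @param data,A as in [fit_polygenic_lmm()].
#' @param age_cut age threshold (years) for the age-group interaction.
#' @param terms optional named character vector of interaction terms to
#'   scan instead of the defaults.
#' @return data frame with one row per interaction coefficient: the
#'   interaction label, term name, estimate, se, p, 95% CI, and a
#'   `significant` flag at p < 0.05; failed fits carry the error message.
#' @export
interaction_scan <- function(spec, data, A, age_cut = 50, terms = NULL) {
  if (!length(spec$exposure)) stop("spec has no exposure term to scan")
  expo <- spec$exposure[1]
  data$age_group <- factor(ifelse(data$age < age_cut,
                                  paste0("lt", age_cut),
                                  paste0("ge", age_cut)),
                           levels = paste0(c("lt", "ge"), age_cut))
  candidates <- if (!is.null(terms)) terms else
    c(exposure_by_age = paste0(expo, ":age"),
      exposure_by_sex = paste0(expo, ":sex"),
      exposure_by_sex_by_age_group = paste0(expo, ":sex:age_group"))
  base_fit <- fit_polygenic_lmm(spec, data, A)
  base_terms <- base_fit$coef$term

  rows <- list()
  for (lab in names(candidates)) {
    term <- candidates[[lab]]
    aug <- spec
    aug$interactions <- c(spec$interactions, term)
    res <- tryCatch({
      fit <- fit_polygenic_lmm(aug, data, A)
      new <- setdiff(fit$coef$term, base_terms)
      tb <- fit$coef[fit$coef$term %in% new, , drop = FALSE]
      cbind(interaction = lab, tb,
            significant = tb$p < 0.05, error = NA_character_)
    }, error = function(e) {
      data.frame(interaction = lab, term = term, estimate = NA_real_,
                 se = NA_real_, z = NA_real_, p = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, significant = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[lab]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified model fits
#'
#' Refits the model within strata defined by sex and by age group (the
#' default mirrors an all/men/women by age < 50 / >= 50 layout).  The
#' relationship matrix is subset to stratum members (relatedness is a
#' property of the pedigree, so it is never re-derived), and constant
#' covariates — notably smoking in women-only strata, where all women are
#' never-smokers — are dropped automatically.  Empty or unestimable strata
#' are skipped with a warning.
#'
#' @param spec a [model_spec()].
#' @param data,A as in [fit_polygenic_lmm()]; `A` must be the matrix (not a
#'   precomputed eigendecomposition) so it can be subset.
#' @param strata named list of logical indexing functions of the data, or
#'   NULL for the default sex-by-age layout.
#' @param age_cut age threshold for the default strata.
#' @return list with `fits` (named list of `lmm_fit`) and `table` (tidy
#'   per-stratum summary of the exposure terms).
#' @export
stratified_fits <- function(spec, data, A, strata = NULL, age_cut = 50) {
  if (inherits(A, "kinship_eigen"))
    stop("pass the relationship matrix itself so strata can be subset")
  if (is.null(strata)) {
    strata <- list(
      all = function(d) rep(TRUE, nrow(d)),
      men = function(d) d$sex == "M",
      women = function(d) d$sex == "F",
      age_lt = function(d) d$age < age_cut,
      age_ge = function(d) d$age >= age_cut,
      men_lt = function(d) d$sex == "M" & d$age < age_cut,
      men_ge = function(d) d$sex == "M" & d$age >= age_cut,
      women_lt = function(d) d$sex == "F" & d$age < age_cut,
      women_ge = function(d) d$sex == "F" & d$age >= age_cut)
    names(strata) <- sub("_lt$", paste0("_lt", age_cut),
                         sub("_ge$", paste0("_ge", age_cut), names(strata)))
  }
  fits <- list()
  rows <- list()
  for (s in names(strata)) {
    keep <- strata[[s]](data)
    if (!any(keep)) {
      warning("stratum '", s, "' is empty; skipped")
      next
    }
    sub <- droplevels(data[keep, , drop = FALSE])
    res <- tryCatch(fit_polygenic_lmm(spec, sub, A), error = function(e) e)
    if (inherits(res, "error")) {
      warning("stratum '", s, "' failed: ", conditionMessage(res))
      next
    }
    fits[[s]] <- res
    tb <- res$coef[res$coef$term %in% spec$exposure, , drop = FALSE]
    if (nrow(tb)) rows[[s]] <- cbind(stratum = s, n = res$n, tb)
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(table)) rownames(table) <- NULL
  list(fits = fits, table = table)
}
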