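#' Averaging-period (moving-average window) scan
#'
#' Fits one fully adjusted polygenic mixed model per candidate averaging
#' window, with the normalized window moving average as the exposure term,
#' and selects the window with the largest absolute exposure coefficient.
#' Ties are broken toward the shorter (more parsimonious) window; with
#' `windows` sorted ascending this is automatic because the first maximum
#' wins.
#'
#' @param data cohort table (covariates + vascular columns + `exam_month`).
#' @param panel long exposure panel.
#' @param A relationship matrix (or [kinship_eigen()] if no subsetting is
#'   needed).
#' @param pollutant pollutant name.
#' @param spec base [model_spec()]; its exposure slot is replaced by the
#'   scanned moving-average term.
#' @param windows candidate averaging windows in months.
#' @return object of class `window_scan`: a per-window table (window, beta,
#'   se, p, ci, log-likelihood, BIC, exposure mean/SD used for
#'   normalization), the selected window, and the per-window fits.
#' @export
window_scan <- function(data, panel, A, pollutant = "PM2.5",
                        spec = model_spec(),
                        windows = c(1, 6, 12, 24, 36, 60, 84)) {
  windows <- sort(unique(windows))
  ke <- if (inherits(A, "kinship_eigen")) A else kinship_eigen(A)
  fits <- list()
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[i]
    ma <- moving_average(panel, data, w, pollutant)
    nz <- normalize_exposure(ma)
    d <- data
    d$pm_z <- nz$z
    sp <- spec
    sp$exposure <- "pm_z"
    fit <- fit_polygenic_lmm(sp, d, ke)
    fits[[as.character(w)]] <- fit
    wt <- wald_test(fit, "pm_z")
    rows[[i]] <- data.frame(pollutant = pollutant, window = w,
                            estimate = wt$estimate, se = wt$se, p = wt$p,
                            ci_lo = wt$ci_lo, ci_hi = wt$ci_hi,
                            loglik = fit$loglik, bic = fit$bic,
                            exposure_mean = nz$mean, exposure_sd = nz$sd,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  sel <- tab$window[which.max(abs(tab$estimate))]
  structure(list(table = tab, selected_window = sel, fits = fits,
                 pollutant = pollutant), class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("Moving-average window scan for", x$pollutant, "\n")
  print(x$table[, c("window", "estimate", "se", "p", "ci_lo", "ci_hi")],
        row.names = FALSE, digits = 3)
  cat("selected window (largest |beta|):", x$selected_window, "months\n")
  invisible(x)
}

#' Fit the set of polynomial distributed-lag mixed models
#'
#' For each polynomial order (0 through 5 by default) the adjusted
#' polygenic mixed model is refitted with the reduced PDL regressors in
#' place of the moving-average term.  Monthly lag coefficients are
#' reconstructed from the fitted polynomial coefficients,
#' `beta_lag = B theta`, with covariance `B Cov(theta) B'`.  The order-0
#' model's single regressor is the row mean of the normalized lag matrix —
#' the normalized moving average itself — so its coefficient, standard
#' error and log-likelihood coincide exactly with the moving-average
#' model's.
#'
#' @param data cohort table.
#' @param lagz normalized `n x L` lag matrix from [normalize_lag_matrix()].
#' @param A relationship matrix or [kinship_eigen()].
#' @param spec base [model_spec()] (exposure slot is replaced).
#' @param orders integer vector of polynomial orders.
#' @param type PDL basis type, see [pdl_basis()].
#' @return list of class `pdl_set`: per-order `lmm_fit`s augmented with
#'   `theta`, `lag_beta` (L monthly coefficients), `lag_vcov` and `order`.
#' @export
fit_pdl_set <- function(data, lagz, A, spec = model_spec(), orders = 0:5,
                        type = c("raw", "orthogonal")) {
  type <- match.arg(type)
  L <- ncol(lagz)
  if (any(orders >= L)) stop("PDL order must be below the number of lags (",
                             L, "); offending order(s): ",
                             paste(orders[orders >= L], collapse = ", "))
  ke <- if (inherits(A, "kinship_eigen")) A else kinship_eigen(A)
  fits <- vector("list", length(orders))
  names(fits) <- paste0("order", orders)
  for (i in seq_along(orders)) {
    k <- orders[i]
    Xk <- pdl_design(lagz, k, type)
    B <- attr(Xk, "basis")
    d <- cbind(data, as.data.frame(Xk))
    sp <- spec
    sp$exposure <- colnames(Xk)
    fit <- tryCatch(fit_polygenic_lmm(sp, d, ke), error = function(e)
      stop("PDL order ", k, " could not be fitted: ", conditionMessage(e)))
    idx <- match(colnames(Xk), fit$coef$term)
    theta <- fit$coef$estimate[idx]
    ctheta <- fit$vcov[colnames(Xk), colnames(Xk), drop = FALSE]
    fit$order <- k
    fit$theta <- stats::setNames(theta, colnames(Xk))
    fit$basis <- B
    fit$lag_beta <- unname(drop(B %*% theta))
    fit$lag_vcov <- B %*% ctheta %*% t(B)
    fits[[i]] <- fit
  }
  structure(fits, class = "pdl_set", L = L)
}

#' Bayesian model averaging over PDL orders
#'
#' Combines the distributed-lag fits with BIC-approximated posterior model
#' probabilities under equal prior weights,
#' \deqn{P(M_k \mid y) = \frac{\exp(-BIC_k/2)}{\sum_j \exp(-BIC_j/2)},}
#' computed stably by shifting with the smallest BIC (log-sum-exp).  The
#' averaged monthly lag coefficients are the probability-weighted mixture
#' of the per-order reconstructions; their uncertainty combines
#' within-model variance and between-model spread (the standard BMA
#' mixture variance).  An AIC-weight variant is available.
#'
#' @param fits a `pdl_set` from [fit_pdl_set()].
#' @param weights `"bic"` (default) or `"aic"`.
#' @return object of class `bma_result`: `posterior` table (order, loglik,
#'   bic, posterior probability), `lag_beta` and `lag_se` (12 monthly
#'   values), `cumulative` and `cumulative_se`, and the input fits.
#' @export
bma_average <- function(fits, weights = c("bic", "aic")) {
  weights <- match.arg(weights)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("PDL fits were computed on different sample sizes: ",
         paste(unique(ns), collapse = ", "))
  ic <- switch(weights,
               bic = vapply(fits, function(f) f$bic, numeric(1)),
               aic = vapply(fits, function(f)
                 -2 * f$loglik + 2 * (f$p + 2), numeric(1)))
  lw <- -0.5 * (ic - min(ic))
  prob <- exp(lw) / sum(exp(lw))

  L <- attr(fits, "L")
  betas <- vapply(fits, function(f) f$lag_beta, numeric(L))
  avg <- drop(betas %*% prob)
  within <- vapply(fits, function(f) diag(f$lag_vcov), numeric(L))
  var_mix <- drop(within %*% prob) + drop((betas - avg)^2 %*% prob)

  cums <- colSums(betas)
  cum_avg <- sum(avg)
  cum_within <- vapply(fits, function(f) sum(f$lag_vcov), numeric(1))
  cum_var <- sum(prob * (cum_within + (cums - cum_avg)^2))

  posterior <- data.frame(
    order = vapply(fits, function(f) f$order, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    ic = ic, posterior_prob = prob, row.names = NULL)
  names(posterior)[3] <- weights

  structure(list(posterior = posterior, lag_beta = avg,
                 lag_se = sqrt(var_mix), cumulative = cum_avg,
                 cumulative_se = sqrt(cum_var), weights = weights,
                 fits = fits), class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("Bayesian model averaging over PDL orders (", x$weights,
      " weights)\n", sep = "")
  print(transform(x$posterior, posterior_prob = round(posterior_prob, 4)),
        row.names = FALSE, digits = 6)
  cat(sprintf("cumulative effect over %d lags: %.4f (SE %.4f)\n",
              length(x$lag_beta), x$cumulative, x$cumulative_se))
  invisible(x)
}

#' Model-averaged lag-coefficient profile
#'
#' Exports the BMA result as a plottable 13-row table: one row per monthly
#' lag (lag 1 = month before the exam) with the probability-weighted
#' coefficient and its 95% interval, plus a final row with the cumulative
#' effect over all lags.
#'
#' @param bma a [bma_average()] result.
#' @return data frame with columns `lag` (`"1"..."12"`, `"cumulative"`),
#'   `estimate`, `se`, `ci_lo`, `ci_hi`, `cumulative` (flag).
#' @export
lag_profile <- function(bma) {
  L <- length(bma$lag_beta)
  est <- c(bma$lag_beta, bma$cumulative)
  se <- c(bma$lag_se, bma$cumulative_se)
  data.frame(lag = c(as.character(seq_len(L)), "cumulative"),
             estimate = est, se = se,
             ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
             cumulative = c(rep(FALSE, L), TRUE),
             stringsAsFactors = FALSE)
}
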