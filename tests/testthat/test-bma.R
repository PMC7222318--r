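# PDL fits on the shared small simulation, computed once.
bma_fixture <- function() {
  if (is.null(.fixture_env$bma)) {
    sim <- small_sim()
    coh <- add_vascular_metrics(sim$cohort)
    lagz <- normalize_lag_matrix(
      build_lag_matrix(sim$panel, coh, 12, "PM2.5"))
    ke <- kinship_eigen(sim$A)
    pdl <- fit_pdl_set(coh, lagz, ke)
    .fixture_env$bma <- list(sim = sim, coh = coh, lagz = lagz, ke = ke,
                             pdl = pdl, bma = bma_average(pdl))
  }
  .fixture_env$bma
}

test_that("the order-0 PDL model IS the 12-month moving-average model", {
  fx <- bma_fixture()
  coh <- fx$coh
  ma <- moving_average(fx$sim$panel, coh, 12, "PM2.5")
  coh$pm_z <- normalize_exposure(ma)$z
  f_ma <- fit_polygenic_lmm(model_spec(exposure = "pm_z"), coh, fx$ke)
  w_ma <- wald_test(f_ma, "pm_z")
  f0 <- fx$pdl$order0
  w0 <- f0$coef[f0$coef$term == "pdl0", ]
  expect_equal(w0$estimate, w_ma$estimate, tolerance = 1e-10)
  expect_equal(w0$se, w_ma$se, tolerance = 1e-10)
  expect_equal(f0$loglik, f_ma$loglik, tolerance = 1e-10)
  # and its lag reconstruction spreads the coefficient uniformly
  expect_equal(f0$lag_beta, rep(w0$estimate / 12, 12), tolerance = 1e-10)
})

test_that("ML log-likelihood is non-decreasing in PDL order", {
  fx <- bma_fixture()
  ll <- vapply(fx$pdl, function(f) f$loglik, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("posterior probabilities are a proper, shift-invariant softmax", {
  mk <- function(bics) {
    fits <- lapply(seq_along(bics), function(i) {
      f <- list(bic = bics[i], loglik = -bics[i] / 2, n = 100, p = i,
                order = i - 1, lag_beta = rep(i, 12),
                lag_vcov = diag(0.01, 12))
      f
    })
    names(fits) <- paste0("order", seq_along(bics) - 1)
    attr(fits, "L") <- 12
    class(fits) <- "pdl_set"
    fits
  }
  # identical BICs: uniform posterior
  b <- bma_average(mk(rep(1234.5, 6)))
  expect_equal(b$posterior$posterior_prob, rep(1 / 6, 6))
  expect_equal(sum(b$posterior$posterior_prob), 1)

  # a 20-point BIC advantage is overwhelming
  b2 <- bma_average(mk(c(1000, rep(1020, 5))))
  expect_gt(b2$posterior$posterior_prob[1], 0.99)

  # shifting all BICs by a constant leaves the posterior unchanged,
  # even at magnitudes that would overflow exp(-BIC/2) naively
  b3 <- bma_average(mk(rep(1234.5, 6) + 5e5))
  expect_equal(b3$posterior$posterior_prob, b$posterior$posterior_prob)

  # mismatched sample sizes across fits are rejected
  bad <- mk(rep(10, 6))
  bad$order0$n <- 99
  expect_error(bma_average(bad), "sample sizes")
})

test_that("model-averaged lag coefficients mix estimates and uncertainty", {
  fx <- bma_fixture()
  b <- fx$bma
  prob <- b$posterior$posterior_prob
  betas <- vapply(fx$pdl, function(f) f$lag_beta, numeric(12))
  expect_equal(b$lag_beta, drop(betas %*% prob))
  expect_equal(b$cumulative, sum(b$lag_beta))
  # mixture variance is at least the weighted within-model variance
  within <- drop(vapply(fx$pdl, function(f) diag(f$lag_vcov),
                        numeric(12)) %*% prob)
  expect_true(all(b$lag_se^2 >= within - 1e-12))
})

test_that("order-0 dominance flattens the averaged lag profile", {
  fx <- bma_fixture()
  # rebuild with only the order-0 fit: profile must be exactly flat and
  # each lag equal to cumulative/12
  solo <- fx$pdl["order0"]
  attr(solo, "L") <- 12
  class(solo) <- "pdl_set"
  b <- bma_average(solo)
  expect_equal(b$posterior$posterior_prob, 1)
  expect_equal(max(b$lag_beta) - min(b$lag_beta), 0, tolerance = 1e-12)
  expect_equal(b$lag_beta, rep(b$cumulative / 12, 12), tolerance = 1e-10)
  ma_beta <- wald_test(fx$pdl$order0, "pdl0")$estimate
  expect_equal(b$cumulative, ma_beta, tolerance = 1e-10)

  # and in the full average, the profile spread shrinks with P(order 0)
  full <- fx$bma
  p0 <- full$posterior$posterior_prob[1]
  spread <- max(full$lag_beta) - min(full$lag_beta)
  betas <- vapply(fx$pdl, function(f) f$lag_beta, numeric(12))
  max_model_spread <- max(apply(betas, 2, function(x) max(x) - min(x)))
  expect_lte(spread, (1 - p0) * max_model_spread + 1e-12)
})

test_that("lag profile export is lossless and sums to the cumulative row", {
  fx <- bma_fixture()
  prof <- lag_profile(fx$bma)
  expect_equal(nrow(prof), 13)
  expect_equal(sum(prof$estimate[!prof$cumulative]),
               prof$estimate[prof$cumulative])
  expect_equal(prof$ci_lo, prof$estimate - 1.96 * prof$se)

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(prof, path, row.names = FALSE)
  back <- read.csv(path, colClasses = c(lag = "character"))
  expect_equal(back$estimate, prof$estimate)
  expect_equal(back$lag, prof$lag)
})

test_that("window scan selects deterministically with shortest-wins ties", {
  fx <- bma_fixture()
  coh <- fx$coh
  ws <- window_scan(coh, fx$sim$panel, fx$ke, "PM2.5",
                    windows = c(6, 12, 24))
  expect_setequal(ws$table$window, c(6, 12, 24))
  expect_equal(ws$selected_window,
               ws$table$window[which.max(abs(ws$table$estimate))])
  # single-window scan returns that window
  ws1 <- window_scan(coh, fx$sim$panel, fx$ke, "PM2.5", windows = 12)
  expect_equal(ws1$selected_window, 12)
  # exact tie prefers the shorter window: duplicate a window's MA by
  # scanning the same window twice is not possible, so check the
  # tie-break rule directly on the ordered table
  expect_true(!is.unsorted(ws$table$window))
})

test_that("high PDL orders on degenerate exposure series raise rank errors", {
  fx <- bma_fixture()
  coh <- fx$coh
  lag_const <- fx$lagz
  lag_const[, ] <- rowMeans(fx$lagz)  # every month identical: rank 1
  expect_error(fit_pdl_set(coh, lag_const, fx$ke, orders = 0:2),
               "order 1|alias")
  expect_error(fit_pdl_set(coh, fx$lagz, fx$ke, orders = 12), "below")
})
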