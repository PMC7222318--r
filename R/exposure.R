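#' Date-indexed moving-average exposure
#'
#' Mean of the monthly concentrations over the `window` months strictly
#' before each participant's exam month: lag 1 is the month immediately
#' prior to the exam, so a 12-month window averages lags 1 through 12.  The
#' exam month itself is never included.
#'
#' @param panel long exposure panel (`id`, `month`, `pollutant`, `conc`).
#' @param exam data frame with columns `id` and `exam_month` (integer month
#'   index, see [month_index()]); typically the cohort table.
#' @param window number of months to average over.
#' @param pollutant pollutant name to select from the panel.
#' @return named numeric vector of per-participant means (ug/m^3), in the
#'   row order of `exam`.
#' @export
moving_average <- function(panel, exam, window, pollutant = "PM2.5") {
  lm <- build_lag_matrix(panel, exam, L = window, pollutant = pollutant)
  stats::setNames(rowMeans(lm), rownames(lm))
}

#' Participant-by-lag exposure matrix
#'
#' Column `l` holds each participant's concentration `l` months before the
#' exam month.  Coverage must be complete; gaps raise an error naming the
#' participant and the missing months (no imputation is performed).
#'
#' @inheritParams moving_average
#' @param L number of monthly lags (columns).
#' @return an `n x L` matrix, rownames = participant ids, colnames
#'   `lag1..lagL`.
#' @export
build_lag_matrix <- function(panel, exam, L, pollutant = "PM2.5") {
  stopifnot(all(c("id", "month", "pollutant", "conc") %in% names(panel)),
            all(c("id", "exam_month") %in% names(exam)), L >= 1)
  sub <- panel[panel$pollutant == pollutant, , drop = FALSE]
  if (!nrow(sub)) stop("no panel entries for pollutant '", pollutant, "'")
  key <- paste(sub$id, sub$month, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (id, month) entries in panel")

  ids <- as.character(exam$id)
  want_month <- outer(exam$exam_month, seq_len(L), `-`)
  want_key <- paste(rep(ids, times = L), as.vector(want_month), sep = "\r")
  v <- sub$conc[match(want_key, key)]
  out <- matrix(v, nrow(exam), L,
                dimnames = list(ids, paste0("lag", seq_len(L))))
  if (anyNA(out)) {
    i <- which(rowSums(is.na(out)) > 0)[1]
    miss <- want_month[i, is.na(out[i, ])]
    stop("exposure coverage gap for participant '", ids[i], "': missing ",
         paste(month_label(miss), collapse = ", "))
  }
  out
}

#' Normalize an exposure variable to z-scores
#'
#' Centers by the sample mean and scales by the sample standard deviation
#' (denominator n-1), so downstream effect estimates are per SD of
#' exposure.  The centering constants are returned for later rescaling of
#' effect sizes to concentration increments.
#'
#' @param x numeric vector of per-participant exposures (n >= 2).
#' @return list with `z` (unit-variance z-scores), `mean` and `sd`
#'   (ug/m^3).
#' @seealso [rescale_per_increment()] for converting per-SD effects to
#'   per-increment effects.
#' @export
normalize_exposure <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to normalize")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: exposure cannot be normalized")
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Normalize a lag matrix on the moving-average scale
#'
#' All `L` lag columns are centered and scaled by a single pair of
#' constants: the sample mean and SD of the participants' `L`-month moving
#' average (the row means).  With this common scaling the row mean of the
#' normalized matrix is exactly the normalized moving average, so the
#' order-0 distributed-lag regressor is literally the moving-average
#' z-score and the sum of monthly lag coefficients is the effect of a
#' one-SD increase in the `L`-month moving average.  (Column-wise z-scoring
#' would break both identities because a mean of per-column z-scores has
#' variance below 1.)
#'
#' @param lagmat matrix from [build_lag_matrix()].
#' @return normalized matrix with attributes `center` and `scale` (the
#'   moving-average mean and SD, ug/m^3).
#' @export
normalize_lag_matrix <- function(lagmat) {
  ma <- rowMeans(lagmat)
  m <- mean(ma)
  s <- stats::sd(ma)
  if (s == 0) stop("zero variance: moving average is constant")
  z <- (lagmat - m) / s
  attr(z, "center") <- m
  attr(z, "scale") <- s
  z
}

#' Polynomial distributed-lag basis
#'
#' Maps the `order + 1` polynomial coefficients of a PDL model to `L`
#' monthly lag weights: weight of lag `l` is
#' \eqn{\beta_l = \sum_k \theta_k p_k(l)}.  The constant basis function is
#' `p_0(l) = 1/L`, so the order-0 regressor built from a lag matrix is its
#' row mean — exactly the `L`-month moving average, making the textbook
#' "zero-order model = moving-average model" equivalence literal.  Higher
#' raw basis functions are powers of the lag index rescaled to [0, 1],
#' `p_k(l) = ((l - 1)/(L - 1))^k`; an orthogonal-polynomial variant is
#' available and leaves fitted values (and hence model weights) unchanged.
#'
#' @param L number of monthly lags.
#' @param order polynomial order, `0 <= order <= min(5, L - 1)` for the
#'   usual analysis (any `order < L` is accepted).
#' @param type `"raw"` (default) or `"orthogonal"`.
#' @return an `L x (order + 1)` transform matrix.
#' @export
pdl_basis <- function(L, order, type = c("raw", "orthogonal")) {
  type <- match.arg(type)
  if (order < 0) stop("order must be >= 0")
  if (order >= L) stop("order (", order, ") must be < number of lags (", L, ")")
  B <- matrix(1 / L, L, order + 1,
              dimnames = list(paste0("lag", 1:L), paste0("p", 0:order)))
  if (order > 0) {
    u <- (seq_len(L) - 1) / (L - 1)
    if (type == "raw") {
      for (k in 1:order) B[, k + 1] <- u^k
    } else {
      B[, 2:(order + 1)] <- stats::poly(u, degree = order)
    }
  }
  B
}

#' Reduced PDL design columns from a lag matrix
#'
#' Collapses an `n x L` (normalized) lag matrix to the `order + 1`
#' regressors of a polynomial distributed-lag model:
#' regressor `k` is \eqn{\sum_l x_{il} p_k(l)}.  Fitted polynomial
#' coefficients are mapped back to monthly lag weights with the same basis
#' (`beta_l = B theta`).
#'
#' @param lagmat `n x L` lag matrix (normalized or raw).
#' @inheritParams pdl_basis
#' @return `n x (order + 1)` matrix with columns `pdl0..pdl<order>` and the
#'   basis attached as attribute `"basis"`.
#' @export
pdl_design <- function(lagmat, order, type = c("raw", "orthogonal")) {
  B <- pdl_basis(ncol(lagmat), order, type)
  X <- lagmat %*% B
  colnames(X) <- paste0("pdl", 0:order)
  attr(X, "basis") <- B
  X
}
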