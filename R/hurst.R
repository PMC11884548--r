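#' Orthonormal Haar discrete wavelet transform
#'
#' Pyramidal decomposition with the orthonormal Haar filter
#' (\code{d = (x[2k-1] - x[2k]) / sqrt(2)},
#' \code{a = (x[2k-1] + x[2k]) / sqrt(2)}). When a level has odd length the
#' trailing sample is carried into the final approximation, so the transform
#' conserves energy for any input length.
#'
#' @param series numeric vector.
#' @param n_levels number of detail levels, >= 2.
#' @return list with \code{details} (list of per-level detail coefficient
#'   vectors, finest first) and \code{approx} (coarsest approximation,
#'   including any carried samples).
#' @export
haar_dwt <- function(series, n_levels) {
  if (!is.numeric(series) || any(!is.finite(series)))
    stop_bad_arg("'series' must be finite numeric")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop_bad_arg("'n_levels' must be >= 2")
  if (length(series) < 2^n_levels)
    stop_bad_arg(sprintf("series too short: %d levels need length >= %d",
                         n_levels, 2^n_levels))
  a <- as.numeric(series)
  details <- vector("list", n_levels)
  carried <- numeric(0)
  for (j in seq_len(n_levels)) {
    n <- length(a)
    if (n %% 2L == 1L) {
      carried <- c(carried, a[n])
      a <- a[-n]
      n <- n - 1L
    }
    odd <- a[seq(1L, n, by = 2L)]
    even <- a[seq(2L, n, by = 2L)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(details = details, approx = c(a, carried))
}

default_n_levels <- function(T_len) max(2L, floor(log2(T_len)) - 3L)

level_stats <- function(series, n_levels) {
  dwt <- haar_dwt(series, n_levels)
  nj <- lengths(dwt$details)
  Sj <- vapply(dwt$details, function(d) sum(d^2), numeric(1))
  list(nj = nj, Sj = Sj)
}

#' Hurst exponent by log-variance wavelet regression
#'
#' Independent reference estimator: regresses \code{log2} of the mean squared
#' detail coefficient on the scale index j over \code{[j_min, j_max]}; the
#' slope beta maps to \code{H = (beta + 1)/2}.
#'
#' @param series numeric vector.
#' @param j_min,j_max scale range (finest scale is 1). \code{j_max = NULL}
#'   uses the default number of levels.
#' @return estimated Hurst exponent (scalar).
#' @export
hurst_logvar <- function(series, j_min = 1L, j_max = NULL) {
  if (is.null(j_max)) j_max <- default_n_levels(length(series))
  if (j_max - j_min + 1L < 3L)
    stop_bad_arg("need at least 3 wavelet levels for the regression")
  st <- level_stats(series, j_max)
  j <- j_min:j_max
  nj <- st$nj[j]
  if (any(nj < 8L))
    stop_bad_arg("each regression level needs >= 8 coefficients")
  logvar <- log2(st$Sj[j] / nj)
  beta <- coef(lm(logvar ~ j))[2]
  unname((beta + 1) / 2)
}

#' Hurst exponent by wavelet maximum likelihood
#'
#' Fits the fractionally-integrated-noise wavelet model in which detail
#' coefficients at scale j are independent zero-mean Gaussian with variance
#' \code{sigma2 * 2^(2*d*j)}. The innovation scale \code{sigma2} is profiled
#' out in closed form and the memory parameter d is found by bounded
#' one-dimensional search of the profile log-likelihood. Returns
#' \code{H = d + 0.5}.
#'
#' @param series numeric vector, length >= 256 recommended.
#' @param d_bounds box constraint on the memory parameter d.
#' @param n_levels wavelet levels; default keeps >= 8 coefficients at the
#'   coarsest level.
#' @param normalize mean-center and variance-normalize first (H is invariant
#'   under the model; default TRUE).
#' @return object of class \code{hurst_fit} with fields \code{H}, \code{d},
#'   \code{sigma2}, \code{loglik}, \code{n_levels}, \code{boundary}.
#' @examples
#' fit <- hurst_fin(simulate_fgn(0.7, 2048, seed = 1))
#' coef(fit)
#' @export
hurst_fin <- function(series, d_bounds = c(-0.5, 1.5), n_levels = NULL,
                      normalize = TRUE) {
  if (!is.numeric(series) || any(!is.finite(series)))
    stop_bad_arg("'series' must be finite numeric")
  if (length(d_bounds) != 2L || d_bounds[1] >= d_bounds[2])
    stop_bad_arg("'d_bounds' must be increasing length-2")
  if (is.null(n_levels)) n_levels <- default_n_levels(length(series))
  if (normalize) {
    s <- sd(series)
    if (s == 0) stop_bad_arg("constant series: Hurst exponent undefined")
    series <- (series - mean(series)) / s
  }
  st <- level_stats(series, n_levels)
  j <- seq_len(n_levels)
  M <- sum(st$nj)
  # profile log-likelihood in d (sigma2 profiled out)
  nll <- function(d) {
    sigma2 <- sum(st$Sj * 2^(-2 * d * j)) / M
    0.5 * (M * log(2 * pi * sigma2) + M + 2 * d * log(2) * sum(st$nj * j))
  }
  opt <- optimize(nll, interval = d_bounds, tol = 1e-6)
  d <- opt$minimum
  boundary <- min(d - d_bounds[1], d_bounds[2] - d) < 1e-4
  sigma2 <- sum(st$Sj * 2^(-2 * d * j)) / M
  structure(list(H = d + 0.5, d = d, sigma2 = sigma2,
                 loglik = -opt$objective, n_levels = n_levels,
                 boundary = boundary),
            class = "hurst_fit")
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf(
    "wavelet-ML Hurst fit: H = %.4f (d = %.4f, sigma2 = %.4g, %d levels)%s\n",
    x$H, x$d, x$sigma2, x$n_levels,
    if (x$boundary) " [at optimization bound]" else ""))
  invisible(x)
}

#' @export
coef.hurst_fit <- function(object, ...) {
  c(H = object$H, d = object$d, sigma2 = object$sigma2)
}

#' @export
logLik.hurst_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, class = "logLik")
}

#' Region-wise Hurst exponent map
#'
#' Applies \code{\link{hurst_fin}} to each column of a T x N time-series
#' matrix (each column mean-centered and variance-normalized first).
#' Constant columns yield \code{NA} with a warning.
#'
#' @param ts T x N numeric matrix (regions in columns).
#' @param d_bounds,n_levels passed to \code{\link{hurst_fin}}.
#' @return numeric vector of length N of Hurst exponents (a regional map).
#' @export
hurst_map <- function(ts, d_bounds = c(-0.5, 1.5), n_levels = NULL) {
  check_matrix(ts, "ts")
  if (any(!is.finite(ts))) stop_bad_arg("'ts' contains missing values")
  out <- rep(NA_real_, ncol(ts))
  bad <- logical(ncol(ts))
  for (i in seq_len(ncol(ts))) {
    if (sd(ts[, i]) == 0) { bad[i] <- TRUE; next }
    out[i] <- hurst_fin(ts[, i], d_bounds = d_bounds, n_levels = n_levels)$H
  }
  if (any(bad))
    warning(sprintf("constant series in region(s) %s: H set to NA",
                    paste(which(bad), collapse = ", ")))
  if (!is.null(colnames(ts))) names(out) <- colnames(ts)
  out
}
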