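#' Static functional connectivity
#'
#' Pearson correlation matrix of a T x N time-series matrix.
#'
#' @param ts T x N numeric matrix, no constant columns.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
static_fc <- function(ts) {
  check_matrix(ts, "ts")
  if (nrow(ts) < 2L) stop_bad_arg("'ts' needs at least 2 time points")
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0))
    stop_bad_arg(sprintf("constant time series in region(s) %s",
                         paste(which(sds == 0), collapse = ", ")))
  fc <- cor(ts)
  diag(fc) <- 1
  fc
}

#' Sliding-window functional connectivity dynamics (FCD)
#'
#' Computes windowed FC matrices (windows of \code{window_length} samples,
#' advanced by \code{step}), vectorizes each window's upper triangle, and
#' Pearson-correlates the vectors pairwise. With step 1 and T time points
#' there are \code{T - window_length + 1} windows (695 points and 100-sample
#' windows give the canonical 596 x 596 matrix).
#'
#' @param ts T x N numeric matrix.
#' @param window_length window length in samples (default 100).
#' @param step window increment in samples (default 1).
#' @return object of class \code{fcd}: a W x W symmetric correlation matrix
#'   with unit diagonal and attributes \code{window_length} and \code{step}.
#' @export
sliding_window_fcd <- function(ts, window_length = 100L, step = 1L) {
  check_matrix(ts, "ts")
  T_len <- nrow(ts)
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (T_len < window_length + 1L)
    stop_bad_arg(sprintf("T = %d is too short for window_length = %d",
                         T_len, window_length))
  W <- (T_len - window_length) %/% step + 1L
  N <- ncol(ts)
  starts <- seq(1L, by = step, length.out = W)
  ends <- starts + window_length - 1L
  # windowed first and second moments via cumulative sums
  pad_cumsum <- function(m) rbind(0, apply(m, 2L, cumsum))
  cs1 <- pad_cumsum(ts)
  cs2 <- pad_cumsum(ts^2)
  S1 <- cs1[ends + 1L, , drop = FALSE] - cs1[starts, , drop = FALSE]
  S2 <- cs2[ends + 1L, , drop = FALSE] - cs2[starts, , drop = FALSE]
  sd_w <- sqrt(pmax(S2 - S1^2 / window_length, 0))        # W x N
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  P <- nrow(ut)
  V <- matrix(0, W, P)                                     # window FC rows
  chunk <- max(1L, floor(5e6 / T_len))
  for (b in seq(1L, P, by = chunk)) {
    j <- b:min(b + chunk - 1L, P)
    csp <- pad_cumsum(ts[, ut[j, 1L], drop = FALSE] *
                        ts[, ut[j, 2L], drop = FALSE])
    Sp <- csp[ends + 1L, , drop = FALSE] - csp[starts, , drop = FALSE]
    V[, j] <- (Sp - S1[, ut[j, 1L], drop = FALSE] *
                 S1[, ut[j, 2L], drop = FALSE] / window_length) /
      (sd_w[, ut[j, 1L], drop = FALSE] * sd_w[, ut[j, 2L], drop = FALSE])
  }
  fcd <- cor(t(V))
  diag(fcd) <- 1
  structure(fcd, class = c("fcd", "matrix", "array"),
            window_length = window_length, step = step)
}

#' Empirical CDF of the FCD upper triangle
#'
#' @param fcd an \code{fcd} matrix (or any symmetric W x W matrix, W >= 2).
#' @return object of class \code{fcd_cdf}: list with sorted \code{grid}
#'   values and cumulative probabilities \code{cum}.
#' @export
fcd_cdf <- function(fcd) {
  check_matrix(fcd, "fcd", square = TRUE)
  if (nrow(fcd) < 2L) stop_bad_arg("FCD must be at least 2 x 2")
  v <- sort(fcd[upper.tri(fcd)])
  n <- length(v)
  structure(list(grid = v, cum = seq_len(n) / n), class = "fcd_cdf")
}

#' @export
print.fcd_cdf <- function(x, ...) {
  cat(sprintf("empirical CDF on %d values in [%.3f, %.3f]\n",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

# evaluate a CDF (right-continuous step function) at points x
eval_cdf <- function(cdf, x) {
  idx <- findInterval(x, cdf$grid)
  c(0, cdf$cum)[idx + 1L]
}

#' Group-average functional connectivity
#'
#' Averages FC matrices across subjects after Fisher z-transform, then
#' back-transforms (off-diagonal entries clamped away from +/-1 before
#' \code{atanh}).
#'
#' @param fc_list non-empty list of N x N FC matrices.
#' @return N x N averaged FC with unit diagonal.
#' @export
group_fc <- function(fc_list) {
  if (!is.list(fc_list) || length(fc_list) == 0L)
    stop_bad_arg("'fc_list' must be a non-empty list")
  dims <- vapply(fc_list, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop_bad_arg("FC dimension mismatch")
  z <- lapply(fc_list, function(m) atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)))
  avg <- tanh(Reduce(`+`, z) / length(z))
  diag(avg) <- 1
  avg
}

#' Group-average FCD CDF
#'
#' Evaluates each subject's CDF on a common 1000-point grid over [-1, 1]
#' (linear interpolation) and averages pointwise; the average of CDFs is
#' itself a CDF.
#'
#' @param cdf_list non-empty list of \code{fcd_cdf} objects.
#' @param grid_points grid resolution (default 1000).
#' @return an \code{fcd_cdf} on the common grid.
#' @export
group_fcd_cdf <- function(cdf_list, grid_points = 1000L) {
  if (!is.list(cdf_list) || length(cdf_list) == 0L)
    stop_bad_arg("'cdf_list' must be a non-empty list")
  grid <- seq(-1, 1, length.out = grid_points)
  mats <- vapply(cdf_list, function(cdf) {
    approx(cdf$grid, cdf$cum, xout = grid, method = "linear",
           yleft = 0, yright = 1, ties = "ordered")$y
  }, numeric(grid_points))
  cum <- rowMeans(mats)
  cum <- cummax(pmin(cum, 1))
  cum[grid_points] <- 1
  structure(list(grid = grid, cum = cum), class = "fcd_cdf")
}

#' Kolmogorov-Smirnov distance between two empirical CDFs
#'
#' Sup-norm difference evaluated on the union of the two grids (both CDFs
#' treated as right-continuous step functions).
#'
#' @param cdf_a,cdf_b \code{fcd_cdf} objects.
#' @return KS distance in [0, 1].
#' @export
ks_distance <- function(cdf_a, cdf_b) {
  stopifnot(inherits(cdf_a, "fcd_cdf"), inherits(cdf_b, "fcd_cdf"))
  x <- sort(unique(c(cdf_a$grid, cdf_b$grid)))
  max(abs(eval_cdf(cdf_a, x) - eval_cdf(cdf_b, x)))
}
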