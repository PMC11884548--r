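#' Autocovariance of fractional Gaussian noise
#'
#' gamma(k) = sigma2/2 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)).
#'
#' @param k vector of nonnegative integer lags.
#' @param H Hurst exponent in (0, 1).
#' @param sigma2 variance (gamma(0)).
#' @return numeric vector of autocovariances.
#' @export
fgn_autocov <- function(k, H, sigma2 = 1) {
  check_scalar(H, "H", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(sigma2, "sigma2", lower = 0)
  sigma2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

#' Simulate exact fractional Gaussian noise (Davies-Harte)
#'
#' Circulant-embedding synthesis of a stationary Gaussian series with the
#' exact fGn autocovariance. The embedding length is the next power of two
#' at or above \code{n_samples}; the series is truncated back to
#' \code{n_samples}. For fGn the circulant eigenvalues are provably
#' nonnegative; this is asserted rather than handled.
#'
#' @param H Hurst exponent in (0, 1). \code{H = 0.5} gives white noise.
#' @param n_samples series length.
#' @param sigma2 marginal variance.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return numeric vector of length \code{n_samples}.
#' @examples
#' x <- simulate_fgn(0.8, 1024, seed = 1)
#' cor(x[-1], x[-length(x)])   # near 2^(2*0.8-1) - 1 = 0.52
#' @export
simulate_fgn <- function(H, n_samples, sigma2 = 1, seed = NULL) {
  check_scalar(n_samples, "n_samples", lower = 2)
  n2 <- next_pow2(n_samples)
  m <- 2L * n2
  g <- fgn_autocov(0:n2, H, sigma2)
  circ <- c(g, rev(g[2:n2]))                 # length m, circulant first row
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop("internal error: negative circulant eigenvalue in Davies-Harte")
  lam <- pmax(lam, 0)
  with_seed(seed, {
    v1 <- rnorm(m)
    v2 <- rnorm(m)
    w <- complex(length.out = m)
    w[1] <- v1[1]
    w[n2 + 1] <- v1[n2 + 1]
    idx <- 2:n2
    w[idx] <- (v1[idx] + 1i * v2[idx]) / sqrt(2)
    w[m + 2L - idx] <- Conj(w[idx])
    x <- fft(sqrt(lam) * w) / sqrt(m)
    Re(x)[seq_len(n_samples)]
  })
}
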