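#' Covariance matrix adaptation evolution strategy (minimizer)
#'
#' Standard (mu/mu_w, lambda) CMA-ES with rank-one and rank-mu covariance
#' updates and cumulative step-size adaptation. Non-finite objective values
#' are allowed (such candidates rank last). Used as the search engine for
#' \code{\link{pmfm_fit}} but usable as a general derivative-free minimizer.
#'
#' @param fn objective, called on a numeric vector; smaller is better.
#' @param x0 initial mean.
#' @param sigma0 initial step size.
#' @param n_iterations number of generations.
#' @param lambda population size (default \code{4 + floor(3 log n)}).
#' @param seed integer seed or NULL.
#' @return list with \code{best_x}, \code{best_f}, \code{trace}
#'   (best-so-far objective per generation, non-increasing), and
#'   \code{iterates} (matrix of the best candidate of each generation, one
#'   row per generation, with attribute \code{"f"}).
#' @export
cmaes_minimize <- function(fn, x0, sigma0 = 0.2, n_iterations = 50L,
                           lambda = NULL, seed = NULL) {
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mu_eff <- 1 / sum(wts^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  with_seed(seed, {
    xmean <- as.numeric(x0)
    sigma <- sigma0
    pc <- ps <- numeric(n)
    C <- diag(n)
    eig <- list(vectors = diag(n), values = rep(1, n))
    best_f <- Inf
    best_x <- xmean
    trace <- numeric(n_iterations)
    iterates <- matrix(NA_real_, n_iterations, n)
    iter_f <- numeric(n_iterations)
    for (g in seq_len(n_iterations)) {
      BD <- eig$vectors %*% diag(sqrt(pmax(eig$values, 1e-20)), n)
      Z <- matrix(rnorm(n * lambda), n, lambda)
      Y <- BD %*% Z
      X <- xmean + sigma * Y
      f <- apply(X, 2L, function(x) {
        v <- fn(x)
        if (!is.finite(v)) Inf else v
      })
      ord <- order(f)
      sel <- ord[seq_len(mu)]
      y_w <- drop(Y[, sel, drop = FALSE] %*% wts)
      xmean <- xmean + sigma * y_w
      Cinv_y <- drop(eig$vectors %*%
                       (t(eig$vectors) %*% y_w / sqrt(pmax(eig$values, 1e-20))))
      ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) * Cinv_y
      hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN <
        1.4 + 2 / (n + 1)
      pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * y_w
      rank_mu <- matrix(0, n, n)
      for (k in seq_len(mu))
        rank_mu <- rank_mu + wts[k] * tcrossprod(Y[, sel[k]])
      C <- (1 - c1 - cmu) * C +
        c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
        cmu * rank_mu
      sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
      C <- (C + t(C)) / 2
      eig <- eigen(C, symmetric = TRUE)
      eig <- list(vectors = eig$vectors, values = pmax(eig$values, 1e-20))
      gen_best <- ord[1L]
      iterates[g, ] <- X[, gen_best]
      iter_f[g] <- f[gen_best]
      if (f[gen_best] < best_f) {
        best_f <- f[gen_best]
        best_x <- X[, gen_best]
      }
      trace[g] <- best_f
    }
    attr(iterates, "f") <- iter_f
    list(best_x = best_x, best_f = best_f, trace = trace, iterates = iterates)
  })
}
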