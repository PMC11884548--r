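#' Mean alteration of structurally connected neighbors
#'
#' For each node i with degree N_i (count of nonzero SC entries),
#' \code{D_i = (1/N_i) sum_j d_j * SC_ij} over connected neighbors j != i;
#' when \code{fc} is supplied each term is additionally weighted by
#' \code{FC_ij}. Isolated nodes get \code{NA} with a warning.
#'
#' @param d_map regional alteration map (e.g. Cohen's d), length N.
#' @param sc N x N symmetric nonnegative structural connectivity.
#' @param fc optional N x N functional connectivity (same shape).
#' @return regional map of neighbor alterations (length N).
#' @export
neighbor_alteration <- function(d_map, sc, fc = NULL) {
  check_matrix(sc, "sc", square = TRUE)
  if (length(d_map) != nrow(sc)) stop_bad_arg("d_map length must match SC")
  if (any(sc < 0)) stop_bad_arg("SC must be nonnegative")
  if (all(sc == 0)) stop_bad_arg("SC is all zero")
  W <- sc
  diag(W) <- 0
  if (!is.null(fc)) {
    check_matrix(fc, "fc", square = TRUE)
    if (!all(dim(fc) == dim(sc))) stop_bad_arg("fc shape must match sc")
    W <- W * fc
  }
  deg <- rowSums(sc > 0) - (diag(sc) > 0)
  out <- drop(W %*% d_map) / deg
  if (any(deg == 0)) {
    out[deg == 0] <- NA_real_
    warning(sprintf("isolated node(s) %s: neighbor alteration set to NA",
                    paste(which(deg == 0), collapse = ", ")))
  }
  out
}

#' Node-versus-neighbor coupling statistic
#'
#' Spearman correlation between a regional alteration map and the mean
#' alteration of each node's connected neighbors.
#'
#' @param d_map regional alteration map.
#' @param sc structural connectivity.
#' @param fc optional functional connectivity weighting.
#' @return Spearman correlation coefficient.
#' @export
neighbor_coupling <- function(d_map, sc, fc = NULL) {
  D <- neighbor_alteration(d_map, sc, fc)
  ok <- is.finite(D)
  cor(d_map[ok], D[ok], method = "spearman")
}

#' Epicenter likelihood map
#'
#' Likelihood of region i acting as a disease epicenter: the Spearman
#' correlation between row i of a healthy connectivity profile matrix
#' (self-connection excluded) and the alteration map (entry i excluded).
#' Regions are ranked in descending likelihood. Optional spin p-values per
#' node when a parcellation is supplied.
#'
#' @param d_map regional alteration map.
#' @param conn_profile N x N connectivity matrix (SC or FC).
#' @param parc optional \code{parcellation} for spin p-values.
#' @param n_rotations spin iterations (default 1000; only used with
#'   \code{parc}).
#' @param seed integer seed for the spin null.
#' @return data.frame with \code{region}, \code{likelihood}, \code{rank}
#'   (1 = most likely epicenter) and, when \code{parc} is given,
#'   \code{p_spin}.
#' @export
epicenter_likelihood <- function(d_map, conn_profile, parc = NULL,
                                 n_rotations = 1000L, seed = 1L) {
  check_matrix(conn_profile, "conn_profile", square = TRUE)
  N <- nrow(conn_profile)
  if (length(d_map) != N) stop_bad_arg("d_map length must match profiles")
  lik <- vapply(seq_len(N), function(i) {
    prof <- conn_profile[i, -i]
    if (sd(prof) == 0) return(NA_real_)
    cor(prof, d_map[-i], method = "spearman")
  }, numeric(1))
  out <- data.frame(region = seq_len(N), likelihood = lik,
                    rank = rank(-lik, ties.method = "min",
                                na.last = "keep"))
  if (!is.null(parc)) {
    surr <- spin_surrogates(d_map, parc, n_rotations, seed = seed)
    p <- vapply(seq_len(N), function(i) {
      if (!is.finite(lik[i])) return(NA_real_)
      null_i <- apply(surr, 2L, function(m)
        cor(conn_profile[i, -i], m[-i], method = "spearman"))
      (1 + sum(abs(null_i) >= abs(lik[i]))) / (n_rotations + 1)
    }, numeric(1))
    out$p_spin <- p
  }
  out
}

random_rotation <- function() {
  # uniform rotation from the QR decomposition of a Gaussian matrix
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin surrogates of a regional map
#'
#' Spatial-autocorrelation-preserving null maps for bilateral spherical
#' parcellations: per iteration a uniform random 3D rotation is applied to
#' the left-hemisphere centroids (its x-mirrored counterpart to the right),
#' and each region receives the value of the nearest rotated source region
#' within its own hemisphere. Values never cross hemispheres; duplication/
#' omission under the nearest-neighbor reassignment is accepted.
#'
#' @param map regional map (length N).
#' @param parc a \code{parcellation} with unit-sphere centroids.
#' @param n_rotations number of surrogates.
#' @param seed integer seed.
#' @return N x n_rotations matrix of surrogate maps.
#' @export
spin_surrogates <- function(map, parc, n_rotations, seed = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  if (length(map) != length(parc$pair))
    stop_bad_arg("map length does not match parcellation")
  iL <- which(parc$hemisphere == "L")
  iR <- which(parc$hemisphere == "R")
  CL <- parc$centroid[iL, , drop = FALSE]
  CR <- parc$centroid[iR, , drop = FALSE]
  M <- diag(c(-1, 1, 1))
  with_seed(seed, {
    out <- matrix(NA_real_, length(map), n_rotations)
    for (k in seq_len(n_rotations)) {
      R <- random_rotation()
      Rm <- M %*% R %*% M
      # nearest rotated source for each original centroid (max dot product)
      srcL <- max.col(CL %*% t(CL %*% t(R)), ties.method = "first")
      srcR <- max.col(CR %*% t(CR %*% t(Rm)), ties.method = "first")
      out[iL, k] <- map[iL][srcL]
      out[iR, k] <- map[iR][srcR]
    }
    out
  })
}

null_test <- function(observed, surrogate, p, type) {
  structure(list(observed = observed, surrogate = surrogate, p = p,
                 null_type = type), class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("%s null test: observed = %.4f, p = %.4g (%d surrogates)\n",
              x$null_type, x$observed, x$p, length(x$surrogate)))
  invisible(x)
}

#' Spin permutation p-value for a map-to-map statistic
#'
#' The first map is rotated \code{n} times (see
#' \code{\link{spin_surrogates}}); the two-sided p-value is
#' \code{(1 + #{|null| >= |observed|}) / (n + 1)}.
#'
#' @param stat_fn function of (map_a, map_b) returning a scalar statistic
#'   (default: Spearman correlation).
#' @param map_a,map_b regional maps.
#' @param parc a \code{parcellation}.
#' @param n number of rotations (reference protocol: 5000).
#' @param seed integer seed.
#' @param alternative "two.sided" (default) or "greater".
#' @return a \code{null_test} (observed statistic, surrogate statistics,
#'   p-value).
#' @export
spin_pvalue <- function(stat_fn = function(a, b) cor(a, b, method = "spearman"),
                        map_a, map_b, parc, n = 5000L, seed = 1L,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  obs <- stat_fn(map_a, map_b)
  surr <- spin_surrogates(map_a, parc, n, seed = seed)
  null_stats <- apply(surr, 2L, function(m) stat_fn(m, map_b))
  p <- if (alternative == "two.sided")
    (1 + sum(abs(null_stats) >= abs(obs))) / (n + 1)
  else
    (1 + sum(null_stats >= obs)) / (n + 1)
  null_test(obs, null_stats, p, "spin")
}

#' Degree- and length-preserving connectome rewiring
#'
#' Edges are binned by Euclidean centroid distance (equal-count bins) and
#' randomly swapped within bins (Maslov-Sneppen double-edge swaps). A swap
#' is accepted only if it creates no self- or duplicate edge and both new
#' edges still fall inside the current length bin, so the degree sequence,
#' edge count, weight multiset, and binned edge-length distribution are
#' all preserved exactly. Because the length constraint rejects most
#' proposals on spatially embedded graphs, many swaps are attempted per
#' edge; with the defaults most edge slots take part in accepted swaps
#' while the mean edge length drifts by well under two percent.
#'
#' @param sc N x N symmetric nonnegative connectivity.
#' @param dist N x N distance matrix.
#' @param n_bins number of equal-count distance bins (default 5; narrower
#'   bins preserve length better but starve the swap chain on small
#'   spatial graphs).
#' @param passes attempted swaps per edge within each bin (default 2000;
#'   acceptance under the length constraint is of order 1 percent, and
#'   attempts are cheap).
#' @param seed integer seed.
#' @return rewired N x N matrix.
#' @export
rewire_preserving_length <- function(sc, dist, n_bins = 5L, passes = 2000L,
                                     seed = NULL) {
  check_matrix(sc, "sc", square = TRUE)
  check_matrix(dist, "dist", square = TRUE)
  if (n_bins < 1L) stop_bad_arg("'n_bins' must be >= 1")
  N <- nrow(sc)
  ut <- which(upper.tri(sc) & sc > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2L) return(sc)
  w <- sc[ut]
  d <- dist[ut]
  br <- unique(quantile(d, probs = seq(0, 1, length.out = n_bins + 1L)))
  br[1L] <- br[1L] - 1e-9                 # include the shortest edge
  bin <- as.integer(cut(d, breaks = br, include.lowest = TRUE)) - 1L
  res <- with_seed(seed,
    rewire_swaps_cpp(cbind(ut[, 1], ut[, 2]) - 1L, bin, N, passes, dist, br))
  e <- res$edges + 1L
  out <- matrix(0, N, N)
  out[cbind(e[, 1], e[, 2])] <- w
  out[cbind(e[, 2], e[, 1])] <- w
  out
}

#' Rewired-null p-value for a map-network statistic
#'
#' One-sided exceedance p-value: the fraction of rewired-surrogate
#' statistics at or above the observed one (with +1 correction).
#'
#' @param stat_fn function of (d_map, sc) returning a scalar (default:
#'   \code{\link{neighbor_coupling}}).
#' @param d_map regional alteration map.
#' @param sc structural connectivity.
#' @param dist distance matrix for length binning.
#' @param n_null number of rewired surrogates (reference protocol: 1000).
#' @param n_bins,passes rewiring parameters.
#' @param seed integer seed.
#' @return a \code{null_test}.
#' @export
rewired_pvalue <- function(stat_fn = neighbor_coupling, d_map, sc, dist,
                           n_null = 1000L, n_bins = 5L, passes = 2000L,
                           seed = 1L) {
  obs <- stat_fn(d_map, sc)
  null_stats <- with_seed(seed, vapply(seq_len(n_null), function(k) {
    sc_null <- rewire_preserving_length(sc, dist, n_bins, passes, seed = NULL)
    stat_fn(d_map, sc_null)
  }, numeric(1)))
  p <- (1 + sum(null_stats >= obs)) / (n_null + 1)
  null_test(obs, null_stats, p, "rewired")
}

#' Label-permutation p-value for a map-to-map statistic
#'
#' Offered for maps without spherical coordinates (e.g. subcortex): the
#' first map's values are permuted uniformly.
#'
#' @inheritParams spin_pvalue
#' @param n number of permutations.
#' @return a \code{null_test}.
#' @export
perm_pvalue <- function(stat_fn = function(a, b) cor(a, b, method = "spearman"),
                        map_a, map_b, n = 5000L, seed = 1L) {
  obs <- stat_fn(map_a, map_b)
  null_stats <- with_seed(seed, vapply(seq_len(n), function(k)
    stat_fn(sample(map_a), map_b), numeric(1)))
  p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n + 1)
  null_test(obs, null_stats, p, "label-permutation")
}
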