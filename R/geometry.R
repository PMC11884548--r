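#' Build a synthetic bilateral spherical parcellation
#'
#' Places \code{n_regions/2} quasi-uniform centroids on the unit sphere
#' restricted to the right hemisphere (x > 0) via a jittered Fibonacci
#' lattice, and mirrors them across the x = 0 plane so every left-hemisphere
#' region has an exact homotopic partner. Community (network) labels are
#' assigned by k-means clustering of the right-hemisphere centroids and
#' shared by homotopic pairs, emulating bilateral functional networks.
#'
#' @param n_regions even integer >= 8, total number of regions.
#' @param n_communities integer >= 1, number of network labels.
#' @param seed integer seed controlling jitter and clustering.
#' @return An object of class \code{parcellation}: a list with
#'   \code{region_id} (0-based), \code{hemisphere} ("L"/"R"),
#'   \code{centroid} (N x 3, unit rows), \code{community} (integer), and
#'   \code{pair} (1-based index of each region's homotopic partner).
#' @examples
#' p <- make_geometry(16, 2, seed = 1)
#' range(abs(sqrt(rowSums(p$centroid^2)) - 1))
#' @export
make_geometry <- function(n_regions, n_communities = 1L, seed = 1L) {
  if (length(n_regions) != 1L || n_regions < 8L || n_regions %% 2L != 0L)
    stop_bad_arg("'n_regions' must be an even integer >= 8")
  if (n_communities < 1L) stop_bad_arg("'n_communities' must be >= 1")
  nh <- n_regions %/% 2L
  with_seed(seed, {
    # Fibonacci lattice on the sphere, folded onto x > 0
    i <- seq_len(nh) - 0.5
    phi <- acos(1 - 2 * i / nh)
    theta <- pi * (1 + sqrt(5)) * i
    cr <- cbind(abs(sin(phi) * cos(theta)), sin(phi) * sin(theta), cos(phi))
    cr <- cr + matrix(rnorm(3 * nh, sd = 0.03), nh, 3)
    cr[, 1] <- abs(cr[, 1]) + 1e-6          # stay strictly in x > 0
    cr <- cr / sqrt(rowSums(cr^2))
    cl <- if (n_communities == 1L) rep(1L, nh) else
      kmeans(cr, centers = n_communities, nstart = 5L)$cluster
    cl_left <- cl
    cl_right <- cl
    cL <- cr
    cL[, 1] <- -cL[, 1]
    centroid <- rbind(cL, cr)               # L block first, then R
    structure(list(
      region_id  = 0:(n_regions - 1L),
      hemisphere = rep(c("L", "R"), each = nh),
      centroid   = centroid,
      community  = c(cl_left, cl_right),
      pair       = c(seq_len(nh) + nh, seq_len(nh))
    ), class = "parcellation")
  })
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d regions (%d per hemisphere), %d communities\n",
              length(x$region_id), sum(x$hemisphere == "L"),
              length(unique(x$community))))
  invisible(x)
}

n_regions <- function(parc) length(parc$region_id)

centroid_distances <- function(parc) {
  unname(as.matrix(stats::dist(parc$centroid)))
}

#' Build a synthetic distance-dependent structural connectome
#'
#' Edge placement favours short connections (probability proportional to
#' \code{exp(-dist/decay_length)}); edge weights are log-normal. The minimum
#' spanning tree over centroid distance is always included so the graph is
#' connected, and the number of edges is fixed to
#' \code{round(density * choose(N, 2))} so the realized density matches the
#' request.
#'
#' @param parc a \code{parcellation}.
#' @param density fraction of possible edges, in (0, 1].
#' @param decay_length length scale of the exponential distance penalty,
#'   in the same (unit-sphere chord) units as the centroid distances.
#' @param seed integer seed.
#' @return An object of class \code{connectome}: list with \code{sc}
#'   (N x N nonnegative symmetric, zero diagonal), \code{dist} (N x N
#'   Euclidean centroid distances), and \code{fc = NULL}.
#' @export
make_connectome <- function(parc, density = 0.3, decay_length = 0.75, seed = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  check_scalar(density, "density", lower = 1e-12, upper = 1)
  check_scalar(decay_length, "decay_length", lower = 1e-12)
  N <- n_regions(parc)
  D <- centroid_distances(parc)
  n_pairs <- N * (N - 1L) / 2L
  m_target <- round(density * n_pairs)
  if (m_target < N - 1L)
    stop_bad_arg(sprintf(
      "density %.3g yields %d edges but %d are needed to connect %d regions",
      density, m_target, N - 1L, N))
  with_seed(seed, {
    ut <- which(upper.tri(D), arr.ind = TRUE)
    d_ut <- D[upper.tri(D)]
    # MST over distance guarantees connectedness
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    mst_el <- igraph::as_edgelist(mst, names = FALSE)
    mst_key <- paste(pmin(mst_el[, 1], mst_el[, 2]),
                     pmax(mst_el[, 1], mst_el[, 2]))
    key <- paste(ut[, 1], ut[, 2])
    in_mst <- key %in% mst_key
    # rank non-MST pairs by u/q: smallest first realizes p(edge) ~ q
    q <- exp(-d_ut / decay_length)
    score <- runif(n_pairs) / q
    score[in_mst] <- -Inf
    keep <- rank(score, ties.method = "first") <= m_target
    # heavy-tailed weights, stronger at short range, as in tractography SC
    w <- numeric(n_pairs)
    w[keep] <- rlnorm(sum(keep), meanlog = 0, sdlog = 1.5) *
      exp(-d_ut[keep] / decay_length)
    sc <- matrix(0, N, N)
    sc[upper.tri(sc)] <- w
    sc <- sc + t(sc)
    structure(list(sc = sc, dist = D, fc = NULL), class = "connectome")
  })
}

#' @export
print.connectome <- function(x, ...) {
  N <- nrow(x$sc)
  m <- sum(x$sc[upper.tri(x$sc)] > 0)
  cat(sprintf("connectome: %d regions, %d edges (density %.3f)%s\n",
              N, m, m / choose(N, 2),
              if (is.null(x$fc)) "" else ", FC attached"))
  invisible(x)
}

#' Generate smooth synthetic annotation maps
#'
#' Produces stand-ins for the two cortical annotation maps that parameterize
#' the mean-field model (an intracortical myelin proxy and a principal
#' functional-connectivity gradient): low-order polynomials of the centroid
#' coordinates plus Gaussian noise with standard deviation
#' \code{1/smoothness}. Both the polynomial basis and the noise are
#' mirrored across hemispheres, so homotopic partners carry identical
#' values — matching the homotopic organization of real cortical
#' annotations (and required for ipsi/contra sorting to be unconfounded).
#' Both maps are z-scored across regions.
#'
#' @param parc a \code{parcellation}.
#' @param smoothness positive; larger values give smoother (more spatially
#'   autocorrelated) maps.
#' @param seed integer seed.
#' @return list with numeric vectors \code{myelin} and \code{gradient},
#'   each of length N with mean 0 and SD 1.
#' @export
make_annotation_maps <- function(parc, smoothness = 3, seed = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  check_scalar(smoothness, "smoothness", lower = 1e-12)
  C <- parc$centroid
  basis <- cbind(abs(C[, 1]), C[, 2], C[, 3],
                 C[, 2]^2, C[, 3]^2, abs(C[, 1]) * C[, 2], C[, 2] * C[, 3])
  nh <- nrow(C) %/% 2L
  with_seed(seed, {
    one_map <- function() {
      beta <- rnorm(ncol(basis))
      noise_h <- rnorm(nh, sd = 1 / smoothness)    # shared by mirror pairs
      raw <- drop(basis %*% beta) + rep(noise_h, 2L)
      as.numeric(scale(raw))
    }
    myelin <- one_map()
    # the two annotations are complementary axes: orthogonalize the
    # gradient against the myelin proxy so the linear parameterization of
    # regional circuit properties is well-posed
    gradient <- as.numeric(scale(lm.fit(cbind(1, myelin),
                                        one_map())$residuals))
    list(myelin = myelin, gradient = gradient)
  })
}
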