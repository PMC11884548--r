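# shared fixtures, built fresh in code (no stored data)

small_substrate <- function(n = 40L, seed = 1L) {
  parc <- make_geometry(n, 4L, seed = seed)
  conn <- make_connectome(parc, density = 0.3, seed = seed)
  maps <- make_annotation_maps(parc, smoothness = 3, seed = seed)
  list(parc = parc, conn = conn, maps = maps,
       sc = conn$sc, myelin = maps$myelin, gradient = maps$gradient)
}

# inverse of the orthonormal Haar step, for building series from
# prescribed wavelet coefficients (model-exact synthesis)
haar_idwt <- function(details, approx) {
  a <- approx
  for (j in rev(seq_along(details))) {
    d <- details[[j]]
    n <- 2L * length(d)
    out <- numeric(n)
    out[seq(1L, n, 2L)] <- (a[seq_along(d)] + d) / sqrt(2)
    out[seq(2L, n, 2L)] <- (a[seq_along(d)] - d) / sqrt(2)
    a <- out
  }
  a
}

# series whose detail variances follow the fitted model exactly:
# var(d_j) = 2^(2 d j)
model_exact_series <- function(d, n_levels, n = 2^12, seed = 1L) {
  set.seed(seed)
  details <- lapply(seq_len(n_levels), function(j)
    rnorm(n / 2^j, sd = 2^(d * j)))
  approx <- rnorm(n / 2^n_levels, sd = 2^(d * n_levels))
  haar_idwt(details, approx)
}

# smooth map for spin-test fixtures: a random linear field in (|x|, y, z)
# with mirrored noise, i.e. homotopically symmetric like real annotation
# maps. The paired L/R rotations of the spin null keep such fields
# exchangeable; hemispherically asymmetric maps would not be.
smooth_map <- function(parc, seed) {
  set.seed(seed)
  C <- parc$centroid
  nh <- nrow(C) %/% 2L
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  raw <- drop(cbind(abs(C[, 1]), C[, 2], C[, 3]) %*% u) +
    rep(rnorm(nh, sd = 0.3), 2L)
  as.numeric(scale(raw))
}

# Moran's I on an inverse-distance weight matrix (ape is the oracle)
morans_i <- function(map, parc) {
  w <- 1 / (centroid_dist_matrix(parc) + diag(nrow(parc$centroid)))
  diag(w) <- 0
  ape::Moran.I(map, w)$observed
}

centroid_dist_matrix <- function(parc) as.matrix(dist(parc$centroid))
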