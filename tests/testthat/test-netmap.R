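test_that("neighbor alteration matches hand and brute-force oracles", {
  # 3-node toy: node1-node2 weight 2, node1-node3 weight 4
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 2
  sc[1, 3] <- sc[3, 1] <- 4
  d <- c(NA, 0.5, 1.0)
  d[1] <- 0.7
  D <- neighbor_alteration(d, sc)
  expect_equal(D[1], (0.5 * 2 + 1.0 * 4) / 2)
  fc <- matrix(1, 3, 3)
  fc[1, 2] <- fc[2, 1] <- 0.5
  fc[1, 3] <- fc[3, 1] <- 0.25
  Dfc <- neighbor_alteration(d, sc, fc)
  expect_equal(Dfc[1], (0.5 * 2 * 0.5 + 1.0 * 4 * 0.25) / 2)
  # binary SC with constant map returns the constant
  set.seed(1)
  A <- matrix(rbinom(64, 1, 0.5), 8); A <- A * t(A); diag(A) <- 0
  A[1, 2] <- A[2, 1] <- 1    # ensure no isolated node
  keep <- rowSums(A) > 0
  Dc <- suppressWarnings(neighbor_alteration(rep(3, 8), A))
  expect_equal(unname(Dc[keep]), rep(3, sum(keep)))
  # brute-force double loop on random instances
  for (s in 1:5) {
    set.seed(s)
    n <- sample(5:12, 1)
    W <- matrix(runif(n * n), n) * matrix(rbinom(n * n, 1, 0.6), n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    dm <- rnorm(n)
    F2 <- cor(matrix(rnorm(n * 50), 50, n))
    brute <- vapply(seq_len(n), function(i) {
      nb <- which(W[i, ] > 0)
      if (!length(nb)) return(NA_real_)
      sum(dm[nb] * W[i, nb] * F2[i, nb]) / length(nb)
    }, numeric(1))
    got <- suppressWarnings(neighbor_alteration(dm, W, F2))
    expect_equal(got, brute, tolerance = 1e-12)
  }
  expect_error(neighbor_alteration(1:3, matrix(0, 3, 3)), "all zero")
})

test_that("epicenter likelihood is a rank statistic with self-match", {
  set.seed(2)
  N <- 20L
  prof <- cor(matrix(rnorm(N * 80), 80, N))
  d_map <- prof[7, ]
  d_map[7] <- 0.2                         # value at the excluded self-entry
  ep <- epicenter_likelihood(d_map, prof)
  expect_equal(ep$likelihood[7], 1)
  expect_equal(ep$rank[7], 1L)
  # invariance to strictly monotone transforms of the map
  ep2 <- epicenter_likelihood(exp(2 * d_map), prof)
  expect_equal(ep$likelihood, ep2$likelihood)
  # independent random maps rarely match any profile strongly
  set.seed(3)
  mx <- replicate(20, max(abs(
    epicenter_likelihood(rnorm(N), prof)$likelihood)))
  expect_lt(median(mx), 0.75)
})

test_that("spin surrogates preserve hemisphere and autocorrelation", {
  parc <- make_geometry(68L, 4L, seed = 4L)
  map <- smooth_map(parc, 5)
  surr <- spin_surrogates(map, parc, 200L, seed = 6L)
  iL <- parc$hemisphere == "L"
  expect_true(all(surr[iL, ] %in% map[iL]))
  expect_true(all(surr[!iL, ] %in% map[!iL]))
  # constant map: all surrogates identical, p-value 1
  cs <- spin_surrogates(rep(2, 68), parc, 10L, seed = 1L)
  expect_true(all(cs == 2))
  # spatial autocorrelation of surrogates stays near the original
  mi_orig <- morans_i(map, parc)
  mi_surr <- mean(apply(surr[, 1:100], 2L, morans_i, parc = parc))
  expect_lt(abs(mi_surr - mi_orig), 0.25 * abs(mi_orig))
})

test_that("spin p-values are extreme for identical maps, calibrated on null", {
  parc <- make_geometry(40L, 2L, seed = 7L)
  map <- smooth_map(parc, 8)
  res <- spin_pvalue(map_a = map, map_b = map, parc = parc, n = 200L,
                     seed = 9L)
  expect_equal(res$observed, 1)
  expect_lte(res$p, 5 / 201)
  rej <- vapply(1:100, function(s) {
    a <- smooth_map(parc, 1000 + s)
    b <- smooth_map(parc, 2000 + s)
    spin_pvalue(map_a = a, map_b = b, parc = parc, n = 99L,
                seed = s)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("rewiring preserves degrees, counts, weights and binned lengths", {
  sub <- small_substrate(40L, seed = 11L)
  sc <- sub$sc; dmat <- sub$conn$dist
  rw <- rewire_preserving_length(sc, dmat, seed = 12L)
  expect_equal(rowSums(rw > 0), rowSums(sc > 0))
  expect_equal(sum(rw[upper.tri(rw)] > 0), sum(sc[upper.tri(sc)] > 0))
  expect_equal(sort(rw[rw > 0]), sort(sc[sc > 0]))   # weights carried
  # in-bin acceptance keeps the binned length histogram exactly
  len_of <- function(m) dmat[upper.tri(dmat) & m > 0]
  br <- unique(quantile(len_of(sc), probs = seq(0, 1, length.out = 6L)))
  br[1] <- br[1] - 1e-9
  expect_equal(table(cut(len_of(rw), br, include.lowest = TRUE)),
               table(cut(len_of(sc), br, include.lowest = TRUE)))
  expect_lt(abs(mean(len_of(rw)) - mean(len_of(sc))),
            0.05 * mean(len_of(sc)))
  # rewiring does move edges
  expect_gt(sum((rw > 0) != (sc > 0)), 0)
})

test_that("rewired null separates topology-driven from random maps", {
  sub <- small_substrate(68L, seed = 13L)
  sc <- sub$sc
  # positive control: map diffused along the graph follows SC topology
  ps <- vapply(1:5, function(s) {
    set.seed(s)
    A <- sc / max(sc)
    P <- A / pmax(rowSums(A), 1e-12)
    d_smooth <- as.numeric((diag(68) + P %*% P + P) %*% rnorm(68) / 3)
    rewired_pvalue(d_map = d_smooth, sc = sc, dist = sub$conn$dist,
                   n_null = 99L, seed = 100L + s)$p
  }, numeric(1))
  expect_gte(sum(ps < 0.05), 4L)
  # calibration under independent maps
  rej <- vapply(1:60, function(s) {
    set.seed(300 + s)
    rewired_pvalue(d_map = rnorm(68), sc = sc, dist = sub$conn$dist,
                   n_null = 49L, seed = s)$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})
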