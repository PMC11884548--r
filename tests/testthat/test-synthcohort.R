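test_that("geometry is bilateral, unit-norm, and reproducible", {
  p <- make_geometry(8L, 2L, seed = 3L)
  expect_equal(sum(p$hemisphere == "L"), 4L)
  expect_equal(sum(p$hemisphere == "R"), 4L)
  # homotopic pairs are exact x-mirrors
  mirrored <- p$centroid[p$pair, ] * matrix(rep(c(-1, 1, 1), each = 8), 8)
  expect_equal(p$centroid, mirrored, tolerance = 1e-12)
  expect_lt(max(abs(sqrt(rowSums(p$centroid^2)) - 1)), 1e-12)
  # homotopic pairs share a community
  expect_equal(p$community, p$community[p$pair])
  expect_identical(p, make_geometry(8L, 2L, seed = 3L))
  expect_error(make_geometry(9L), "even")
})

test_that("connectome hits requested density, stays connected", {
  p <- make_geometry(68L, 4L, seed = 1L)
  dens <- vapply(1:20, function(s) {
    cn <- make_connectome(p, density = 0.3, seed = s)
    m <- sum(cn$sc[upper.tri(cn$sc)] > 0)
    g <- igraph::graph_from_adjacency_matrix(cn$sc > 0, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1L)
    m / choose(68, 2)
  }, numeric(1))
  expect_true(all(dens >= 0.9 * 0.3 & dens <= 1.1 * 0.3))
  full <- make_connectome(p, density = 1, seed = 1L)
  expect_true(all(full$sc[upper.tri(full$sc)] > 0))
  expect_equal(full$sc, t(full$sc))
  expect_equal(diag(full$sc), rep(0, 68))
  expect_error(make_connectome(p, density = 0.005), "connect")
})

test_that("annotation maps are z-scored, smooth, reproducible", {
  p <- make_geometry(68L, 4L, seed = 2L)
  for (s in 1:10) {
    m <- make_annotation_maps(p, smoothness = 5, seed = s)
    expect_lt(abs(mean(m$myelin)), 1e-10)
    expect_lt(abs(sd(m$myelin) - 1), 1e-10)
    expect_lt(abs(mean(m$gradient)), 1e-10)
    # spatial autocorrelation is positive for smooth maps
    expect_gt(morans_i(m$myelin, p), 0)
  }
  expect_identical(make_annotation_maps(p, seed = 7L),
                   make_annotation_maps(p, seed = 7L))
})

test_that("fGn generator matches the exact autocovariance", {
  # white-noise special case
  y <- simulate_fgn(0.5, 4096, seed = 11L)
  expect_lt(abs(cor(y[-1], y[-4096])), 0.05)
  expect_equal(fgn_autocov(1:4, 0.5), rep(0, 4))
  # closed-form lag-1 correlation at H = 0.8
  rho1 <- vapply(1:50, function(s) {
    x <- simulate_fgn(0.8, 4096, seed = s)
    mean(x[-1] * x[-4096]) / mean(x^2)
  }, numeric(1))
  expect_lt(abs(mean(rho1) - (2^(2 * 0.8 - 1) - 1)), 0.05)
  # sample variance near sigma2
  v <- vapply(1:50, function(s)
    var(simulate_fgn(0.7, 4096, sigma2 = 2, seed = s)), numeric(1))
  expect_lt(abs(mean(v) / 2 - 1), 0.05)
  expect_identical(simulate_fgn(0.7, 512, seed = 5L),
                   simulate_fgn(0.7, 512, seed = 5L))
})

test_that("fGn autocovariance is exact at lags 0-5 within 3 SE", {
  for (H in c(0.6, 0.7, 0.8)) {
    n <- 2048L
    reps <- 200L
    gk <- vapply(1:reps, function(s) {
      x <- simulate_fgn(H, n, seed = 1000L + s)
      vapply(0:5, function(k) mean(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
    }, numeric(6))
    m <- rowMeans(gk)
    se <- apply(gk, 1L, sd) / sqrt(reps)
    expect_true(all(abs(m - fgn_autocov(0:5, H)) < 3 * se),
                label = sprintf("H = %.1f autocovariance", H))
  }
})

test_that("cohort generation honors the spec and records truth", {
  sp <- cohort_spec(n_controls = 6L, n_patients = 6L, n_regions = 16L,
                    n_communities = 2L, T_len = 256L, delta_h = 0.15)
  co <- make_cohort(sp, seed = 9L)
  grp <- vapply(co$subjects, `[[`, character(1), "group")
  expect_equal(sum(grp == "control"), 6L)
  expect_equal(sum(grp == "patient"), 6L)
  expect_true(all(vapply(co$subjects, function(s)
    (s$focus_side == "none") == (s$group == "control"), logical(1))))
  expect_equal(dim(co$subjects[[1]]$ts), c(256L, 16L))
  expect_equal(co$truth$delta_h, 0.15)
  expect_true(all(co$truth$h_patient_focusL[co$truth$affected] <
                    co$truth$h_control[co$truth$affected]))
  # bit-reproducible
  co2 <- make_cohort(sp, seed = 9L)
  expect_identical(co$subjects[[3]]$ts, co2$subjects[[3]]$ts)
  # null cohort: identical truth maps
  co0 <- make_cohort(cohort_spec(n_controls = 4L, n_patients = 4L,
                                 n_regions = 16L, T_len = 256L,
                                 delta_h = 0), seed = 1L)
  expect_equal(co0$truth$h_control, co0$truth$h_patient_focusL)
  expect_error(make_cohort(cohort_spec(n_regions = 16L, affected = 99L)),
               "affected")
})

test_that("cognitive scores track subject-mean Hurst when coupled", {
  cors <- vapply(1:3, function(s) {
    co <- make_cohort(cohort_spec(n_controls = 20L, n_patients = 20L,
                                  n_regions = 16L, T_len = 512L,
                                  delta_h = 0.15, cog_slope = 20,
                                  cog_noise = 0.3), seed = s)
    h_est <- vapply(co$subjects, function(su) mean(hurst_map(su$ts)),
                    numeric(1))
    cog <- vapply(co$subjects, function(su) su$cognition[["score"]],
                  numeric(1))
    cor(h_est, cog)
  }, numeric(1))
  expect_true(all(cors > 0))
})
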