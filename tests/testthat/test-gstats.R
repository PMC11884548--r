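test_that("control z-scoring and affine invariance", {
  set.seed(1)
  maps <- matrix(rnorm(20 * 6, mean = 5), 20, 6)
  z <- zscore_to_controls(maps, 1:10)
  expect_equal(colMeans(z[1:10, ]), rep(0, 6))
  expect_equal(apply(z[1:10, ], 2, sd), rep(1, 6))
  # a subject at the control mean maps to zero
  maps2 <- rbind(maps[1:10, ], colMeans(maps[1:10, ]))
  z2 <- zscore_to_controls(maps2, 1:10)
  expect_equal(unname(z2[11, ]), rep(0, 6))
  expect_equal(zscore_to_controls(maps + 3, 1:10), z)
  bad <- maps; bad[1:10, 2] <- 1
  expect_error(zscore_to_controls(bad, 1:10), "region\\(s\\) 2")
})

test_that("ipsi/contra flipping is an involution tied to focus side", {
  p <- make_geometry(8L, 1L, seed = 1L)
  map <- c(1, 1, 1, 1, 2, 2, 2, 2)   # L = 1s, R = 2s
  expect_equal(flip_to_ipsi(map, "L", p), map)
  expect_equal(flip_to_ipsi(map, "none", p), map)
  flipped <- flip_to_ipsi(map, "R", p)
  expect_equal(flipped[1:4], rep(2, 4))  # ipsi slots now hold the R values
  expect_equal(flip_to_ipsi(flipped, "R", p), map)
})

test_that("region comparison finds injected effects and controls type I", {
  set.seed(10)
  n <- 40L; N <- 30L
  # null: no group effect anywhere, age effect in all regions
  pvals <- replicate(50, {
    age <- runif(2 * n, 20, 60)
    sex <- sample(c("M", "F"), 2 * n, replace = TRUE)
    maps <- matrix(rnorm(2 * n * N), 2 * n, N) + outer(age, rep(0.02, N))
    grp <- rep(c("control", "patient"), each = n)
    compare_regions(maps, grp, data.frame(age = age, sex = sex))$p
  })
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  # injected effect in 10 of 30 regions
  set.seed(11)
  maps <- matrix(rnorm(2 * n * N), 2 * n, N)
  maps[(n + 1):(2 * n), 1:10] <- maps[(n + 1):(2 * n), 1:10] - 1.2
  cmp <- compare_regions(maps, rep(c("control", "patient"), each = n),
                         data.frame(age = runif(2 * n, 20, 60)))
  expect_gte(sum(cmp$significant[1:10]), 8L)
  expect_lte(sum(cmp$significant[11:30]), 1L)
  expect_true(all(cmp$cohens_d[1:10] < 0))   # lower in patients => d < 0
  # identical groups give d = 0
  same <- rbind(maps[1:n, ], maps[1:n, ])
  cmp0 <- compare_regions(same, rep(c("control", "patient"), each = n))
  expect_equal(cmp0$cohens_d, rep(0, N))
  expect_error(compare_regions(maps, rep(c("control", "patient"), each = n),
                               data.frame(age = rep(1, 2 * n))),
               "collinear")
})

test_that("summary t and chi-square reproduce printed cohort statistics", {
  expect_equal(round(abs(summary_ttest(34.25, 3.98, 40,
                                       35.80, 11.04, 40)), 2), 0.84)
  expect_equal(round(abs(summary_ttest(31.83, 11.35, 30,
                                       30.87, 11.46, 30)), 2), 0.33)
  expect_equal(summary_ttest(1, 1, 10, 1, 1, 10), 0)
  expect_equal(round(chisq_2x2(matrix(c(19, 17, 21, 23), 2)), 2), 0.20)
  expect_equal(round(chisq_2x2(matrix(c(11, 10, 19, 20), 2)), 2), 0.07)
  expect_equal(chisq_2x2(matrix(10, 2, 2)), 0)
  # Welch equals pooled t at equal group sizes
  expect_equal(summary_ttest(2, 1.3, 25, 1.1, 0.8, 25),
               (2 - 1.1) / (sqrt((1.3^2 + 0.8^2) / 2) * sqrt(2 / 25)))
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("partial correlation residualizes covariates correctly", {
  set.seed(12)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  expect_equal(partial_corr(x, y)[["r"]], cor(x, y))
  expect_equal(partial_corr(x, x, data.frame(z = rnorm(100)))[["r"]], 1)
  # x and y independent given z
  cnt <- vapply(1:100, function(s) {
    set.seed(s)
    z <- rnorm(500)
    x <- z + rnorm(500); y <- z + rnorm(500)
    abs(partial_corr(x, y, data.frame(z = z))[["r"]]) < 0.1
  }, logical(1))
  expect_gte(mean(cnt), 0.95)
  # matches cor.test in the no-covariate case
  ct <- cor.test(x, y)
  pc <- partial_corr(x, y)
  expect_equal(pc[["t"]], unname(ct$statistic))
  expect_equal(pc[["p"]], ct$p.value)
})

test_that("BH q-values match the brute-force step-up definition", {
  bh_brute <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  for (s in 1:20) {
    set.seed(s)
    p <- runif(sample(3:20, 1))^2
    expect_equal(p.adjust(p, "BH"), bh_brute(p))
  }
})

test_that("community means reduce correctly and calibrate under the null", {
  set.seed(13)
  maps <- matrix(rnorm(40 * 12), 40, 12)
  grp <- rep(c("control", "patient"), each = 20)
  comm <- rep(1:3, each = 4)
  nm <- network_means(maps, comm, grp)
  expect_equal(nrow(nm), 3L)
  cst <- network_means(matrix(2, 40, 12), comm, grp)
  expect_equal(cst$mean_control, rep(2, 3))
  expect_equal(cst$mean_patient, rep(2, 3))
  one <- network_means(maps, rep(1L, 12), grp)
  expect_equal(one$t,
               t.test(rowMeans(maps)[21:40], rowMeans(maps)[1:20],
                      var.equal = TRUE)$statistic, ignore_attr = TRUE)
  # null calibration across replicates
  any_sig <- vapply(1:50, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(40 * 12), 40, 12)
    any(network_means(m, comm, grp)$q < 0.05)
  }, logical(1))
  expect_gte(mean(!any_sig), 0.9)
  expect_error(network_means(maps, rep(1L, 10), grp), "match the number")
})

test_that("PC1 scores capture shared variance with a fixed sign", {
  set.seed(14)
  base <- rnorm(50)
  rank1 <- outer(base, c(1, 2, 3))
  p1 <- pc1_scores(rank1 + matrix(rnorm(150, sd = 1e-8), 50))
  expect_equal(p1$variance_explained, 1, tolerance = 1e-6)
  iso <- pc1_scores(matrix(rnorm(2000 * 4), 2000, 4))
  expect_equal(iso$variance_explained, 0.25, tolerance = 0.05)
  shared <- matrix(rnorm(200 * 5), 200, 5) + outer(rnorm(200), rep(1, 5))
  p2 <- pc1_scores(shared)
  expect_gt(cor(p2$scores, rowMeans(scale(shared))), 0)
  expect_error(pc1_scores(cbind(rnorm(10), rep(1, 10))), "zero-variance")
})
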