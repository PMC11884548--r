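test_that("static FC is a correlation matrix with exact limits", {
  set.seed(1)
  ts <- matrix(rnorm(400), 100, 4)
  ts[, 2] <- 2 * ts[, 1]
  fc <- static_fc(ts)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc, t(fc))
  expect_equal(diag(fc), rep(1, 4))
  long <- matrix(rnorm(4096 * 3), 4096, 3)
  expect_lt(max(abs(static_fc(long)[upper.tri(diag(3))])), 0.1)
  ts[, 3] <- 7
  expect_error(static_fc(ts), "region\\(s\\) 3")
})

test_that("FCD window count follows the sliding-window formula", {
  cases <- list(c(695, 100, 1, 596), c(200, 50, 1, 151), c(200, 50, 10, 16))
  for (cs in cases) {
    ts <- matrix(rnorm(cs[1] * 6), cs[1], 6)
    fcd <- sliding_window_fcd(ts, cs[2], cs[3])
    expect_equal(nrow(fcd), cs[4])
    expect_equal(diag(unclass(fcd)), rep(1, cs[4]))
    expect_true(all(abs(fcd) <= 1 + 1e-12))
  }
  tiny <- sliding_window_fcd(matrix(rnorm(101 * 5), 101, 5), 100L, 1L)
  expect_equal(dim(unclass(tiny)), c(2L, 2L))
  expect_error(sliding_window_fcd(matrix(rnorm(300), 50, 6), 100L), "short")
})

test_that("FCD separates stationary from state-switching dynamics", {
  set.seed(2)
  n <- 10L
  # stationary: one stable, strongly structured FC pattern
  load <- seq(0.5, 2, length.out = n)
  shared <- rnorm(800)
  stat_ts <- matrix(rnorm(800 * n, sd = 0.4), 800, n) + outer(shared, load)
  # switching: the coupling structure changes halfway through
  f1 <- rnorm(800) * rep(c(1, 0), each = 400)
  f2 <- rnorm(800) * rep(c(0, 1), each = 400)
  switch_ts <- matrix(rnorm(800 * n, sd = 0.4), 800, n) +
    outer(f1, c(load[1:5], rep(0, 5))) + outer(f2, c(rep(0, 5), load[6:10]))
  m_stat <- mean(sliding_window_fcd(stat_ts)[upper.tri(diag(701))])
  m_switch <- mean(sliding_window_fcd(switch_ts)[upper.tri(diag(701))])
  expect_gt(m_stat, 0.5)
  expect_lt(m_switch, m_stat)
})

test_that("FCD CDF and its group average behave as distributions", {
  f <- matrix(c(1, 0.3, 0.3, 1), 2)
  cdf <- fcd_cdf(f)
  expect_equal(cdf$grid, 0.3)
  expect_equal(cdf$cum, 1)
  set.seed(3)
  fcd <- sliding_window_fcd(matrix(rnorm(160 * 8), 160, 8), 50L)
  cdf <- fcd_cdf(fcd)
  expect_equal(cdf$cum[length(cdf$cum)], 1)
  expect_true(all(diff(cdf$cum) >= 0))
  expect_equal(median(cdf$grid), median(fcd[upper.tri(fcd)]))
  # group averaging: single element is identity; identical pair unchanged
  g1 <- group_fcd_cdf(list(cdf))
  g2 <- group_fcd_cdf(list(cdf, cdf))
  expect_equal(g1$cum, g2$cum)
  expect_true(all(diff(g2$cum) >= 0))
  expect_equal(g2$cum[length(g2$cum)], 1)
})

test_that("group FC averaging is Fisher-z based and dimension-checked", {
  set.seed(4)
  fcs <- lapply(1:3, function(i) static_fc(matrix(rnorm(600), 100, 6)))
  expect_equal(group_fc(fcs[1]), fcs[[1]])
  avg <- group_fc(fcs)
  expect_equal(avg, t(avg))
  expect_equal(diag(avg), rep(1, 6))
  manual <- tanh(mean(vapply(fcs, function(f) atanh(f[1, 2]), numeric(1))))
  expect_equal(avg[1, 2], manual)
  expect_error(group_fc(list(fcs[[1]], diag(4))), "mismatch")
})

test_that("KS distance matches closed forms and is a metric", {
  f <- function(v) fcd_cdf(matrix(c(1, v, v, 1), 2))
  expect_equal(ks_distance(f(0.4), f(0.4)), 0)
  expect_equal(ks_distance(f(-1), f(1)), 1)
  # N(0,1) vs N(1,1): maximal gap 2*pnorm(0.5) - 1
  set.seed(5)
  a <- structure(list(grid = sort(rnorm(1e4)), cum = (1:1e4) / 1e4),
                 class = "fcd_cdf")
  b <- structure(list(grid = sort(rnorm(1e4, 1)), cum = (1:1e4) / 1e4),
                 class = "fcd_cdf")
  expect_lt(abs(ks_distance(a, b) - (2 * pnorm(0.5) - 1)), 0.02)
  # metric properties on random triples
  for (s in 1:10) {
    set.seed(s)
    cds <- lapply(1:3, function(i)
      structure(list(grid = sort(runif(50, -1, 1)), cum = (1:50) / 50),
                class = "fcd_cdf"))
    d12 <- ks_distance(cds[[1]], cds[[2]])
    d21 <- ks_distance(cds[[2]], cds[[1]])
    d13 <- ks_distance(cds[[1]], cds[[3]])
    d23 <- ks_distance(cds[[2]], cds[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})
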