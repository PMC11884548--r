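test_that("theta induces regional parameters linearly with guards", {
  sub <- small_substrate(16L)
  cp <- regional_params(mfm_theta(c_w = 0.5, c_I = 0.3, c_s = 0.005),
                        sub$myelin, sub$gradient)
  expect_equal(cp$w, rep(0.5, 16))
  ident <- regional_params(mfm_theta(a_w = 1, b_w = 0, c_w = 0,
                                     c_s = 0.005),
                           pmax(sub$myelin, 0.01), sub$gradient)
  expect_equal(ident$w, pmax(sub$myelin, 0.01))
  expect_error(regional_params(mfm_theta(c_s = -0.1), sub$myelin,
                               sub$gradient), "invalid theta")
  expect_error(mfm_theta(G = NaN), "finite")
})

test_that("transfer function handles its removable singularity", {
  tc <- transfer_constants()
  expect_equal(transfer_rate(tc$b / tc$a), 1 / tc$d_t, tolerance = 1e-6)
  expect_equal(transfer_rate((tc$b + 10) / tc$a),
               10 / (1 - exp(-10 * tc$d_t)), tolerance = 1e-3)
  grid <- transfer_rate(seq(0, 1, length.out = 200))
  expect_true(all(diff(grid) >= 0))
})

test_that("deterministic single-region dynamics reach the exact fixed point", {
  tc <- transfer_constants()
  cp <- structure(list(w = 0.5, I = 0.3, sigma = 1e-12, G = 0),
                  class = "circuit_params")
  S <- mfm_simulate(cp, matrix(0, 1, 1), duration = 20, burn_in = 20,
                    seed = 1L)
  root <- uniroot(function(s) {
    x <- 0.5 * tc$J * s + 0.3
    -s / tc$tau_s + tc$gamma_k * (1 - s) * transfer_rate(x, tc)
  }, c(1e-6, 0.999), tol = 1e-10)$root
  expect_equal(S[nrow(S), 1], root, tolerance = 1e-6)
})

test_that("simulation respects symmetry, determinism and independence", {
  # identical regions + symmetric ring coupling + zero noise:
  # all trajectories identical
  N <- 6L
  ring <- matrix(as.numeric(abs(outer(1:N, 1:N, "-")) %in% c(1, N - 1)),
                 N, N)
  cp <- structure(list(w = rep(0.6, N), I = rep(0.31, N),
                       sigma = rep(1e-12, N), G = 1),
                  class = "circuit_params")
  S <- mfm_simulate(cp, ring, duration = 10, burn_in = 5, seed = 2L)
  expect_lt(max(apply(S, 1L, sd)), 1e-10)
  # seeded reproducibility
  cp$sigma <- rep(0.005, N)
  S1 <- mfm_simulate(cp, ring, duration = 5, burn_in = 1, seed = 3L)
  S2 <- mfm_simulate(cp, ring, duration = 5, burn_in = 1, seed = 3L)
  expect_identical(S1, S2)
  expect_true(all(S1 >= 0 & S1 <= 1))
  # G = 0: regions decorrelate as T grows
  cp0 <- structure(list(w = rep(0.9, N), I = rep(0.31, N),
                        sigma = rep(0.01, N), G = 0),
                   class = "circuit_params")
  Sg <- mfm_simulate(cp0, ring, duration = 1200, burn_in = 20, seed = 4L,
                     store_dt = 0.6)
  fc <- static_fc(Sg)
  expect_lt(mean(abs(fc[upper.tri(fc)])), 0.05)
  expect_error(mfm_simulate(cp, ring, duration = 5, dt = 0.05), "dt")
})

test_that("hemodynamic model relaxes, peaks once, and tracks TR", {
  # constant drive converges to a constant
  Sc <- matrix(0.15, 6000, 1)
  B <- mfm_bold(Sc, 0.01, hemo_constants(TR = 0.5))
  late <- B[(nrow(B) - 20):nrow(B), 1]
  expect_lt(sd(late), 1e-6)
  # impulse: single-peaked response, back near baseline within 30 s
  Simp <- matrix(0.05, 6000, 1)
  Simp[1000:1050, 1] <- 0.6
  Bi <- mfm_bold(Simp, 0.01, hemo_constants(TR = 0.5))[, 1]
  base <- Bi[15]
  pk <- which.max(Bi)
  expect_gt(Bi[pk], base)
  expect_lt(abs(Bi[110] - base), 0.2 * (Bi[pk] - base))  # 55 s later
  # any secondary excursion (undershoot) is smaller than the main peak
  post <- Bi[(pk + 5):110]
  expect_lt(max(abs(post - base)), Bi[pk] - base)
  # doubling TR halves the number of samples
  expect_equal(nrow(mfm_bold(Sc, 0.01, hemo_constants(TR = 1))),
               nrow(B) %/% 2L)
  expect_error(mfm_bold(Sc + 2, 0.01), "0, 1")
})

test_that("fit cost is zero on self-comparison and guards invalid theta", {
  sub <- small_substrate(16L)
  st <- sim_settings(n_tr = 120L, window_length = 40L)
  th <- mfm_theta(a_w = 0.12, b_w = -0.08, c_w = 0.9, c_I = 0.315,
                  c_s = 0.01, G = 1)
  gd <- synthetic_group_data(th, sub, st, seed = 77L)
  self <- fit_cost(th, gd, st, seed = 77L)
  expect_equal(self[["r"]], 1, tolerance = 1e-12)
  expect_equal(self[["ks"]], 0, tolerance = 1e-12)
  expect_equal(self[["cost"]], 0, tolerance = 1e-12)
  bad <- th; bad["c_s"] <- -1
  expect_equal(fit_cost(unclass(bad), gd, st)[["cost"]], Inf)
  other <- fit_cost(mfm_theta(c_w = 0.4, c_I = 0.3, c_s = 0.008, G = 0.5),
                    gd, st, seed = 5L)
  expect_gte(other[["cost"]], 0)
  expect_lte(other[["cost"]], 3)
})

test_that("CMA-ES minimizes a quadratic and keeps an elitist trace", {
  sphere <- function(x) sum((x - c(1, -2, 0.5))^2)
  run <- cmaes_minimize(sphere, c(0, 0, 0), sigma0 = 0.5,
                        n_iterations = 60L, seed = 1L)
  expect_lt(run$best_f, 1e-4)
  expect_true(all(diff(run$trace) <= 0))
  run2 <- cmaes_minimize(sphere, c(0, 0, 0), sigma0 = 0.5,
                         n_iterations = 60L, seed = 1L)
  expect_identical(run$best_x, run2$best_x)
  # non-finite objective values are tolerated
  holey <- function(x) if (x[1] < 0) NaN else sum(x^2)
  run3 <- cmaes_minimize(holey, c(2, 2), sigma0 = 0.3, n_iterations = 40L,
                         seed = 2L)
  expect_lt(run3$best_f, 1e-2)
})

test_that("excitability perturbation lowers measured Hurst (core premise)", {
  sub <- small_substrate(40L)
  prem <- ei_premise_experiment(sub, n_seeds = 4L, duration = 250,
                                seed = 11L)
  expect_true(mean(prem$delta) < 0)
  expect_true(all(is.finite(prem$delta)))
})
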