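test_that("time-delay embedding builds the documented lag rows", {
  m <- embed_series(1:5, E = 2, tau = 1)
  expect_equal(unname(m), cbind(2:5, 1:4), ignore_attr = TRUE)
  expect_equal(attr(m, "time"), 2:5)
  # E = 1 is the identity
  expect_equal(as.numeric(embed_series(1:7, E = 1)), 1:7)
  # E = 3, tau = 2 on 10 points: rows start at t = 5 (hand enumeration)
  m2 <- embed_series(1:10, E = 3, tau = 2)
  expect_equal(nrow(m2), 6)
  expect_equal(unname(m2[1, ]), c(5, 3, 1))
  expect_equal(unname(m2[6, ]), c(10, 8, 6))
  expect_error(embed_series(1:3, E = 4), "short")
  # missing lags are dropped with bookkeeping
  x <- c(1, 2, NA, 4, 5, 6)
  m3 <- embed_series(x, E = 2, tau = 1)
  expect_equal(attr(m3, "time"), c(2, 5, 6))
})

test_that("simplex projection is near-perfect on a noise-free logistic map", {
  x <- numeric(500); x[1] <- 0.31
  for (t in 1:499) x[t + 1] <- 3.8 * x[t] * (1 - x[t])
  sx <- simplex(x, E_range = 1:4)
  expect_gt(sx$rho[sx$E == 2], 0.99)
})

test_that("simplex on i.i.d. noise has skill indistinguishable from zero", {
  set.seed(21)
  x <- rnorm(400)
  sx <- simplex(x, E_range = 2)
  expect_lt(abs(sx$rho), 2 / sqrt(sx$n_pred))
})

test_that("the predictee is excluded from its own neighbour set", {
  set.seed(22)
  x <- rnorm(300)
  # tp = 0 asks the map to reproduce a coordinate of the state itself;
  # without exclusion the point would be its own neighbour and skill would
  # be exactly 1, so any skill strictly below 1 shows the exclusion works
  sx <- simplex(x, E_range = 2, tp = 0)
  expect_lt(sx$rho, 1 - 1e-4)
  expect_error(simplex(rep(1, 50)), "constant")
})

test_that("S-map with theta = 0 reproduces the global OLS fit", {
  set.seed(31)
  X <- cbind(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  y <- 1.5 * X[, "a"] - 0.7 * X[, "c"] + rnorm(80, 0, 0.3)
  sm <- smap(X, y, theta = 0)
  ols <- coef(lm(y ~ X))
  for (t in c(1, 40, 80)) {
    expect_equal(unname(sm$intercepts[t]), unname(ols[1]), tolerance = 1e-8)
    expect_equal(unname(sm$coefficients[t, ]), unname(ols[-1]),
                 tolerance = 1e-8)
  }
})

test_that("S-map recovers a known linear generator at any theta", {
  set.seed(32)
  X <- cbind(x1 = runif(120), x2 = runif(120))
  y <- 2 * X[, "x1"] - 3 * X[, "x2"] + rnorm(120, 0, 1e-8)
  for (th in c(0, 1, 4)) {
    sm <- smap(X, y, theta = th)
    expect_equal(unname(colMeans(sm$coefficients, na.rm = TRUE)), c(2, -3),
                 tolerance = 1e-5)
    expect_lt(max(abs(sm$coefficients[, "x1"] - 2), na.rm = TRUE), 1e-4)
  }
})

test_that("S-map flags singular designs and null drivers average to zero", {
  set.seed(33)
  X <- cbind(x1 = rnorm(60), flat = rep(1, 60))
  y <- X[, "x1"] + rnorm(60, 0, 0.1)
  sm <- smap(X, y, theta = 2)
  expect_true(all(is.na(sm$coefficients)))   # intercept column collinear
  # driver with no causal role
  X2 <- cbind(x1 = rnorm(150), noise = rnorm(150))
  y2 <- 2 * X2[, "x1"] + rnorm(150, 0, 0.2)
  sm2 <- smap(X2, y2, theta = 1)
  expect_lt(abs(mean(sm2$coefficients[, "noise"], na.rm = TRUE)), 0.1)
  expect_gt(mean(sm2$coefficients[, "x1"], na.rm = TRUE), 1.8)
})

test_that("S-map coefficients vary continuously with theta", {
  set.seed(34)
  X <- cbind(x1 = rnorm(70), x2 = rnorm(70))
  y <- X[, "x1"] * (1 + 0.5 * X[, "x2"]) + rnorm(70, 0.05)
  a <- smap(X, y, theta = 1)$coefficients
  b <- smap(X, y, theta = 1 + 1e-5)$coefficients
  expect_lt(max(abs(a - b), na.rm = TRUE), 1e-3)
})

test_that("cross-map standard error follows the analytic form", {
  expect_equal(cross_map_se(1, 100), 0)
  expect_equal(cross_map_se(0, 259), 0.0625)
  expect_equal(cross_map_se(0.5, 103), sqrt(0.75 / 100))
  expect_error(cross_map_se(0.2, 3), "N")
  expect_error(cross_map_se(1.2, 50), "rho")
})

test_that("CCM detects implanted unidirectional coupling and its absence", {
  # x drives y (beta_yx > 0); y does not drive x (beta_xy = 0)
  cfg <- coupled_map_config(r_x = 3.7, r_y = 3.72, beta_xy = 0, beta_yx = 0.35,
                            n_steps = 500, burn_in = 100, seed = 3)
  d <- gen_coupled_logistic(cfg)
  libs <- c(20, 50, 100, 200, 350)
  fwd <- ccm(d$x, d$y, E = 2, tp = 0, lib_sizes = libs, n_samples = 40,
             seed = 101)
  rev <- ccm(d$y, d$x, E = 2, tp = 0, lib_sizes = libs, n_samples = 40,
             seed = 102)
  expect_true(fwd$converged)     # x recoverable from y's manifold
  expect_false(rev$converged)
  expect_gt(fwd$rho_max, rev$rho_max)
  # skill grows with library size for the true direction
  expect_gt(cor(fwd$by_lib$lib_size, fwd$by_lib$rho, method = "spearman"),
            0.5)
})

test_that("CCM finds nothing between independent chaotic series", {
  cfg <- coupled_map_config(beta_xy = 0, beta_yx = 0, n_steps = 400,
                            burn_in = 100, seed = 5)
  d <- gen_coupled_logistic(cfg)
  libs <- c(20, 60, 150, 280)
  fwd <- ccm(d$x, d$y, E = 2, tp = 0, lib_sizes = libs, n_samples = 30,
             seed = 201)
  rev <- ccm(d$y, d$x, E = 2, tp = 0, lib_sizes = libs, n_samples = 30,
             seed = 202)
  expect_false(fwd$converged)
  expect_false(rev$converged)
  expect_lt(abs(fwd$rho_max), 0.25)
})

test_that("CCM is bit-reproducible under a fixed seed", {
  cfg <- coupled_map_config(n_steps = 300, burn_in = 50, seed = 9)
  d <- gen_coupled_logistic(cfg)
  a <- ccm(d$x, d$y, E = 2, lib_sizes = c(30, 100, 200), n_samples = 20,
           seed = 7)
  b <- ccm(d$x, d$y, E = 2, lib_sizes = c(30, 100, 200), n_samples = 20,
           seed = 7)
  expect_identical(a$by_lib, b$by_lib)
  expect_error(ccm(d$x, d$y, E = 2, lib_sizes = 300, n_samples = 5, seed = 1),
               "exceeds")
  expect_error(ccm(d$x, d$y, E = 2, n_samples = 0, seed = 1), "n_samples")
})
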