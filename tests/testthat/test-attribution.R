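test_that("weekly aggregation folds years into 52 bins with bookkeeping", {
  rec <- daily_records(2016:2020)
  wk <- weekly_aggregate(rec)
  expect_equal(attr(wk, "retained"), 260)
  expect_true(all(wk$WEEK >= 1 & wk$WEEK <= 52))
  # first week of the first year omitted
  wk2 <- weekly_aggregate(rec, omit_weeks = data.frame(YEAR = 2016, WEEK = 1))
  expect_equal(attr(wk2, "retained"), 259)
  # one year, no omissions
  expect_equal(attr(weekly_aggregate(daily_records(2018)), "retained"), 52)
  # omitting a whole year
  omit <- data.frame(YEAR = 2017, WEEK = 1:52)
  expect_equal(attr(weekly_aggregate(rec, omit_weeks = omit), "retained"),
               208)
  expect_error(weekly_aggregate(rec[0, ]), "empty")
})

test_that("retained count equals 52*years - omissions for random sets", {
  rec <- daily_records(2016:2018)
  set.seed(41)
  for (i in 1:10) {
    k <- sample(0:30, 1)
    om <- unique(data.frame(YEAR = sample(2016:2018, k, replace = TRUE),
                            WEEK = sample(1:52, k, replace = TRUE)))
    wk <- weekly_aggregate(rec, omit_weeks = om)
    expect_equal(attr(wk, "retained"), 52 * 3 - nrow(om))
  }
})

test_that("cross-correlation recovers a pure shift and is antisymmetric", {
  set.seed(42)
  x <- rnorm(200)
  y <- c(rep(NA, 3), x[1:197])   # y_t = x_{t-3}
  cc <- cross_correlation(x, y, max_lag = 10)
  expect_equal(cc$best_lag, 3)
  expect_equal(cc$r_at_best, 1, tolerance = 1e-12)
  expect_true(cc$ci95[1] <= 1 && cc$ci95[2] >= cc$r_at_best - 1e-9)
  rev <- cross_correlation(y, x, max_lag = 10)
  expect_equal(rev$best_lag, -3)
  # df follows the full aligned series convention
  expect_equal(cc$df, sum(is.finite(x) & is.finite(y)) - 2)
  expect_error(cross_correlation(x, rep(1, 200), max_lag = 5), "constant")
})

test_that("breakpoint estimator finds a noise-free knee exactly", {
  swc <- seq(70, 100, 0.25)
  gpp <- ifelse(swc < 82.5, 3 - 0.1 * (82.5 - swc), 3)
  bp <- breakpoint(gpp, swc, grid = seq(72, 98, 0.5), n_boot = 50, seed = 2)
  expect_true(bp$has_break)
  expect_equal(bp$threshold_est, 82.5)
  expect_lte(bp$sse_segmented, bp$sse_linear)
})

test_that("a pure linear relation yields a no-breakpoint verdict", {
  set.seed(43)
  x <- runif(100, 70, 100)
  y <- 0.05 * x + rnorm(100, 0, 0.1)
  bp <- breakpoint(y, x, grid = seq(75, 95, 0.5), n_boot = 0)
  expect_false(bp$has_break)
})

test_that("bootstrap CI covers the knee and error shrinks with noise", {
  # coverage at moderate noise
  cover <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    x <- runif(150, 70, 95)
    signal <- ifelse(x < 80, 2.5 - 0.12 * (80 - x), 2.5)
    y <- signal + rnorm(150, 0, 0.2 * sd(signal))
    bp <- breakpoint(y, x, grid = seq(72, 93, 0.5), n_boot = 200, seed = s)
    if (bp$bootstrap_ci[1] <= 80 && bp$bootstrap_ci[2] >= 80)
      cover <- cover + 1
  }
  expect_gte(cover, 9)
  # consistency: estimation error shrinks as noise vanishes
  errs <- vapply(c(0.3, 0.1, 0.01), function(sg) {
    set.seed(77)
    x <- runif(200, 70, 95)
    y <- ifelse(x < 80, 2.5 - 0.12 * (80 - x), 2.5) + rnorm(200, 0, sg)
    abs(breakpoint(y, x, grid = seq(72, 93, 0.5), n_boot = 0)$threshold_est -
          80)
  }, numeric(1))
  expect_true(errs[3] <= errs[1] + 0.5 && errs[3] <= 0.5)
  expect_error(breakpoint(1:30, seq(70, 99, by = 1), grid = c(60, 80)),
               "range")
})

test_that("redundancy analysis matches a brute-force eigen oracle", {
  set.seed(44)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("GPP", "RECO")))
  r <- rda_ordination(Y, X)
  # oracle: eigendecomposition of the fitted-value covariance
  Ys <- scale(Y); Xs <- scale(X)
  Yhat <- Xs %*% solve(crossprod(Xs), crossprod(Xs, Ys))
  ev <- eigen(crossprod(Yhat) / (nrow(Y) - 1))
  expect_equal(r$eig, ev$values[ev$values > 1e-10], tolerance = 1e-8)
  # axes orthonormal (site scores have unit variance, zero correlation)
  cs <- crossprod(r$site_scores) / (nrow(Y) - 1)
  expect_equal(cs, diag(ncol(cs)), tolerance = 1e-8, ignore_attr = TRUE)
  # variance accounting
  expect_lte(r$total_constrained, r$total_variance + 1e-10)
  expect_true(all(diff(r$proportion_explained) <= 1e-12))
  expect_true(all(r$proportion_explained >= 0 &
                    r$proportion_explained <= 1))
})

test_that("RDA agrees with vegan on eigenvalues", {
  skip_if_not_installed("vegan")
  set.seed(45)
  X <- matrix(rnorm(160), 40, 4)
  Y <- X %*% matrix(rnorm(8), 4, 2) + matrix(rnorm(80, 0, 0.5), 40, 2)
  colnames(Y) <- c("GPP", "RECO"); colnames(X) <- paste0("x", 1:4)
  ours <- rda_ordination(Y, X)
  ref <- vegan::rda(scale(Y) ~ scale(X))
  expect_equal(unname(ours$eig),
               unname(ref$CCA$eig[seq_along(ours$eig)]), tolerance = 1e-8)
})

test_that("RDA handles exact fits, orthogonal noise and collinearity", {
  set.seed(46)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  B <- matrix(rnorm(8), 4, 2)
  Yexact <- X %*% B
  colnames(Yexact) <- c("GPP", "RECO")
  r1 <- rda_ordination(Yexact, X)
  expect_equal(sum(r1$proportion_explained), 1, tolerance = 1e-8)
  # independent noise: little variance explained at large n
  Yn <- matrix(rnorm(1000), 500, 2, dimnames = list(NULL, c("GPP", "RECO")))
  Xn <- matrix(rnorm(2000), 500, 4)
  r2 <- rda_ordination(Yn, Xn)
  expect_lt(sum(r2$proportion_explained), 0.05)
  # collinear column dropped with a message
  Xc <- cbind(X, dup = X[, 1])
  expect_message(r3 <- rda_ordination(Yexact, Xc), "collinear")
  expect_equal(r3$dropped, "dup")
})
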