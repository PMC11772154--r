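# Empirical dynamic modelling from first principles: time-delay embedding,
# simplex projection (nearest-neighbour forecasting used to select the
# embedding dimension), S-map locally linear coefficients (time-varying
# interaction strengths), and convergent cross mapping (CCM) with analytic
# standard errors.
#
# Conventions used throughout (documented once here):
#  - distances are Euclidean; state blocks should be standardized (z-score)
#    before embedding multivariate data;
#  - simplex/CCM use E + 1 neighbours with exponential weights
#    w_i = exp(-d_i / d_min) and a floor of 1e-6 (duplicate states give
#    d_min = 0: exact duplicates then share weight 1);
#  - the predictee is never its own neighbour (leave-one-out), with an
#    optional Theiler exclusion window on |time difference|;
#  - ties among equidistant neighbours break by time index (stable order),
#    so every result is deterministic given the seed.

#' Time-delay embedding of a scalar series
#'
#' Builds the lag-coordinate block whose row for time t is
#' (x_t, x_{t-tau}, ..., x_{t-(E-1)tau}). Rows containing any missing lag are
#' dropped; the original time index of each retained row is kept in the
#' `time` attribute so downstream alignment never relies on row position.
#'
#' @param x Numeric series.
#' @param E Embedding dimension (>= 1).
#' @param tau Lag step in sampling intervals (>= 1).
#' @return Matrix with E columns and attribute `time` (original indices).
#' @examples
#' embed_series(1:5, E = 2, tau = 1)  # rows (2,1) (3,2) (4,3) (5,4)
#' @export
embed_series <- function(x, E, tau = 1) {
  if (E < 1 || tau < 1) stop("E and tau must be >= 1")
  n <- length(x)
  if (n <= (E - 1) * tau) stop("series too short for this embedding")
  t0 <- seq.int((E - 1) * tau + 1, n)
  M <- vapply(0:(E - 1), function(k) x[t0 - k * tau], numeric(length(t0)))
  M <- matrix(M, ncol = E)
  keep <- rowSums(!is.finite(M)) == 0
  M <- M[keep, , drop = FALSE]
  attr(M, "time") <- t0[keep]
  colnames(M) <- paste0("lag", 0:(E - 1))
  M
}

# Simplex-style nearest-neighbour prediction of y at each focal row of an
# embedded block, using only library rows. `D` is the full pairwise distance
# matrix between rows; `lib` an index multiset (duplicates allowed); `times`
# the time index per row; `excl` the Theiler window.
.nn_predict <- function(D, y, lib, times, pred, k, excl = 0) {
  out <- rep(NA_real_, length(pred))
  lib_t <- times[lib]
  for (m in seq_along(pred)) {
    i <- pred[m]
    ok <- abs(lib_t - times[i]) > excl     # excludes self (diff 0) too
    if (sum(ok) < k) next
    cand <- lib[ok]
    d <- D[i, cand]
    o <- order(d, times[cand])             # stable tie-break by time
    nn <- o[seq_len(k)]
    dn <- d[nn]
    dmin <- dn[1]
    w <- if (dmin > 0) exp(-dn / dmin) else as.numeric(dn == 0)
    w <- pmax(w, 1e-6)
    yn <- y[cand][nn]
    fin <- is.finite(yn)
    if (!any(fin)) next
    out[m] <- sum(w[fin] * yn[fin]) / sum(w[fin])
  }
  out
}

.dist_matrix <- function(M) as.matrix(stats::dist(M))

#' Simplex projection: forecast skill across embedding dimensions
#'
#' Leave-one-out nearest-neighbour forecasting of x_{t+tp} from the
#' E-dimensional lag state at t, with E + 1 exponentially weighted
#' neighbours. The embedding dimension maximizing the Pearson correlation
#' between forecasts and observations is reported as `best_E`.
#'
#' @param x Numeric series.
#' @param E_range Candidate embedding dimensions (default 1:10).
#' @param tau Lag step (default 1).
#' @param tp Prediction horizon in steps (default 1).
#' @param exclusion_radius Theiler window: neighbours within this many time
#'   steps of the predictee are excluded (default 0 = self only).
#' @return data.frame with columns `E`, `rho`, `n_pred`; attribute `best_E`.
#' @export
simplex <- function(x, E_range = 1:10, tau = 1, tp = 1,
                    exclusion_radius = 0) {
  if (sd(x, na.rm = TRUE) == 0)
    stop("constant series: forecast skill undefined")
  res <- lapply(E_range, function(E) {
    M <- embed_series(x, E, tau)
    times <- attr(M, "time")
    y <- rep(NA_real_, length(times))
    tgt <- times + tp
    ok <- tgt >= 1 & tgt <= length(x)
    y[ok] <- x[tgt[ok]]
    valid <- which(is.finite(y))
    if (length(valid) < E + 2) return(data.frame(E = E, rho = NA_real_,
                                                 n_pred = 0L))
    D <- .dist_matrix(M)
    pred <- .nn_predict(D, y, lib = seq_len(nrow(M)), times = times,
                        pred = valid, k = E + 1, excl = exclusion_radius)
    fin <- is.finite(pred) & is.finite(y[valid])
    data.frame(E = E, rho = cor(pred[fin], y[valid][fin]),
               n_pred = sum(fin))
  })
  out <- do.call(rbind, res)
  attr(out, "best_E") <- out$E[which.max(out$rho)]
  out
}

#' S-map locally linear coefficients (time-varying interaction strengths)
#'
#' For every row t of a multivariate state block, solves the locally weighted
#' least-squares linear map predicting the target from the block, with
#' weights \eqn{w_i = \exp(-\theta\, d(x_i, x_t) / \bar d_t)} where
#' \eqn{\bar d_t} is the mean distance to the focal state. The solution uses
#' a singular-value decomposition with a relative tolerance, and weeks whose
#' weighted design is numerically singular get NA coefficients. With
#' \eqn{\theta = 0} all weights are 1 and every week reproduces the global
#' ordinary-least-squares fit. Coefficients are partial derivatives
#' d(target)/d(driver) in the units of the (possibly standardized) inputs.
#'
#' @param block Matrix or data.frame of driver columns (the state space).
#'   Columns are used as-is; standardize beforehand if comparability of
#'   coefficient magnitudes across drivers is wanted.
#' @param target Numeric vector, one value per row of `block`.
#' @param theta Nonlinearity parameter (>= 0).
#' @param tp Prediction horizon: the fit at row t predicts
#'   `target[t + tp]` (default 0: pre-aligned input).
#' @return Object of class `smap_result`: list with `coefficients`
#'   (rows = weeks, one column per driver), `intercepts`, `forecast_skill`
#'   (rho between in-sample local predictions and observations), `theta`,
#'   `target_name`.
#' @export
smap <- function(block, target, theta = 0, tp = 0) {
  if (theta < 0) stop("theta must be >= 0")
  X <- as.matrix(block)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(target) != n) stop("target must align with block rows")
  y <- rep(NA_real_, n)
  idx <- seq_len(n) + tp
  ok <- idx >= 1 & idx <= n
  y[ok] <- target[idx[ok]]
  usable <- which(is.finite(y) & rowSums(!is.finite(X)) == 0)
  if (length(usable) < ncol(X) + 2) stop("too few complete rows for S-map")
  D <- .dist_matrix(X[usable, , drop = FALSE])
  p <- ncol(X)
  coefs <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  icept <- rep(NA_real_, n)
  pred <- rep(NA_real_, n)
  Xu <- cbind(`(Intercept)` = 1, X[usable, , drop = FALSE])
  yu <- y[usable]
  for (m in seq_along(usable)) {
    d <- D[m, ]
    dbar <- mean(d[-m])
    w <- if (theta == 0 || dbar == 0) rep(1, length(d)) else
      exp(-theta * d / dbar)
    sw <- sqrt(w)
    fit <- tryCatch(.svd_lstsq(Xu * sw, yu * sw), error = function(e) NULL)
    if (is.null(fit)) next
    t_orig <- usable[m]
    icept[t_orig] <- fit[1]
    coefs[t_orig, ] <- fit[-1]
    pred[t_orig] <- sum(Xu[m, ] * fit)
  }
  fin <- is.finite(pred) & is.finite(y)
  skill <- if (sum(fin) > 2) cor(pred[fin], y[fin]) else NA_real_
  structure(list(coefficients = coefs, intercepts = icept,
                 forecast_skill = skill, theta = theta,
                 target_name = deparse(substitute(target))),
            class = "smap_result")
}

# Least squares via SVD with relative singular-value tolerance; errors on
# effectively rank-deficient systems.
.svd_lstsq <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  if (!all(keep)) stop("singular design")
  drop(sv$v %*% ((crossprod(sv$u, b)) / sv$d))
}

#' @export
print.smap_result <- function(x, ...) {
  cat("S-map result (theta =", x$theta, ")\n")
  cat("  drivers:", paste(colnames(x$coefficients), collapse = ", "), "\n")
  cat("  predictable weeks:", sum(is.finite(x$intercepts)), "\n")
  cat("  forecast skill (rho):", format(x$forecast_skill, digits = 3), "\n")
  invisible(x)
}

#' Standard error of a cross-map skill estimate
#'
#' \eqn{SE = \sqrt{(1 - \rho^2)/(N - 3)}} where N is the library size
#' (number of weeks) at that step of the CCM.
#'
#' @param rho Cross-map skill (Pearson correlation, |rho| <= 1).
#' @param N Library size (> 3).
#' @return SE, same length as `rho`.
#' @examples
#' cross_map_se(0, 259)  # 1/16
#' @export
cross_map_se <- function(rho, N) {
  if (any(N <= 3)) stop("N must exceed 3")
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE)) stop("|rho| must be <= 1")
  sqrt(pmax(1 - rho^2, 0) / (N - 3))
}

#' Convergent cross mapping between a putative cause and an effect
#'
#' Reconstructs the shadow manifold of the EFFECT series by time-delay
#' embedding and cross-maps the CAUSE from it: if the cause drives the
#' effect, its values are recoverable from the effect's manifold with skill
#' that grows (converges) as the library of manifold points enlarges.
#' Libraries are drawn with replacement (`n_samples` per size, seeded); skill
#' is the mean Pearson correlation between observed and cross-mapped cause
#' values. Convergence is declared when skill at the largest library exceeds
#' skill at the smallest by more than `conv_gain` and is significant at
#' 1.96 analytic standard errors.
#'
#' @param cause Numeric series (the variable being cross-mapped, i.e. the
#'   putative driver).
#' @param effect Numeric series (the variable whose manifold is built).
#' @param E Embedding dimension for the effect manifold (default: chosen by
#'   [simplex()] over 1:10 on the effect series).
#' @param tau Lag step (default 1 week).
#' @param tp Cross-map horizon: the cause is taken at t + tp relative to the
#'   effect state at t. The default -1 reads "causes precede effects by one
#'   week".
#' @param lib_sizes Increasing library sizes; default: 5 sizes from
#'   about E + 2 up to the number of available manifold points.
#' @param n_samples Random libraries per size (default 100).
#' @param seed Integer seed for library sampling (required for
#'   reproducibility).
#' @param exclusion_radius Theiler window (default 0).
#' @param conv_gain Minimum skill gain from smallest to largest library
#'   (default 0.1).
#' @return Object of class `ccm_result`: data.frame `by_lib` with columns
#'   `lib_size`, `rho`, `se`; plus `rho_max`, `converged`, `E`, `tp`,
#'   `cause_name`, `effect_name`.
#' @export
ccm <- function(cause, effect, E = NULL, tau = 1, tp = -1,
                lib_sizes = NULL, n_samples = 100, seed,
                exclusion_radius = 0, conv_gain = 0.1) {
  if (missing(seed)) stop("seed is required")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (length(cause) != length(effect))
    stop("cause and effect must be aligned and equally long")
  cz <- as.numeric(scale(cause))
  ez <- as.numeric(scale(effect))
  if (is.null(E)) {
    sx <- simplex(ez, E_range = 1:10, tau = tau, tp = 1,
                  exclusion_radius = exclusion_radius)
    E <- attr(sx, "best_E")
  }
  M <- embed_series(ez, E, tau)
  times <- attr(M, "time")
  y <- rep(NA_real_, length(times))
  tgt <- times + tp
  ok <- tgt >= 1 & tgt <= length(cz)
  y[ok] <- cz[tgt[ok]]
  valid <- which(is.finite(y))
  n_avail <- length(valid)
  if (is.null(lib_sizes)) {
    lo <- max(E + 2, 10)
    if (n_avail <= lo) stop("too few points for CCM")
    lib_sizes <- unique(round(seq(lo, n_avail, length.out = 5)))
  }
  lib_sizes <- sort(unique(as.integer(lib_sizes)))
  if (max(lib_sizes) > n_avail)
    stop("largest library size exceeds available points (", n_avail, ")")
  D <- .dist_matrix(M)
  k <- E + 1
  set.seed(as.integer(seed))
  rho_mean <- se <- numeric(length(lib_sizes))
  for (li in seq_along(lib_sizes)) {
    L <- lib_sizes[li]
    rhos <- vapply(seq_len(n_samples), function(s) {
      lib <- sample(valid, L, replace = TRUE)
      ph <- .nn_predict(D, y, lib = lib, times = times, pred = valid,
                        k = k, excl = exclusion_radius)
      fin <- is.finite(ph)
      if (sum(fin) < 4 || sd(ph[fin]) == 0) return(NA_real_)
      cor(ph[fin], y[valid][fin])
    }, numeric(1))
    rho_mean[li] <- mean(rhos, na.rm = TRUE)
    se[li] <- cross_map_se(min(abs(rho_mean[li]), 1), L)
  }
  rho_max <- rho_mean[length(lib_sizes)]
  converged <- isTRUE(
    (rho_max - rho_mean[1]) > conv_gain &&
      rho_max > 1.96 * se[length(lib_sizes)])
  structure(list(
    by_lib = data.frame(lib_size = lib_sizes, rho = rho_mean, se = se),
    rho_max = rho_max, converged = converged, E = E, tp = tp,
    cause_name = deparse(substitute(cause)),
    effect_name = deparse(substitute(effect))),
    class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat("CCM", x$cause_name, "->", x$effect_name,
      sprintf("(E = %d, tp = %d)\n", x$E, x$tp))
  print(x$by_lib, row.names = FALSE)
  cat(sprintf("rho_max = %.3f; converged: %s\n", x$rho_max, x$converged))
  invisible(x)
}
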