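# Downstream attribution: calendar-week aggregation with exact week-count
# bookkeeping, lagged cross-correlation (e.g. ET leading soil-water decline),
# segmented-regression threshold (breakpoint) estimation for the GPP-SWC
# relation, and redundancy analysis (constrained ordination) of weekly
# causal-strength estimates.

#' Assign 52 seven-day week bins within each calendar year
#'
#' Weeks are anchored at January 1: bin w covers days of year
#' 7(w-1)+1 .. 7w, and the tail days 358-365/366 fold into bin 52, so every
#' year has exactly 52 bins.
#'
#' @param dates Date vector.
#' @return data.frame with integer columns `YEAR` and `WEEK` (1-52).
#' @export
week_bins <- function(dates) {
  dates <- as.Date(dates)
  yd <- as.integer(strftime(dates, "%j"))
  data.frame(YEAR = as.integer(strftime(dates, "%Y")),
             WEEK = pmin((yd - 1L) %/% 7L + 1L, 52L))
}

#' Aggregate records to the 52-bin weekly grid with omission bookkeeping
#'
#' Partitions each calendar year in `[period_start, period_end]` into 52
#' seven-day bins ([week_bins()]), averages all numeric columns per bin
#' (precipitation columns, matched by name `P` or `P_weekly`, are summed),
#' drops the bins listed in `omit_weeks`, and reports the retained count.
#'
#' @param records data.frame with a `date` column plus numeric channels.
#' @param period_start,period_end Dates bounding the analysis period
#'   (inclusive); default: the record range.
#' @param omit_weeks data.frame with columns `YEAR` and `WEEK` naming bins to
#'   drop (e.g. the first week of the first year when fluxes are absent), or
#'   NULL.
#' @return data.frame of weekly bins (columns `YEAR`, `WEEK`, `week_start`,
#'   then the aggregated channels) with attribute `retained` (row count).
#' @export
weekly_aggregate <- function(records, period_start = NULL, period_end = NULL,
                             omit_weeks = NULL) {
  if (!"date" %in% names(records)) stop("records need a 'date' column")
  if (nrow(records) == 0) stop("empty record set")
  d <- as.Date(records$date)
  if (is.null(period_start)) period_start <- min(d)
  if (is.null(period_end)) period_end <- max(d)
  keep <- d >= as.Date(period_start) & d <= as.Date(period_end)
  if (!any(keep)) stop("no records inside the period")
  rec <- records[keep, , drop = FALSE]
  wb <- week_bins(rec$date)
  num <- names(rec)[vapply(rec, is.numeric, logical(1))]
  key <- paste(wb$YEAR, wb$WEEK, sep = "-")
  agg <- lapply(num, function(v) {
    f <- if (v %in% c("P", "P_weekly")) function(z) sum(z, na.rm = TRUE)
         else function(z) mean(z, na.rm = TRUE)
    tapply(rec[[v]], key, f)
  })
  ukey <- sort(unique(key))
  parts <- do.call(rbind, strsplit(ukey, "-", fixed = TRUE))
  out <- data.frame(YEAR = as.integer(parts[, 1]),
                    WEEK = as.integer(parts[, 2]))
  for (i in seq_along(num)) out[[num[i]]] <- as.numeric(agg[[i]][ukey])
  out <- out[order(out$YEAR, out$WEEK), , drop = FALSE]
  if (!is.null(omit_weeks)) {
    om <- paste(omit_weeks$YEAR, omit_weeks$WEEK, sep = "-")
    out <- out[!(paste(out$YEAR, out$WEEK, sep = "-") %in% om), ,
               drop = FALSE]
  }
  out$week_start <- as.Date(paste0(out$YEAR, "-01-01")) + (out$WEEK - 1L) * 7L
  out <- out[, c("YEAR", "WEEK", "week_start",
                 setdiff(names(out), c("YEAR", "WEEK", "week_start")))]
  rownames(out) <- NULL
  attr(out, "retained") <- nrow(out)
  out
}

#' Lagged cross-correlation between two weekly series
#'
#' Pearson correlation of (x_t, y_{t+k}) for every lag k in
#' `[-max_lag, max_lag]`, on pairwise-complete observations. Positive lags
#' mean y follows x. The best lag maximizes |r|; its 95% confidence interval
#' comes from the Fisher z-transform with the pair count at that lag. The
#' reported degrees of freedom follow the conventional N - 2 with N the
#' complete aligned series length (not the lag-shortened pair count).
#'
#' @param x,y Aligned numeric series.
#' @param max_lag Maximum |lag| scanned, weeks.
#' @param detrend If TRUE, remove a linear trend from both series first
#'   (default FALSE: raw series).
#' @return list of class `ccf_result`: `best_lag`, `r_at_best`, `df`, `ci95`
#'   (length-2), `n_pairs`, and `r_by_lag` (data.frame lag/r/n).
#' @export
cross_correlation <- function(x, y, max_lag = 26, detrend = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must be aligned")
  if (n <= max_lag + 3) stop("series too short for max_lag")
  if (sd(x, na.rm = TRUE) == 0 || sd(y, na.rm = TRUE) == 0)
    stop("constant series: correlation undefined")
  if (detrend) {
    t <- seq_len(n)
    x <- stats::residuals(lm(x ~ t, na.action = stats::na.exclude))
    y <- stats::residuals(lm(y ~ t, na.action = stats::na.exclude))
  }
  lags <- -max_lag:max_lag
  tab <- do.call(rbind, lapply(lags, function(k) {
    if (k >= 0) { xi <- x[seq_len(n - k)]; yi <- y[seq_len(n - k) + k] }
    else        { xi <- x[seq_len(n + k) - k]; yi <- y[seq_len(n + k)] }
    ok <- is.finite(xi) & is.finite(yi)
    r <- if (sum(ok) > 3) cor(xi[ok], yi[ok]) else NA_real_
    data.frame(lag = k, r = r, n = sum(ok))
  }))
  best <- which.max(abs(tab$r))
  np <- tab$n[best]
  z <- atanh(tab$r[best])
  zse <- 1 / sqrt(np - 3)
  ci <- tanh(z + c(-1.96, 1.96) * zse)
  n_full <- sum(is.finite(x) & is.finite(y))
  structure(list(best_lag = tab$lag[best], r_at_best = tab$r[best],
                 df = n_full - 2L, ci95 = ci, n_pairs = np,
                 r_by_lag = tab),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("best lag = %d weeks, r = %.3f (df = %d, 95%% CI %.3f..%.3f)\n",
              x$best_lag, x$r_at_best, x$df, x$ci95[1], x$ci95[2]))
  invisible(x)
}

# Continuous two-segment design: below the knee psi the response picks up an
# extra slope on (x - psi); above it the basic line applies, and the two
# segments meet at psi.
.seg_sse <- function(x, y, psi) {
  X <- cbind(1, x, pmin(x - psi, 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Segmented-regression threshold (breakpoint) estimation
#'
#' Fits a continuous two-segment piecewise-linear model of `y` on `x` by
#' exhaustive grid search over candidate knees, minimizing the residual sum
#' of squares. A simple linear fit guards against over-segmentation: when the
#' segmented model does not beat the line by AIC, the verdict is
#' "no breakpoint". A seeded nonparametric bootstrap (resampling pairs)
#' yields a percentile confidence interval for the knee.
#'
#' @param y Response (e.g. growing-season GPP).
#' @param x Driver (e.g. SWC, percent).
#' @param grid Candidate knee positions; default: 0.5-unit steps spanning the
#'   central 90% of `x`.
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed Seed for the bootstrap.
#' @return list of class `breakpoint_result`: `threshold_est`, `has_break`,
#'   `sse_segmented`, `sse_linear`, `aic_segmented`, `aic_linear`,
#'   `bootstrap_ci` (2.5/97.5 percentiles), `coefficients`, `grid`.
#' @export
breakpoint <- function(y, x, grid = NULL, n_boot = 500, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 20) stop("need at least 20 paired observations")
  if (is.null(grid)) {
    qs <- quantile(x, c(0.05, 0.95))
    grid <- seq(ceiling(qs[1] * 2) / 2, floor(qs[2] * 2) / 2, by = 0.5)
  }
  if (min(grid) < min(x) || max(grid) > max(x))
    stop("candidate grid extends outside the data range")
  sses <- vapply(grid, function(p) .seg_sse(x, y, p), numeric(1))
  best <- which.min(sses)
  sse_seg <- sses[best]
  sse_lin <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  # AIC with the knee counted as a parameter: p_seg = 4, p_lin = 2 (+ sigma)
  aic_seg <- n * log(sse_seg / n) + 2 * 4
  aic_lin <- n * log(sse_lin / n) + 2 * 2
  has_break <- aic_seg < aic_lin
  psi <- grid[best]
  Xb <- cbind(1, x, pmin(x - psi, 0))
  cf <- stats::lm.fit(Xb, y)$coefficients
  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    for (b in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      sb <- vapply(grid, function(p) .seg_sse(x[i], y[i], p), numeric(1))
      boot[b] <- grid[which.min(sb)]
    }
  }
  structure(list(threshold_est = psi, has_break = has_break,
                 sse_segmented = sse_seg, sse_linear = sse_lin,
                 aic_segmented = aic_seg, aic_linear = aic_lin,
                 bootstrap_ci = quantile(boot, c(0.025, 0.975), na.rm = TRUE,
                                         names = FALSE),
                 coefficients = setNames(cf, c("intercept", "slope",
                                               "below_extra_slope")),
                 grid = grid),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  if (x$has_break)
    cat(sprintf("breakpoint at %.2f (95%% bootstrap CI %.2f..%.2f)\n",
                x$threshold_est, x$bootstrap_ci[1], x$bootstrap_ci[2]))
  else cat("no breakpoint (linear fit preferred by AIC)\n")
  invisible(x)
}

#' Redundancy analysis (constrained ordination)
#'
#' Multivariate least squares of the response matrix on the explanatory
#' matrix followed by a singular-value decomposition of the fitted values:
#' the classic RDA. Both matrices are standardized column-wise (z-scores),
#' so proportions explained refer to the correlation-scale variance of Y.
#' Collinear explanatory columns are dropped (with a message) via the QR
#' rank decision. Scores use correlation-style ("type 2") scaling: response
#' loadings carry the singular values, site scores are unit-variance axis
#' coordinates, and explanatory arrows are the correlations of each X column
#' with the site scores, matching the arrows-as-strength reading of an RDA
#' biplot.
#'
#' @param Y Response matrix/data.frame (e.g. weekly GPP, Reco).
#' @param X Explanatory matrix/data.frame (e.g. S-map strengths plus met
#'   variables).
#' @return list of class `rda_result`: `site_scores`, `response_loadings`,
#'   `arrows` (per explanatory variable), `eig` (axis variances),
#'   `proportion_explained`, `total_constrained`, `total_variance`,
#'   `dropped` (names of collinear columns removed).
#' @export
rda_ordination <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X need matching rows")
  cc <- stats::complete.cases(Y, X)
  Y <- Y[cc, , drop = FALSE]; X <- X[cc, , drop = FALSE]
  n <- nrow(Y)
  if (n < ncol(X) + 2) stop("too few complete rows")
  Ys <- scale(Y); Xs <- scale(X)
  if (any(!is.finite(Ys)) || any(!is.finite(Xs)))
    stop("constant column in Y or X")
  qrx <- qr(Xs)
  dropped <- character(0)
  if (qrx$rank < ncol(Xs)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(Xs)[-keep]
    message("dropping collinear explanatory columns: ",
            paste(dropped, collapse = ", "))
    Xs <- Xs[, keep, drop = FALSE]
    qrx <- qr(Xs)
  }
  Yhat <- qr.fitted(qrx, Ys)
  sv <- svd(Yhat)
  pos <- sv$d > 1e-10 * max(sv$d, 1e-300)
  d <- sv$d[pos]; U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  eig <- d^2 / (n - 1)
  total_var <- sum(apply(Ys, 2, var))
  site <- U * sqrt(n - 1)                    # unit-variance site scores
  loadings <- V %*% diag(d / sqrt(n - 1), length(d))
  arrows <- cor(Xs, site)
  ax <- paste0("RDA", seq_along(d))
  colnames(site) <- colnames(loadings) <- colnames(arrows) <- ax
  rownames(loadings) <- colnames(Ys)
  rownames(arrows) <- colnames(Xs)
  structure(list(site_scores = site, response_loadings = loadings,
                 arrows = arrows, eig = eig,
                 proportion_explained = eig / total_var,
                 total_constrained = sum(eig), total_variance = total_var,
                 dropped = dropped),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("RDA:", length(x$eig), "constrained axes;",
      sprintf("%.1f%% of response variance constrained\n",
              100 * x$total_constrained / x$total_variance))
  print(round(rbind(eig = x$eig, prop = x$proportion_explained), 4))
  invisible(x)
}
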