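# Drought and plant-water-stress indicators: the ET/PET moisture coefficient,
# a standardized precipitation-evapotranspiration index (SPEI) built on a
# three-parameter log-logistic fit by unbiased probability-weighted moments,
# and the annual high/low classification of drought-related parameters.

#' Moisture coefficient (ET/PET) with weekly stress flag
#'
#' The ratio of actual to potential evapotranspiration. Weeks with a value
#' strictly below 0.6 are flagged as plant-water stressed.
#'
#' @param et Actual evapotranspiration, kg H2O m-2 day-1.
#' @param pet Potential evapotranspiration, mm day-1 (must be positive; weeks
#'   with non-positive PET are returned NA and flagged undefined).
#' @param stress_threshold Weekly stress cut-off on the ratio (default 0.6,
#'   strict inequality).
#' @return data.frame with columns `ratio` and logical `stressed`
#'   (`NA` where PET is non-positive or missing).
#' @export
moisture_coefficient <- function(et, pet, stress_threshold = 0.6) {
  bad <- !is.finite(pet) | pet <= 0 | !is.finite(et)
  ratio <- ifelse(bad, NA_real_, et / pet)
  data.frame(ratio = ratio,
             stressed = ifelse(bad, NA, ratio < stress_threshold))
}

# Unbiased probability-weighted moments w0, w1, w2 of a sample, in the
# convention the log-logistic parameter formulas expect:
# w_s estimates E[X (1 - F(X))^s].
.pwm <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  w0 <- mean(x)
  w1 <- sum((n - j) / (n - 1) * x) / n
  w2 <- sum((n - j) * (n - j - 1) / ((n - 1) * (n - 2)) * x) / n
  c(w0 = w0, w1 = w1, w2 = w2)
}

#' Fit a three-parameter log-logistic distribution by L-moment matching
#'
#' Parameters of the log-logistic CDF
#' \eqn{F(x) = [1 + (\alpha/(x-\gamma))^\beta]^{-1}} from unbiased
#' probability-weighted moments:
#' \eqn{\beta = (2w_1-w_0)/(6w_1-w_0-6w_2)},
#' \eqn{\alpha = (w_0-2w_1)\beta / (\Gamma(1+1/\beta)\Gamma(1-1/\beta))},
#' \eqn{\gamma = w_0 - \alpha\Gamma(1+1/\beta)\Gamma(1-1/\beta)},
#' with \eqn{w_s} the unbiased estimator of \eqn{E[X(1-F(X))^s]}.
#' The location parameter absorbs constant shifts of the data exactly, which
#' makes the resulting index invariant to re-basing the water balance.
#'
#' @param x Numeric sample (e.g. rolling climatic water balance sums).
#' @return list(alpha, beta, gamma).
#' @keywords internal
fit_loglogistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("need at least 4 finite values to fit")
  if (sd(x) == 0) stop("degenerate (constant) series: log-logistic fit failed")
  w <- .pwm(x)
  beta <- (2 * w["w1"] - w["w0"]) / (6 * w["w1"] - w["w0"] - 6 * w["w2"])
  if (!is.finite(beta) || beta <= 1)
    stop("log-logistic shape parameter out of range (beta <= 1); ",
         "series unsuitable for SPEI standardization")
  g1 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w["w0"] - 2 * w["w1"]) * beta / g1
  gam <- w["w0"] - alpha * g1
  out <- list(alpha = unname(alpha), beta = unname(beta),
              gamma = unname(gam))
  # the log-logistic is right-skewed; a fit with non-positive scale (or an
  # origin above the data) means the sample skew is on the wrong side
  if (out$alpha <= 0 || any(x <= out$gamma))
    stop("log-logistic fit invalid for this skew direction")
  out
}

#' Standardized precipitation-evapotranspiration index
#'
#' Rolling `scale`-week sums of the climatic water balance (P - PET) are fit
#' with a three-parameter log-logistic distribution (unbiased
#' probability-weighted moments) and mapped through the standard normal
#' quantile function. Probabilities are clamped to [1e-6, 1 - 1e-6] before
#' the normal quantile so values left of the fitted origin stay finite.
#'
#' Classical monthly SPEI fits one distribution per calendar month so that
#' each sample is climatologically homogeneous. With weekly data over few
#' years there are too few observations per calendar week, so instead the
#' weekly climatology of the rolling sums (mean per week-of-year) is removed
#' and the pooled anomalies are fit; a raw pooled fit of strongly seasonal
#' sums is bimodal and falls outside the log-logistic family. Left-skewed
#' samples are handled by fitting the reflected series and back-transforming
#' the probabilities.
#'
#' @param water_balance Weekly climatic water balance P - PET, mm week-1.
#' @param scale Accumulation window in weeks (default 12, about 3 months).
#' @param deseasonalize Remove the week-of-year climatology of the rolling
#'   sums before fitting (default TRUE; disable for non-seasonal input).
#' @param period Weeks per year for the climatology (default 52).
#' @return Numeric vector aligned with the input; the first `scale - 1`
#'   entries are NA (incomplete window). Attribute `reflected` records
#'   whether the mirrored fit was needed.
#' @examples
#' set.seed(1)
#' z <- spei(rnorm(500, 0, 10), scale = 12, deseasonalize = FALSE)
#' mean(z, na.rm = TRUE)  # ~0
#' @export
spei <- function(water_balance, scale = 12, deseasonalize = TRUE,
                 period = 52) {
  if (scale < 1) stop("scale must be >= 1")
  n <- length(water_balance)
  if (n < 2 * scale) stop("series shorter than twice the accumulation scale")
  acc <- rolling_sum(water_balance, scale)
  if (deseasonalize) {
    bin <- ((seq_len(n) - 1L) %% period) + 1L
    clim <- tapply(acc, bin, mean, na.rm = TRUE)
    acc <- acc - as.numeric(clim[as.character(bin)])
  }
  x <- acc[is.finite(acc)]
  reflected <- FALSE
  par <- tryCatch(fit_loglogistic(x), error = function(e) NULL)
  if (is.null(par)) {
    # left-skewed balance (common for pooled strongly seasonal sums): fit
    # the reflected sample, which has the skew the family requires, and
    # back-transform the probabilities
    par <- fit_loglogistic(-x)
    reflected <- TRUE
  }
  ll_cdf <- function(v) {
    p <- 1 / (1 + (par$alpha / (v - par$gamma))^par$beta)
    p[v <= par$gamma] <- 0
    p
  }
  p <- if (reflected) 1 - ll_cdf(-acc) else ll_cdf(acc)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  z <- qnorm(p)
  z[!is.finite(acc)] <- NA_real_
  attr(z, "reflected") <- reflected
  z
}

#' Right-aligned rolling sum
#' @param x Numeric vector.
#' @param k Window length.
#' @return Vector of length `length(x)`; first `k - 1` values NA.
#' @keywords internal
rolling_sum <- function(x, k) {
  n <- length(x)
  if (k > n) stop("window longer than series")
  cs <- cumsum(ifelse(is.na(x), 0, x))
  out <- c(rep(NA_real_, k - 1), cs[k:n] - c(0, cs[seq_len(n - k)]))
  # windows containing NA are NA
  nacnt <- cumsum(is.na(x))
  bad <- c(rep(TRUE, k - 1), (nacnt[k:n] - c(0, nacnt[seq_len(n - k)])) > 0)
  out[bad] <- NA_real_
  out
}

#' Classify years into high/low drought-parameter categories
#'
#' Applies the fixed annual classification thresholds: plant-water stress is
#' high when the moisture coefficient is below 0.4 (strict), drought is
#' severe when SPEI is at or below -1.5, surface conductance is high at or
#' above 0.2 m s-1, ET is high at or above 3 kg H2O m-2 day-1, SWC decline is
#' high when SWC falls below 82.5 % (strict), and the evaporative fraction is
#' high above 0.5 (strict).
#'
#' @param summaries data.frame with one row per year and columns `year`,
#'   `moisture_coef`, `spei`, `gsw`, `et`, `swc`, `ef` (annual summaries:
#'   growing-season means for moisture_coef/gsw/et/ef, growing-season minima
#'   for spei/swc; see [annual_summary()]).
#' @param thresholds Named list of the six cut-offs; defaults are the
#'   standard set.
#' @return data.frame: `year` plus logical columns `stress_high`,
#'   `drought_severe`, `gsw_high`, `et_high`, `swc_decline_high`, `ef_high`.
#' @export
classify_years <- function(summaries,
                           thresholds = list(moisture = 0.4, spei = -1.5,
                                             gsw = 0.2, et = 3,
                                             swc = 82.5, ef = 0.5)) {
  need <- c("year", "moisture_coef", "spei", "gsw", "et", "swc", "ef")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing summary fields: ",
                         paste(miss, collapse = ", "))
  data.frame(
    year = summaries$year,
    stress_high      = summaries$moisture_coef < thresholds$moisture,
    drought_severe   = summaries$spei <= thresholds$spei,
    gsw_high         = summaries$gsw >= thresholds$gsw,
    et_high          = summaries$et >= thresholds$et,
    swc_decline_high = summaries$swc < thresholds$swc,
    ef_high          = summaries$ef > thresholds$ef
  )
}

#' Annual summaries for the high/low classification
#'
#' Growing-season (April-September; week bins 14-39 of the 52-bin year)
#' means of the moisture coefficient, Gsw, ET and EF, and growing-season
#' minima of SWC and SPEI. The classification reflects summer behaviour, so
#' winter weeks are excluded.
#'
#' @param df Weekly table with columns `YEAR`, `WEEK`, `ET`, `PET`, `GSW`,
#'   `EF`, `SWC` and `SPEI` (see [derive_micromet()] and [spei()]).
#' @param gs_weeks Integer vector of growing-season week bins.
#' @return data.frame with columns `year`, `moisture_coef`, `spei`, `gsw`,
#'   `et`, `swc`, `ef`, ready for [classify_years()].
#' @export
annual_summary <- function(df, gs_weeks = 14:39) {
  need <- c("YEAR", "WEEK", "ET", "PET", "GSW", "EF", "SWC", "SPEI")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  gs <- df[df$WEEK %in% gs_weeks, , drop = FALSE]
  mc <- moisture_coefficient(gs$ET, gs$PET)$ratio
  agg <- function(x, f) tapply(x, gs$YEAR, f, simplify = TRUE)
  mn <- function(x) mean(x, na.rm = TRUE)
  mnm <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  out <- data.frame(
    year          = as.integer(names(agg(gs$ET, mn))),
    moisture_coef = as.numeric(tapply(mc, gs$YEAR, mn)),
    spei          = as.numeric(agg(gs$SPEI, mnm)),
    gsw           = as.numeric(agg(gs$GSW, mn)),
    et            = as.numeric(agg(gs$ET, mn)),
    swc           = as.numeric(agg(gs$SWC, mnm)),
    ef            = as.numeric(agg(gs$EF, mn))
  )
  rownames(out) <- NULL
  out
}
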