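# Synthetic data with known causal structure: (1) a pair of coupled logistic
# maps as a minimal fixture for cross-mapping, and (2) a weekly "synthetic
# bog" generator whose mechanisms mirror the processes the analysis is meant
# to detect — VPD-driven stomatal down-regulation of conductance and
# photosynthesis, a soil-water bucket whose decline lags evapotranspiration
# by a configurable number of weeks, and a soil-moisture limitation of GPP
# that switches on only below a configurable threshold. The generator exposes
# its implanted couplings and thresholds so inferred structure can be
# compared against ground truth.

#' Configuration for the coupled logistic-map fixture
#'
#' The two-species logistic system
#' \deqn{x_{t+1} = x_t (r_x - r_x x_t - \beta_{xy} y_t)}
#' \deqn{y_{t+1} = y_t (r_y - r_y y_t - \beta_{yx} x_t)}
#' where `beta_xy` is the effect of y on x and `beta_yx` the effect of x
#' on y.
#'
#' @param r_x,r_y Growth rates.
#' @param beta_xy Effect of y on x (coupling into the x equation).
#' @param beta_yx Effect of x on y.
#' @param n_steps Total iterations (including burn-in).
#' @param burn_in Initial steps to discard (`n_steps > burn_in >= 0`).
#' @param seed Integer seed (initial conditions).
#' @return list of class `coupled_map_config`.
#' @export
coupled_map_config <- function(r_x = 3.8, r_y = 3.5, beta_xy = 0.02,
                               beta_yx = 0.1, n_steps = 1000, burn_in = 100,
                               seed = 1) {
  stopifnot(n_steps > burn_in, burn_in >= 0, r_x > 0, r_y > 0)
  structure(list(r_x = r_x, r_y = r_y, beta_xy = beta_xy, beta_yx = beta_yx,
                 n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "coupled_map_config")
}

#' Generate a coupled logistic-map pair
#'
#' Deterministic given the seed (which sets the initial conditions only).
#' Trajectories leaving (0, 1) indicate inadmissible parameters and raise an
#' error rather than returning clipped values.
#'
#' @param config A [coupled_map_config()].
#' @return data.frame with columns `x` and `y`,
#'   `n_steps - burn_in` rows.
#' @export
gen_coupled_logistic <- function(config) {
  stopifnot(inherits(config, "coupled_map_config"))
  set.seed(config$seed)
  x <- numeric(config$n_steps); y <- numeric(config$n_steps)
  x[1] <- runif(1, 0.2, 0.8); y[1] <- runif(1, 0.2, 0.8)
  for (t in seq_len(config$n_steps - 1)) {
    x[t + 1] <- x[t] * (config$r_x - config$r_x * x[t] -
                          config$beta_xy * y[t])
    y[t + 1] <- y[t] * (config$r_y - config$r_y * y[t] -
                          config$beta_yx * x[t])
    if (!is.finite(x[t + 1]) || !is.finite(y[t + 1]) ||
        x[t + 1] <= 0 || x[t + 1] >= 1 || y[t + 1] <= 0 || y[t + 1] >= 1)
      stop("trajectory left (0,1): inadmissible coupled-map parameters")
  }
  keep <- seq.int(config$burn_in + 1, config$n_steps)
  data.frame(x = x[keep], y = y[keep])
}

#' Configuration for the synthetic bog generator
#'
#' Defaults state the simulated world: five years of 52 exact seven-day
#' weeks; a soil-moisture limitation of photosynthesis that switches on below
#' 82.5 % volumetric SWC (equivalently a water table 8 cm below the surface);
#' a soil-water store whose decline responds to evapotranspiration with a
#' 14-week delay; and two drought years (the first and last) with amplified
#' atmospheric demand and reduced summer precipitation.
#'
#' @param n_years Simulated years (>= 1; default 5).
#' @param seed Integer seed; all noise and initial states derive from it.
#' @param swc_threshold Volumetric SWC (%) below which GPP and conductance
#'   become water-limited (default 82.5).
#' @param wtd_threshold Water table depth (cm, negative below surface) paired
#'   with `swc_threshold` through the fixed affine SWC-WTD map (default -8).
#' @param et_swc_lag Delay (weeks) with which ET withdraws water from the
#'   monitored soil layer (default 14): the hydraulic memory of the peat.
#' @param drought_years Indices (1-based within the simulated span) of years
#'   with amplified VPD and suppressed summer rain (default `c(1, 5)`).
#' @param stomatal_sensitivity Exponential down-regulation slope of surface
#'   conductance and photosynthesis per kPa of VPD (default 0.5).
#' @param bucket_capacity Soil-water store capacity, mm (default 900).
#' @param drainage_rate Weekly relaxation rate of the store toward its
#'   recharge level (default 0.03 week^-1; models lateral/water-table
#'   exchange in both directions).
#' @param swc_sensitivity Fractional GPP/conductance loss per percentage
#'   point of SWC below the threshold (default 0.10).
#' @param wtd_slope cm of WTD per % SWC in the affine SWC-WTD map
#'   (default 0.8).
#' @param et_draw Fraction of ET drawn (with delay) from the monitored layer
#'   (default 0.48; the remainder is supplied by the water table with a
#'   delay).
#' @param infil_max Total recharge capacity of the monitored layer, mm per
#'   week (default 6.5): 45 percent arrives as steady capillary baseflow
#'   from the water table and the rest as infiltration-limited rain; excess
#'   rain runs off the saturated peat surface.
#' @param dry_season_center Week bin at the middle of the precipitation
#'   trough (default 45, early November: the dry season in this world runs
#'   from high summer deep into autumn, so the lagged evapotranspiration
#'   drawdown completes before the rains return).
#' @param noise_sd Named list of additive noise standard deviations per
#'   channel; any subset may be overridden, and `noise_scale` multiplies all
#'   of them (0 = noise-free).
#' @param noise_scale Global multiplier on all noise SDs (default 1).
#' @param couple_gpp If FALSE, GPP is replaced by pure seeded noise around
#'   its mean — a null world for causal-detection tests (default TRUE).
#' @param start_year First calendar year label (default 2016).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_years = 5, seed = 42, swc_threshold = 82.5,
                       wtd_threshold = -8, et_swc_lag = 14,
                       drought_years = c(1, 5),
                       stomatal_sensitivity = 0.5,
                       bucket_capacity = 900, drainage_rate = 0.03,
                       swc_sensitivity = 0.10, wtd_slope = 0.8,
                       et_draw = 0.48, infil_max = 6.5,
                       dry_season_center = 45,
                       noise_sd = list(), noise_scale = 1,
                       couple_gpp = TRUE, start_year = 2016) {
  if (n_years < 1) stop("n_years must be >= 1")
  if (swc_threshold <= 0 || swc_threshold >= 100)
    stop("swc_threshold must be inside (0, 100)")
  if (et_swc_lag < 0) stop("et_swc_lag must be >= 0")
  if (bucket_capacity <= 0 || drainage_rate < 0 || drainage_rate > 1)
    stop("bucket parameters out of range")
  base_sd <- list(TA = 0.6, SW_IN = 10, VPD = 0.05, P = 3, WS = 0.2,
                  USTAR = 0.02, CO2 = 1.2, GPP = 0.12, RECO = 0.08,
                  SWC = 0.25, WTD = 0.3)
  unknown <- setdiff(names(noise_sd), names(base_sd))
  if (length(unknown)) stop("unknown noise channels: ",
                            paste(unknown, collapse = ", "))
  base_sd[names(noise_sd)] <- noise_sd
  if (any(unlist(base_sd) < 0) || noise_scale < 0)
    stop("noise SDs must be >= 0")
  structure(list(n_years = as.integer(n_years), seed = as.integer(seed),
                 swc_threshold = swc_threshold,
                 wtd_threshold = wtd_threshold,
                 et_swc_lag = as.integer(et_swc_lag),
                 drought_years = as.integer(drought_years),
                 stomatal_sensitivity = stomatal_sensitivity,
                 bucket_capacity = bucket_capacity,
                 drainage_rate = drainage_rate,
                 swc_sensitivity = swc_sensitivity,
                 wtd_slope = wtd_slope, et_draw = et_draw,
                 infil_max = infil_max,
                 dry_season_center = dry_season_center,
                 noise_sd = lapply(base_sd, function(s) s * noise_scale),
                 couple_gpp = isTRUE(couple_gpp),
                 start_year = as.integer(start_year)),
            class = "sim_config")
}

#' Generate a synthetic weekly bog record
#'
#' Simulates `n_years` of 52 exact seven-day weeks (plus an internal spin-up
#' year that is discarded) of coupled meteorology, energy, water and carbon:
#'
#' * seasonal air temperature, shortwave radiation, VPD, precipitation, wind
#'   and friction velocity, with drought years amplifying summer VPD and
#'   cutting summer rain;
#' * surface conductance `Gsw = gmax * season * exp(-sens * VPD) * f(SWC)`,
#'   where `f(SWC)` is 1 at or above `swc_threshold` and declines linearly
#'   below it;
#' * latent heat from the forward Penman-Monteith model with available
#'   energy A = 0.65 SW_IN; H = A - LE; ET from LE;
#' * a soil-water bucket `S_t = S_{t-1} + P_t - a 7 ET_{t-L} -
#'   d (S_{t-1} - S_ref)` clipped to `[0, capacity]`, with L =
#'   `et_swc_lag`, so the monitored SWC declines with a pure L-week delay
#'   after ET; SWC = 100 S / capacity;
#' * WTD as the fixed affine image of SWC calibrated so that
#'   SWC = `swc_threshold` maps exactly to WTD = `wtd_threshold`;
#' * GPP = light-use term x VPD down-regulation x SWC limitation;
#'   Reco as a Q10 function of temperature; NEE = Reco - GPP;
#' * additive seeded observation noise on every output channel.
#'
#' @param config A [sim_config()].
#' @return data.frame with AmeriFlux-style columns (`week_start`, `YEAR`,
#'   `WEEK`, `TA`, `SW_IN`, `RN`, `VPD`, `WS`, `USTAR`, `H`, `LE`, `P`,
#'   `GPP`, `RECO`, `NEE`, `SWC`, `WTD`, `CO2`, `ET`), 52 rows per year, and
#'   attribute `truth`: a list with the implanted coupling map, thresholds,
#'   lag and SWC-WTD map.
#' @export
gen_bog_weekly <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spin <- max(1L, as.integer(ceiling(config$et_swc_lag / 52)))
  ny <- config$n_years + spin
  nw <- 52L * ny
  bin <- rep(1:52, ny)
  yr_idx <- rep(seq_len(ny), each = 52) - spin   # output years are 1..n_years
  seas <- cos(2 * pi * (bin - 28.5) / 52)
  drought <- yr_idx %in% config$drought_years
  sdl <- config$noise_sd
  set.seed(config$seed)
  eps <- lapply(sdl, function(s) rnorm(nw, 0, s))

  # precipitation phase lags radiation: the dry season runs from high summer
  # well into autumn, and drought anomalies ride on the dry season
  seas_p <- cos(2 * pi * (bin - config$dry_season_center) / 52)
  ta <- 10 + 8 * seas + eps$TA
  sw <- pmax(160 + 140 * seas + eps$SW_IN, 15)
  sw[drought & seas > 0] <- sw[drought & seas > 0] * 1.25  # clear skies
  # VPD peaks in late July-August, lagging the radiation peak
  seas_v <- cos(2 * pi * (bin - 32) / 52)
  vpd <- 0.15 + 0.65 * pmax(seas_v, 0)^1.3
  vpd[drought & seas > 0] <- vpd[drought & seas > 0] * 2.0
  vpd <- pmax(vpd + eps$VPD, 0.02)
  p <- pmax(26 - 30 * seas_p + eps$P, 0)
  p[drought & seas_p > 0] <- p[drought & seas_p > 0] * 0.5
  ws <- pmax(2.5 - 0.4 * seas + eps$WS, 0.5)
  ustar <- pmax(0.12 * ws + eps$USTAR, 0.05)
  co2 <- numeric(nw)
  co2[1] <- 415
  for (t in 2:nw) co2[t] <- 415 + 0.7 * (co2[t - 1] - 415) + eps$CO2[t]
  co2 <- co2 + 2 * (-seas)

  st <- psychro_state(ta, e_act = pmax(
    0.6108 * exp(17.27 * ta / (ta + 237.3)) - vpd, 0))
  aero <- aerodynamic_conductance(ws, ustar)
  a_energy <- 0.65 * sw                       # available energy, W m-2
  g_seas <- 0.15 + 0.85 * pmax(seas, 0)
  f_vpd <- exp(-config$stomatal_sensitivity * vpd)

  L <- config$et_swc_lag
  cap <- config$bucket_capacity
  S <- numeric(nw); et <- numeric(nw); le <- numeric(nw)
  gsw <- numeric(nw); f_swc <- numeric(nw)
  S_prev <- cap
  for (t in seq_len(nw)) {
    # first L spin-up weeks have no ET history; use a climatological rate
    # (those weeks are discarded with the spin-up year anyway)
    et_lag <- if (t - L >= 1) et[t - L] else 0.8
    # recharge of the monitored layer is infiltration-limited (excess rain
    # runs off the saturated peat), and a slow drainage leak operates only
    # near saturation
    # recharge = steady capillary baseflow from the water table plus
    # infiltration-limited rain; droughts draw the water table down and cut
    # both (dry-season weeks only)
    cut <- if (drought[t] && seas_p[t] > 0) 0.25 else 1
    inflow <- cut * (0.45 * config$infil_max +
                       min(p[t], 0.55 * config$infil_max))
    leak <- config$drainage_rate * max(S_prev - 0.9 * cap, 0)
    S[t] <- S_prev + inflow - config$et_draw * 7 * et_lag - leak
    S[t] <- min(max(S[t], 0), cap)
    swc_t <- 100 * S[t] / cap
    f_swc[t] <- if (swc_t >= config$swc_threshold) 1 else
      max(0.05, 1 - config$swc_sensitivity * (config$swc_threshold - swc_t))
    gsw[t] <- 0.009 * g_seas[t] * f_vpd[t] * f_swc[t]
    le_t <- penman_monteith_le(a_energy[t], vpd[t], aero$Gah[t], gsw[t],
                               .state_at(st, t))
    le[t] <- min(max(le_t, 0), a_energy[t])
    et[t] <- le_to_et(le[t], st$lambda[t])
    S_prev <- S[t]
  }
  swc_true <- 100 * S / cap
  h <- a_energy - le
  wtd_true <- config$wtd_threshold +
    config$wtd_slope * (swc_true - config$swc_threshold)

  # saturating canopy light response; light rise and VPD down-regulation
  # largely offset across the growing season, as in evergreen moss canopies
  gpp_true <- 4.6 * (1 - exp(-sw / 80)) * f_vpd * f_swc
  if (!config$couple_gpp) gpp_true <- rep(mean(gpp_true), nw)
  gpp <- pmax(gpp_true + eps$GPP, 0)
  reco <- pmax(1.6 * 2.2^((ta - 10) / 10) + eps$RECO, 0)

  keep <- yr_idx >= 1
  year <- config$start_year + yr_idx - 1L
  out <- data.frame(
    week_start = as.Date(paste0(year, "-01-01")) + (bin - 1L) * 7L,
    YEAR = year, WEEK = bin,
    TA = ta, SW_IN = sw, RN = a_energy, VPD = vpd, WS = ws, USTAR = ustar,
    H = h, LE = le, P = p, GPP = gpp, RECO = reco, NEE = reco - gpp,
    SWC = pmin(pmax(swc_true + eps$SWC, 0), 100),
    WTD = wtd_true + eps$WTD, CO2 = co2, ET = et
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    coupling = list(GPP = c("SW_IN", "VPD", "SWC"),
                    ET = c("SW_IN", "VPD", "TA", "SWC"),
                    RECO = "TA",
                    SWC = c("ET", "P")),
    swc_threshold = config$swc_threshold,
    wtd_threshold = config$wtd_threshold,
    et_swc_lag = config$et_swc_lag,
    wtd_map = c(intercept = config$wtd_threshold -
                  config$wtd_slope * config$swc_threshold,
                slope = config$wtd_slope),
    couple_gpp = config$couple_gpp)
  out
}

# Single-week view into a vectorised psychro_state.
.state_at <- function(st, i) {
  out <- lapply(st, function(v) if (length(v) > 1) v[i] else v)
  class(out) <- "psychro_state"
  out
}
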