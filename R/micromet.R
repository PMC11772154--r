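# Micrometeorological derivations from weekly flux-tower records:
# psychrometrics, Penman potential evapotranspiration, aerodynamic and
# surface conductances (big-leaf Penman-Monteith inversion), and the
# evaporative fraction.

#' Psychrometric state of the air
#'
#' Computes the scalar psychrometric quantities needed by the Penman and
#' Penman-Monteith equations at a given air temperature and humidity.
#' Saturation vapour pressure uses the Magnus formula
#' \eqn{e_s = 0.6108 \exp(17.27 T / (T + 237.3))} (kPa), the latent heat of
#' vaporisation the linear approximation
#' \eqn{\lambda = 2.501 - 0.002361\,T} (MJ kg\eqn{^{-1}}), and the
#' psychrometric constant \eqn{\gamma = c_p p / (0.622 \lambda)}.
#'
#' @param tair Air temperature, degrees C. Vectorised.
#' @param rh Relative humidity in percent (0-100), or `NULL` if `e_act`
#'   is given directly.
#' @param e_act Actual vapour pressure, kPa. Overrides `rh` when supplied.
#' @param pressure Air pressure, kPa. Defaults to sea level (101.325 kPa).
#'
#' @return A list of class `psychro_state` with elements `s` (slope of the
#'   saturation vapour pressure curve, kPa per degree C), `gamma` (kPa per
#'   degree C), `lambda` (MJ per kg), `e_sat`, `e_act`, `vpd` (all kPa),
#'   `rho_air` (kg m-3), `cp` (J kg-1 K-1) and `pressure` (kPa). All vector
#'   elements recycle to the length of `tair`.
#' @examples
#' st <- psychro_state(20, rh = 60)
#' st$e_sat  # about 2.34 kPa
#' @export
psychro_state <- function(tair, rh = NULL, e_act = NULL,
                          pressure = .const$P0_KPA) {
  if (any(pressure <= 0)) stop("pressure must be positive (kPa)")
  if (any(tair < -40 | tair > 60, na.rm = TRUE))
    stop("tair outside plausible range [-40, 60] degC")
  e_sat <- 0.6108 * exp(17.27 * tair / (tair + 237.3))
  if (is.null(e_act)) {
    if (is.null(rh)) stop("supply either rh (%) or e_act (kPa)")
    if (any(rh < 0 | rh > 100, na.rm = TRUE)) stop("rh must be in [0, 100]")
    e_act <- e_sat * rh / 100
  }
  if (any(e_act > e_sat + 1e-9, na.rm = TRUE))
    stop("e_act exceeds e_sat; inconsistent humidity input")
  lambda <- 2.501 - 0.002361 * tair               # MJ kg-1
  s      <- 4098 * e_sat / (tair + 237.3)^2       # kPa degC-1
  gamma  <- (.const$CP_J * 1e-6) * pressure / (.const$EPS_MW * lambda)
  tk     <- tair + 273.15
  # moist air density: dry-air law with vapour-pressure correction
  rho_air <- 1000 * pressure / (.const$RD * tk) *
    (1 - 0.378 * e_act / pressure)
  out <- list(s = s, gamma = gamma, lambda = lambda, e_sat = e_sat,
              e_act = e_act, vpd = pmax(e_sat - e_act, 0),
              rho_air = rho_air, cp = .const$CP_J, pressure = pressure)
  class(out) <- "psychro_state"
  out
}

#' Penman aerodynamic wind function
#'
#' The empirical linear wind function used in the aerodynamic term of the
#' Penman potential-evapotranspiration equation:
#' \eqn{f(u) = 2.626 + 1.381 u}.
#'
#' @param u Wind speed at reference height, m s-1 (non-negative).
#' @return Dimensionless wind-function value(s).
#' @examples
#' wind_function(0)  # 2.626
#' @export
wind_function <- function(u) {
  if (any(u < 0, na.rm = TRUE)) stop("wind speed must be non-negative")
  2.626 + 1.381 * u
}

#' Penman potential evapotranspiration
#'
#' Daily-rate potential evapotranspiration from a saturated surface, combining
#' a radiative term with an aerodynamic term:
#' \deqn{PET = \frac{s}{s+\gamma}\frac{R_n}{\lambda} +
#'       \frac{\gamma}{s+\gamma} E_a, \qquad E_a = f(u)\,D}
#' with \eqn{R_n} in MJ m-2 day-1, \eqn{D} the vapour pressure deficit in kPa
#' and \eqn{E_a} in mm day-1.
#'
#' @param rn_daily Net radiation, MJ m-2 day-1.
#' @param vpd Vapour pressure deficit D, kPa.
#' @param u Wind speed, m s-1.
#' @param state A [psychro_state()] evaluated at the record's air temperature.
#' @return PET in mm day-1 (NA where `rn_daily` or `vpd` is missing; missing
#'   inputs are propagated, never silently zeroed).
#' @export
penman_pet <- function(rn_daily, vpd, u, state) {
  stopifnot(inherits(state, "psychro_state"))
  if (any(vpd < 0, na.rm = TRUE)) stop("vpd must be non-negative")
  ea <- wind_function(u) * vpd                      # mm day-1
  w  <- state$s / (state$s + state$gamma)
  w * rn_daily / state$lambda + (1 - w) * ea
}

#' Aerodynamic conductances from wind speed and friction velocity
#'
#' Bulk aerodynamic conductance for heat as two resistances in series:
#' momentum conductance \eqn{G_{am} = u_*^2 / u}, quasi-laminar boundary-layer
#' conductance \eqn{G_{bh} = (6.2\,u_*^{-0.67})^{-1}}, and
#' \eqn{G_{ah} = (1/G_{am} + 1/G_{bh})^{-1}}.
#'
#' @param u Wind speed, m s-1 (strictly positive).
#' @param u_star Friction velocity, m s-1 (strictly positive).
#' @return A data.frame with columns `Gam`, `Gbh`, `Gah`, `Ram`, `Rbh`
#'   (conductances in m s-1, resistances in s m-1). Weeks with `u` or
#'   `u_star` zero/missing get NA in every column rather than an error when
#'   vectorised over a table.
#' @export
aerodynamic_conductance <- function(u, u_star) {
  n <- max(length(u), length(u_star))
  u <- rep_len(u, n); u_star <- rep_len(u_star, n)
  bad <- !is.finite(u) | !is.finite(u_star) | u <= 0 | u_star <= 0
  if (all(bad)) stop("u and u_star must be positive for at least one record")
  gam <- ifelse(bad, NA_real_, u_star^2 / u)
  gbh <- ifelse(bad, NA_real_, 1 / (6.2 * u_star^(-0.67)))
  gah <- 1 / (1 / gam + 1 / gbh)
  data.frame(Gam = gam, Gbh = gbh, Gah = gah, Ram = 1 / gam, Rbh = 1 / gbh)
}

#' Bulk surface conductance by Penman-Monteith inversion
#'
#' Inverts the big-leaf Penman-Monteith equation for the bulk surface
#' conductance to water vapour, approximating available energy as
#' \eqn{A = H + \lambda E}:
#' \deqn{G_{sw} = \frac{\gamma \lambda E \, G_{ah}}
#'   {s(H+\lambda E) + \rho c_p G_{ah} D - \lambda E (s+\gamma)}}
#' Weeks where the denominator is non-positive (physically inconsistent:
#' condensation or strongly advective conditions) or where the result is
#' negative are returned as NA and flagged, never clipped to zero, because
#' truncation would distort downstream state-space embeddings.
#'
#' @param le Latent heat flux, W m-2.
#' @param h Sensible heat flux, W m-2.
#' @param vpd Vapour pressure deficit, kPa.
#' @param gah Bulk aerodynamic conductance for heat, m s-1.
#' @param state A [psychro_state()].
#' @return Numeric vector of Gsw (m s-1) with attribute `flagged`, a logical
#'   vector marking invalid weeks.
#' @export
surface_conductance <- function(le, h, vpd = NULL, gah, state) {
  stopifnot(inherits(state, "psychro_state"))
  d <- .vpd_or(state, vpd)
  num <- state$gamma * le * gah
  den <- state$s * h + state$rho_air * state$cp * gah * d -
    state$gamma * le
  gsw <- num / den
  flag <- !is.finite(gsw) | den <= 0 | gsw < 0
  gsw[flag] <- NA_real_
  # le == 0 is a valid zero-flux week, not an inconsistency
  zero <- !is.na(le) & le == 0 & is.finite(den) & den > 0
  gsw[zero] <- 0
  flag[zero] <- FALSE
  attr(gsw, "flagged") <- flag
  gsw
}

# D may come from the state (derived from rh) or be measured directly;
# measured VPD wins when supplied.
.vpd_or <- function(state, vpd) if (is.null(vpd)) state$vpd else vpd

#' Forward big-leaf Penman-Monteith latent heat flux
#'
#' The forward model matching [surface_conductance()]:
#' \deqn{\lambda E = \frac{s A + \rho c_p G_{ah} D}
#'   {s + \gamma (1 + G_{ah}/G_{sw})}}
#' with available energy \eqn{A} in W m-2. Used by the synthetic generator
#' and as the round-trip oracle for the inversion.
#'
#' @param a_energy Available energy A, W m-2.
#' @param vpd Vapour pressure deficit, kPa.
#' @param gah Aerodynamic conductance, m s-1.
#' @param gsw Surface conductance, m s-1.
#' @param state A [psychro_state()].
#' @return Latent heat flux, W m-2.
#' @export
penman_monteith_le <- function(a_energy, vpd, gah, gsw, state) {
  stopifnot(inherits(state, "psychro_state"))
  (state$s * a_energy + state$rho_air * state$cp * gah * vpd) /
    (state$s + state$gamma * (1 + gah / gsw))
}

#' Evaporative fraction
#'
#' \eqn{EF = \lambda E / (\lambda E + H)}: the share of turbulent energy used
#' for evaporation. Undefined (NA, flagged) where \eqn{\lambda E + H = 0}.
#'
#' @param le Latent heat flux, W m-2.
#' @param h Sensible heat flux, W m-2.
#' @return EF with attribute `flagged` for undefined records.
#' @export
evaporative_fraction <- function(le, h) {
  den <- le + h
  ef <- ifelse(den == 0, NA_real_, le / den)
  attr(ef, "flagged") <- !is.na(den) & den == 0
  ef
}

#' Convert latent heat flux to evapotranspiration
#'
#' @param le Latent heat flux, W m-2.
#' @param lambda Latent heat of vaporisation, MJ kg-1.
#' @return ET in kg H2O m-2 day-1 (numerically mm day-1).
#' @export
le_to_et <- function(le, lambda) {
  le * .const$W_TO_MJ_DAY / lambda
}

#' Derive micrometeorological columns for a weekly table
#'
#' Appends PET, Gam/Gbh/Gah, Gsw, EF, ET (if absent) and the psychrometric
#' VPD check to a weekly record table with AmeriFlux-style columns
#' (`TA`, `SW_IN`, `RN`, `VPD`, `WS`, `USTAR`, `H`, `LE`, ...). `RN` is taken
#' in W m-2 and converted internally to MJ m-2 day-1 for the Penman equation;
#' if an `RN` column is absent it is approximated as 0.65 * `SW_IN`.
#'
#' @param df Weekly record data.frame (see [gen_bog_weekly()] for the layout).
#' @param pressure Air pressure, kPa.
#' @return `df` with columns `PET` (mm day-1), `GAM`, `GBH`, `GAH`, `GSW`
#'   (m s-1), `EF`, `ET` (kg m-2 day-1) appended, plus logical `GSW_FLAG`.
#' @export
derive_micromet <- function(df, pressure = .const$P0_KPA) {
  need <- c("TA", "VPD", "WS", "USTAR", "H", "LE")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  rn_w <- if ("RN" %in% names(df)) df$RN else 0.65 * df$SW_IN
  st <- psychro_state(df$TA, e_act = pmax(
    0.6108 * exp(17.27 * df$TA / (df$TA + 237.3)) - df$VPD, 0),
    pressure = pressure)
  aero <- aerodynamic_conductance(df$WS, df$USTAR)
  gsw <- surface_conductance(df$LE, df$H, df$VPD, aero$Gah, st)
  df$PET <- penman_pet(rn_w * .const$W_TO_MJ_DAY, df$VPD, df$WS, st)
  df$GAM <- aero$Gam
  df$GBH <- aero$Gbh
  df$GAH <- aero$Gah
  df$GSW <- as.numeric(gsw)
  df$GSW_FLAG <- attr(gsw, "flagged")
  ef <- evaporative_fraction(df$LE, df$H)
  df$EF <- as.numeric(ef)
  if (!"ET" %in% names(df)) df$ET <- le_to_et(df$LE, st$lambda)
  df
}
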