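# Shared fixtures, built in code at test time.

# A small, fast synthetic world (3 years) for pipeline-level tests.
small_world <- function(seed = 11, ...) {
  gen_bog_weekly(sim_config(n_years = 3, seed = seed,
                            drought_years = c(1, 3), ...))
}

# Daily records covering whole calendar years, for aggregation bookkeeping.
daily_records <- function(years) {
  d <- seq(as.Date(paste0(min(years), "-01-01")),
           as.Date(paste0(max(years), "-12-31")), by = "day")
  data.frame(date = d, TA = 10 + sin(seq_along(d) / 58), P = 2)
}

# Independently coded one-line Penman evaluation (oracle for penman_pet).
penman_oracle <- function(tair, pressure, rn, u, d) {
  es <- 0.6108 * exp(17.27 * tair / (tair + 237.3))
  s <- 4098 * es / (tair + 237.3)^2
  lam <- 2.501 - 0.002361 * tair
  gam <- 0.001013 * pressure / (0.622 * lam)
  s / (s + gam) * rn / lam + gam / (s + gam) * (2.626 + 1.381 * u) * d
}
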