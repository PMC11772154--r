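test_that("psychrometric state matches the Magnus oracle and sanity bounds", {
  st <- psychro_state(20, rh = 60)
  expect_equal(st$e_sat, 0.6108 * exp(17.27 * 20 / 257.3), tolerance = 1e-12)
  expect_equal(st$e_sat, 2.34, tolerance = 0.01)
  # saturated air has zero vapour pressure deficit
  sat <- psychro_state(15, rh = 100)
  expect_equal(sat$vpd, 0)
  # latent heat of vaporisation decreases with temperature
  lams <- vapply(seq(0, 40, 5), function(t) psychro_state(t, rh = 50)$lambda,
                 numeric(1))
  expect_true(all(diff(lams) < 0))
  expect_error(psychro_state(20, rh = 50, pressure = -1), "pressure")
  expect_error(psychro_state(200, rh = 50), "plausible")
})

test_that("wind function is the Penman linear form", {
  expect_identical(wind_function(0), 2.626)
  expect_equal(wind_function(1), 4.007)
  expect_equal(wind_function(2), 5.388)
  expect_error(wind_function(-1), "non-negative")
})

test_that("Penman PET matches an independent transcription", {
  st <- psychro_state(20, rh = 50, pressure = 101.325)
  expect_equal(penman_pet(0, 0, 2, st), 0)
  # radiative term only: Rn numerically equal to lambda gives s/(s+gamma)
  expect_equal(penman_pet(st$lambda, 0, 2, st),
               st$s / (st$s + st$gamma), tolerance = 1e-12)
  vpd <- st$e_sat - st$e_act
  expect_equal(penman_pet(10, 1, 2, psychro_state(20, e_act = st$e_sat - 1)),
               penman_oracle(20, 101.325, 10, 2, 1), tolerance = 1e-10)
})

test_that("PET is monotone in radiation and vapour pressure deficit", {
  st <- psychro_state(18, rh = 55)
  rns <- seq(0, 15, 0.5)
  expect_true(all(diff(penman_pet(rns, 0.8, 2, st)) >= 0))
  ds <- seq(0, 2, 0.1)
  expect_true(all(diff(penman_pet(8, ds, 2, st)) >= 0))
})

test_that("aerodynamic conductances follow the series-resistance forms", {
  a <- aerodynamic_conductance(3, 0.3)
  expect_equal(a$Gam, 0.03)
  expect_equal(aerodynamic_conductance(1, 1)$Gbh, 1 / 6.2, tolerance = 1e-12)
  # hand-computed series resistance
  expect_equal(a$Gah, 1 / (1 / 0.03 + 6.2 * 0.3^(-0.67)), tolerance = 1e-12)
  expect_true(a$Gah < min(a$Gam, a$Gbh))
  bad <- aerodynamic_conductance(c(0, 2), c(0.3, 0.25))
  expect_true(is.na(bad$Gah[1]) && !is.na(bad$Gah[2]))
})

test_that("surface conductance inverts the forward Penman-Monteith model", {
  st <- psychro_state(17, rh = 65)
  gah <- aerodynamic_conductance(2.5, 0.3)$Gah
  gs_true <- 0.01
  a_energy <- 180
  le <- penman_monteith_le(a_energy, st$vpd, gah, gs_true, st)
  gsw <- surface_conductance(le, a_energy - le, st$vpd, gah, st)
  expect_equal(as.numeric(gsw), gs_true, tolerance = 1e-8)

  # randomized round trips (property)
  set.seed(99)
  for (i in 1:50) {
    st_i <- psychro_state(runif(1, 2, 30), rh = runif(1, 30, 95))
    gah_i <- aerodynamic_conductance(runif(1, 0.8, 6),
                                     runif(1, 0.08, 0.7))$Gah
    gs_i <- runif(1, 5e-4, 0.05)
    a_i <- runif(1, 30, 400)
    le_i <- penman_monteith_le(a_i, st_i$vpd, gah_i, gs_i, st_i)
    got <- surface_conductance(le_i, a_i - le_i, st_i$vpd, gah_i, st_i)
    expect_equal(as.numeric(got), gs_i, tolerance = 1e-6)
  }
})

test_that("surface conductance flags instead of clipping", {
  st <- psychro_state(17, rh = 65)
  gah <- 0.02
  # zero latent heat is a valid zero conductance, not a flag
  g0 <- surface_conductance(0, 100, 0.8, gah, st)
  expect_equal(as.numeric(g0), 0)
  expect_false(attr(g0, "flagged"))
  # physically inconsistent week: denominator <= 0 (huge LE, tiny D)
  gbad <- surface_conductance(500, -480, 0.01, gah, st)
  expect_true(is.na(as.numeric(gbad)))
  expect_true(attr(gbad, "flagged"))
  # Gsw decreases as VPD grows with fluxes held fixed
  ds <- seq(0.5, 3, 0.25)
  gs <- vapply(ds, function(d)
    as.numeric(surface_conductance(120, 60, d, gah, st)), numeric(1))
  expect_true(all(diff(gs) < 0))
})

test_that("evaporative fraction handles the trivial identities", {
  expect_equal(as.numeric(evaporative_fraction(70, 70)), 0.5)
  expect_equal(as.numeric(evaporative_fraction(70, 0)), 1)
  expect_equal(as.numeric(evaporative_fraction(0, 70)), 0)
  und <- evaporative_fraction(0, 0)
  expect_true(is.na(as.numeric(und)) && attr(und, "flagged"))
})

test_that("derive_micromet appends the derived columns and recovers Gsw", {
  wk <- small_world()
  out <- derive_micromet(wk)
  expect_true(all(c("PET", "GAM", "GBH", "GAH", "GSW", "EF", "ET")
                  %in% names(out)))
  expect_true(all(out$PET >= 0, na.rm = TRUE))
  expect_true(all(out$EF >= 0 & out$EF <= 1, na.rm = TRUE))
  expect_error(derive_micromet(wk[, setdiff(names(wk), "LE")]), "missing")
})
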