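# Carbon-flux calculations from culture measurements.

test_that("relative growth rate matches the exponential-growth formula", {
  expect_equal(relative_growth_rate(B0 = 2, Bt = 2, t = 7), 0)
  expect_equal(relative_growth_rate(B0 = 2, Bt = 16, t = 10), log(8) / 10)
  expect_equal(round(relative_growth_rate(2, 16, 10), 5), 0.20794)
  expect_equal(relative_growth_rate(5, 4, 7), log(0.8) / 7)
  expect_equal(round(relative_growth_rate(5, 4, 7), 5), -0.03188)
  # sign tracks the biomass change
  expect_lt(relative_growth_rate(5, 4, 7), 0)
  expect_gt(relative_growth_rate(5, 6, 7), 0)
})

test_that("growth-rate domain errors name the offending field", {
  expect_error(relative_growth_rate(0, 4, 7), "B0")
  expect_error(relative_growth_rate(2, -1, 7), "Bt")
  expect_error(relative_growth_rate(2, 4, 0), "t")
})

test_that("CO2 conversion agrees with a hand-computed ideal-gas oracle", {
  k <- physio_constants()
  # moles of air in a 274 cm3 loop at 101325 Pa and 293.15 K
  n_loop <- 101325 * 274e-6 / (8.314462 * 293.15)
  expect_equal(n_loop, 0.011391, tolerance = 1e-4)
  oracle <- 100e-6 * n_loop * (1440 / 2.5) * 1000
  expect_equal(co2_to_respiration(100, k), oracle, tolerance = 1e-12)
  expect_equal(co2_to_respiration(100, k), 0.6561, tolerance = 1e-4)
  expect_equal(co2_to_respiration(0, k), 0)
  expect_error(co2_to_respiration(-1, k), "delta_ppm")
})

test_that("CO2 conversion is linear in the concentration rise and loop volume", {
  k <- physio_constants()
  expect_equal(co2_to_respiration(200, k), 2 * co2_to_respiration(100, k))
  for (c_scale in c(0.5, 2, 7.3)) {
    k2 <- physio_constants(loop_volume = 274 * c_scale)
    expect_equal(co2_to_respiration(50, k2), c_scale * co2_to_respiration(50, k))
  }
})

test_that("biomass carbon applies the fixed carbon fraction", {
  expect_equal(biomass_carbon(0), 0)
  expect_equal(biomass_carbon(10), 4.3 / 12.011)
  expect_equal(round(biomass_carbon(10), 5), 0.35801)
  expect_equal(round(biomass_carbon(100), 4), 3.5801)
  expect_error(biomass_carbon(-1), "dry_mass")
})

test_that("metabolic quotient divides respiration by biomass carbon", {
  expect_equal(metabolic_quotient(0.6561, 0.35801), 0.6561 / 0.35801)
  expect_equal(round(metabolic_quotient(0.6561, 0.35801), 4), 1.8326)
  expect_equal(metabolic_quotient(0, 1.5), 0)
  expect_error(metabolic_quotient(0.5, 0), "biomass_c")
})

test_that("CUE is the growth share of total carbon flux", {
  expect_equal(carbon_use_efficiency(0.2, 0.2), 0.5)
  expect_equal(carbon_use_efficiency(0.3, 0.1), 0.75)
  expect_equal(carbon_use_efficiency(0, 0.4), 0)
  expect_error(carbon_use_efficiency(0, 0), "non-zero")
})

test_that("CUE is scale invariant and increasing in growth rate", {
  set.seed(42)
  for (i in 1:25) {
    mu <- runif(1, 0.01, 2)
    q <- runif(1, 0.01, 5)
    ct <- runif(1, 0.01, 100)
    expect_equal(carbon_use_efficiency(ct * mu, ct * q),
                 carbon_use_efficiency(mu, q))
    expect_gt(carbon_use_efficiency(mu * 1.1, q), carbon_use_efficiency(mu, q))
    expect_true(carbon_use_efficiency(mu, q) > 0 &&
                  carbon_use_efficiency(mu, q) < 1)
  }
})

test_that("flux batch flags problem samples instead of aborting", {
  ph <- data.frame(
    sample_id = c("shrinks", "grows", "no_mass", "bad_b0"),
    B0_mg = c(5, 2, 2, 0),
    Bt_mg = c(4, 16, 0, 4),
    t_days = c(7, 10, 7, 7),
    delta_co2_ppm = c(50, 100, 20, 30))
  fx <- compute_fluxes(ph)
  expect_s3_class(fx, "flux_table")
  expect_equal(fx$qc_flags, c("NEGATIVE_GROWTH", "", "ZERO_BIOMASS",
                              "INVALID_RECORD"))
  expect_equal(usable_samples(fx), "grows")
  expect_true(is.na(fx$qco2_per_day[3]))
  expect_equal(fx$mu_per_day[2], log(8) / 10)
})

test_that("noiseless synthetic measurements round-trip through the flux equations", {
  ph <- invert_physiology(mu = 0.2, qco2 = 1.0, B0 = 2, t = 10)
  fx <- compute_fluxes(ph)
  expect_equal(fx$mu_per_day, 0.2, tolerance = 1e-9)
  expect_equal(fx$qco2_per_day, 1.0, tolerance = 1e-9)
  expect_equal(fx$cue, 1 / 6, tolerance = 1e-9)
  expect_equal(fx$qc_flags, "")
})

test_that("flux tables survive a write/read cycle", {
  ph <- invert_physiology(mu = c(0.1, 0.3), qco2 = c(0.5, 1.2),
                          B0 = 2, t = 8)
  fx <- compute_fluxes(ph)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_fluxes(fx, path)
  back <- utils::read.delim(path, colClasses = c(qc_flags = "character"))
  expect_equal(back$mu_per_day, fx$mu_per_day)
  expect_equal(back$cue, fx$cue)
})
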