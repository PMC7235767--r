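db <- species_db()

test_that("Buswell-Boyle yields reproduce the printed worked examples", {
  expect_equal(round(buswell_yield(db$nalidixic_acid), 2), 0.58,
               ignore_attr = TRUE)
  expect_equal(round(buswell_yield(db$gaba), 2), 0.49,
               ignore_attr = TRUE)
  # hand stoichiometry: glucose -> 3 mol CH4 / mol
  expect_equal(as.numeric(buswell_yield(db$glucose)),
               3 * 22.414 / 180.16, tolerance = 1e-12)
  expect_false(attr(buswell_yield(db$glucose), "non_methanogenic"))
})

test_that("fully oxidised carbon is clamped and flagged", {
  co2 <- chemical_species("CO2", c = 1, o = 2, molar_mass = 44.01)
  y <- buswell_yield(co2)
  expect_equal(as.numeric(y), 0)
  expect_true(attr(y, "non_methanogenic"))
})

test_that("buswell_yield is scale-consistent and guards composition", {
  single <- chemical_species("gaba", c = 4, h = 9, o = 2, n = 1,
                             molar_mass = 103.12)
  double <- chemical_species("2x", c = 8, h = 18, o = 4, n = 2,
                             molar_mass = 206.24)
  expect_equal(as.numeric(buswell_yield(single)),
               as.numeric(buswell_yield(double)), tolerance = 1e-12)
  expect_error(buswell_yield(db$sodium_phosphate),
               class = "digestor_composition_error")
  carbonless <- chemical_species("water", h = 2, o = 1, molar_mass = 18.02)
  expect_error(buswell_yield(carbonless),
               class = "digestor_composition_error")
  expect_error(chemical_species("bad", c = 6, h = 12, o = 6,
                                molar_mass = 120),
               class = "digestor_composition_error")
  expect_error(chemical_species("neg", c = -1, molar_mass = 10),
               class = "digestor_composition_error")
})

test_that("theoretical methane potentials match the printed chain", {
  expect_equal(round(theoretical_methane(21.11, db$nalidixic_acid), 2),
               12.24)
  expect_equal(round(theoretical_methane(21.11, db$gaba), 2), 10.34)
  expect_equal(theoretical_methane(0, db$glucose), 0)
  # linearity in load (full-precision yield)
  y1 <- theoretical_methane(3, db$glucose, yield_digits = NULL)
  y2 <- theoretical_methane(6, db$glucose, yield_digits = NULL)
  expect_equal(2 * y1, y2, tolerance = 1e-12)
  # direct per-gram factor for an empirical conversion basis
  expect_equal(theoretical_methane(78.26, yield = 28.96 / 78.26,
                                   yield_digits = NULL), 28.96,
               tolerance = 1e-12)
  expect_error(theoretical_methane(-1, db$glucose),
               class = "digestor_domain_error")
})

test_that("organic loading rate follows the weekly VS arithmetic", {
  week <- function(glu, stress = 0, organic = FALSE) {
    do.call(rbind, lapply(c(0, 2, 4), function(d) {
      feeding_event(d, substrate_load = glu,
                    stressor_load = if (d == 0) stress else 0,
                    stressor_is_organic = organic)
    }))
  }
  expect_equal(round(organic_loading_rate(week(1)), 2), 0.43)
  expect_equal(round(organic_loading_rate(week(3)), 2), 1.29)
  expect_equal(round(organic_loading_rate(week(3, 1, TRUE)), 2), 1.43)
  # inorganic stressor leaves the OLR unchanged
  expect_equal(organic_loading_rate(week(3, 5, FALSE)),
               organic_loading_rate(week(3)))
  expect_equal(organic_loading_rate(NULL), 0)
  # additivity over events
  a <- week(2); b <- week(1)
  expect_equal(organic_loading_rate(rbind(a, b)),
               organic_loading_rate(a) + organic_loading_rate(b),
               tolerance = 1e-12)
  spread <- rbind(feeding_event(0, 1), feeding_event(8, 1))
  expect_error(organic_loading_rate(spread),
               class = "digestor_domain_error")
})

test_that("hydraulic retention time matches the reactor arithmetic", {
  expect_equal(hydraulic_retention_time(reactor_config(3, 0.15, 3)),
               46 + 2 / 3, tolerance = 1e-12)
  expect_equal(trunc(hydraulic_retention_time(
    reactor_config(3, 0.15, 3)) * 100) / 100, 46.66)
  expect_equal(hydraulic_retention_time(reactor_config(3, 3, 7)), 1)
  expect_equal(hydraulic_retention_time(reactor_config(1, 0.5, 2)), 7)
  expect_error(hydraulic_retention_time(reactor_config(3, 0, 3)),
               class = "digestor_no_throughput_error")
})

test_that("efficiency and expected surplus reproduce the printed values", {
  expect_equal(round(digestion_efficiency(16.66, 28.96), 2), 57.53)
  expect_equal(digestion_efficiency(5, 5), 100)
  expect_equal(digestion_efficiency(0, 10), 0)
  expect_error(digestion_efficiency(1, 0), class = "digestor_domain_error")
  expect_equal(round(expected_surplus(12.24, 57.53), 2), 7.04)
  expect_equal(round(expected_surplus(10.34, 57.53), 2), 5.95)
  expect_equal(expected_surplus(99, 0), 0)
})

test_that("gas normalisation is the ideal-gas correction", {
  expect_equal(normalize_gas_volume(gas_measurement(1, 273, 1013)), 1)
  expect_equal(normalize_gas_volume(1, 546, 2026), 1)
  expect_equal(normalize_gas_volume(1, 303, 1013), 273 / 303,
               tolerance = 1e-12)
  # composing with the inverse transformation is the identity
  set.seed(42)
  for (i in 1:20) {
    v <- runif(1, 0.1, 10); tk <- runif(1, 250, 330)
    p <- runif(1, 900, 1100)
    vn <- normalize_gas_volume(v, tk, p)
    back <- vn * (tk / 273) * (1013 / p)
    expect_equal(back, v, tolerance = 1e-12)
  }
  expect_error(gas_measurement(1, 0, 1013), class = "digestor_domain_error")
  expect_error(gas_measurement(1, 293, -2), class = "digestor_domain_error")
})

test_that("molar concentration reproduces the phosphate molarity", {
  expect_equal(round(molar_concentration(20.5, db$sodium_phosphate)), 125)
  expect_equal(molar_concentration(163.94, db$sodium_phosphate), 1000)
  expect_equal(molar_concentration(0, db$glucose), 0)
})
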