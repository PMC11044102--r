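test_that("injection variance follows the plug-dilution form", {
  expect_equal(injection_variance(0, 2000, 1, 1)$sigma_v_sq, 0)
  # matched solvent: ratio term is 1, Vinj^2 / delta^2
  iv <- injection_variance(10, 2000, k_e = 3, k_ss = 3)
  expect_equal(iv$sigma_v_sq, 100 / 8)
  expect_equal(iv$sigma_t_sq, 12.5 / 2000^2)
  iv2 <- injection_variance(12.75, 1000, k_e = 2, k_ss = 20)
  expect_equal(iv2$sigma_v_sq, (12.75^2 / 8) * (3 / 21)^2, tolerance = 1e-12)
  expect_equal(iv2$sigma_v_sq, 0.4146, tolerance = 1e-3)
  # pluggable hook
  ivh <- injection_variance(10, 100, 1, 1,
                            variance_fn = function(V, F, d2, ke, kss) V^2 / 12)
  expect_equal(ivh$sigma_v_sq, 100 / 12)
})

test_that("injection variance is monotone in volume and solvent mismatch", {
  v <- vapply(c(1, 5, 10, 20), function(V)
    injection_variance(V, 2000, 1, 1)$sigma_v_sq, numeric(1))
  expect_true(all(diff(v) > 0))
  r <- vapply(c(0.1, 1, 5, 20), function(kss)
    injection_variance(10, 2000, k_e = 2, k_ss = kss)$sigma_v_sq, numeric(1))
  expect_true(all(diff(r) < 0))   # weaker sample solvent focuses
})

test_that("sample-solvent composition blends effluent and make-up", {
  expect_equal(sample_solvent_composition(0.2, F1 = 17, Fmu = 0), 0.8)
  expect_equal(sample_solvent_composition(1, 17, 68, 0), 0)
  expect_equal(sample_solvent_composition(0.13, 17, 68, 0), 17 * 0.87 / 85)
  expect_equal(sample_solvent_composition(0.13, 17, 68, 0), 0.174)
  # same-convention pairing passes the fraction through
  expect_equal(sample_solvent_composition(0.3, 17, 0, invert = FALSE), 0.3)
})

test_that("modulation geometry reproduces fraction-volume arithmetic", {
  g <- modulation_geometry(F1 = 17, Fmu = 68, ts = 0.75, loop_volume = 80)
  expect_equal(g$eluent_fraction, 12.75)
  expect_equal(g$total_fraction, 63.75)
  expect_equal(g$fill_fraction, 63.75 / 80)
  expect_equal(modulation_geometry(17, 0, 1.1, 230)$eluent_fraction, 18.7)
  expect_error(modulation_geometry(17, 153, 0.75, 80), "infeasible")
})

test_that("loop overflow triggers infeasibility exactly at capacity", {
  expect_silent(modulation_geometry(10, 90, 1, 100))          # fill = 1
  expect_error(modulation_geometry(10, 90 + 1e-6, 1, 100))    # just over
})

test_that("column variance and total variance combine additively", {
  expect_equal(column_variance_gradient(0.2, 6400, 0), (0.2 / 80)^2)
  expect_equal(sqrt(column_variance_gradient(0.2, 6400, 3)), 0.01)
  expect_equal(column_variance_gradient(0.2, 6400, 3, G = 0.8),
               0.64 * column_variance_gradient(0.2, 6400, 3))
  expect_equal(total_peak_variance(1, 0, 0), 1)
  expect_equal(total_peak_variance(1, 2, 3), 6)
})

test_that("undersampling factor follows sqrt(1 + 0.21 (ts/sigma)^2)", {
  expect_equal(undersampling_factor(1e-6, 1), 1, tolerance = 1e-9)
  expect_equal(undersampling_factor(1, 1), sqrt(1.21))
  expect_equal(undersampling_factor(4, 1), sqrt(1 + 0.21 * 16))
  expect_gte(undersampling_factor(0.5, 2), 1)
})

test_that("peak capacities follow the window / 4 sigma construction", {
  expect_equal(dimension_peak_capacity(0, 10, 0.25 / 4), 41)
  expect_equal(dimension_peak_capacity(5, 5, 0.1), 1)
  n1 <- dimension_peak_capacity(0, 10, 0.2)
  n2 <- dimension_peak_capacity(0, 10, 0.1)
  expect_equal(n2 - 1, 2 * (n1 - 1))
  expect_equal(two_dimensional_peak_capacity(1, 7), 7)
  expect_equal(two_dimensional_peak_capacity(32, 78), 2496)
  expect_equal(two_dimensional_peak_capacity(32, 78),
               two_dimensional_peak_capacity(78, 32))
})

test_that("dilution factors follow the Gaussian peak-maximum form", {
  expect_equal(dilution_factor_makeup(17, 0), 1)
  expect_equal(dilution_factor_makeup(17, 68), 5)
  expect_equal(dilution_factor_dimension(10 / sqrt(2 * pi), 10), 1)
  expect_gte(dilution_factor_dimension(20 / sqrt(2 * pi), 10), 1)
})

test_that("pressure drop follows Darcy's law with correct units", {
  col <- lc_column(50, 3.0, 1.8, porosity = 0.55, flow_resistance = 700,
                   max_pressure = 1200)
  # flow giving u = 5 mm/s: t0 = L/(u 60) min, flow = V0/t0
  V0 <- 0.55 * pi * 1.5^2 * 50
  flow <- V0 * 5 * 60 / 50
  expect_equal(pressure_drop(col, flow, viscosity = 1),
               700 * 1 * 50 * 5 / 1.8^2 / 100, tolerance = 1e-12)
  expect_equal(pressure_drop(col, flow, 1), 540.1, tolerance = 1e-3)
  expect_equal(pressure_drop(col, 2 * flow, 1),
               2 * pressure_drop(col, flow, 1))
  col2 <- lc_column(50, 3.0, 3.6, porosity = 0.55, flow_resistance = 700)
  expect_equal(pressure_drop(col2, flow, 1), pressure_drop(col, flow, 1) / 4)
  expect_false(pressure_feasible(col, flow * 3, 1))
})

test_that("viscosity interpolation covers the water/ACN range", {
  eta <- solvent_viscosity(c(0, 0.5, 1), temperature = 30)
  expect_true(all(eta > 0))
  expect_true(all(solvent_viscosity(seq(0, 1, 0.1), 60) <
                  solvent_viscosity(seq(0, 1, 0.1), 30)))
})

test_that("column state derives void volume, dead time and velocity", {
  col <- lc_column(150, 1.0, 1.7, porosity = 0.6)
  st <- column_state(col, flow = 17, van_deemter(3.4, 0, 0), n_max = 1e6)
  expect_equal(st$V0, 0.6 * pi * 0.25 * 150)
  expect_equal(st$t0, st$V0 / 17)
  expect_equal(st$u, 150 / (st$t0 * 60))
  expect_equal(st$N, 150 * 1000 / 3.4)
  expect_warning(column_state(col, 17, van_deemter(3.4, 0, 0), n_max = 100),
                 "capped")
})
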