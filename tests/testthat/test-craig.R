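test_that("injection profile integrates to unit mass with correct timing", {
  # rectangular limit: no tail, full loop
  ip <- make_injection_profile(80, 1, 2000, 0.2, 0.01, tail_constant = 0)
  expect_equal(sum(ip$mass), 1, tolerance = 1e-12)
  dur <- length(ip$mass) * ip$dt
  expect_equal(dur, 80 / 2000, tolerance = 1e-6)
  expect_lt(diff(range(ip$mass)), 1e-12)          # flat plug
  expect_true(all(abs(ip$phi - 0.2) < 1e-12))
  # partial fill: 0.02 min of loop-resident mobile phase precedes the plug
  ip2 <- make_injection_profile(80, 0.5, 2000, 0.5, 0.01, tail_constant = 0)
  expect_equal(sum(ip2$mass), 1, tolerance = 1e-12)
  pre <- ip2$time[ip2$mass > 0][1]
  expect_equal(pre, 0.02, tolerance = 1e-3)
  expect_equal(max(ip2$time[ip2$mass > 0]) + ip2$dt, 0.04, tolerance = 1e-3)
  expect_equal(ip2$phi[ip2$time < 0.019], rep(0.01, sum(ip2$time < 0.019)))
  # dispersed default still integrates to 1
  ip3 <- make_injection_profile(80, 0.8, 2000, 0.5, 0.01)
  expect_equal(sum(ip3$mass), 1, tolerance = 1e-12)
  expect_error(make_injection_profile(80, 1.2, 2000, 0.5, 0.01),
               "fill_fraction")
})

test_that("measured-profile import normalises mass and validates the grid", {
  tab <- data.frame(time_min = seq(0, 0.05, by = 0.001),
                    relative_concentration = c(0, rep(2, 30), rep(1, 20)))
  ip <- injection_profile_from_table(tab, sample_solvent = 0.3)
  expect_equal(sum(ip$mass), 1)
  expect_true(all(ip$phi == 0.3))
  bad <- data.frame(time_min = c(0, 0.001, 0.005),
                    relative_concentration = c(1, 1, 1))
  expect_error(injection_profile_from_table(bad, 0.3), "uniform")
})

test_that("isocratic pulse propagation equals the binomial Craig form", {
  # independent oracle: after the injection transfer plus n further
  # transfers, the occupancy of cell 1 + r is the binomial C(n, r) p^r q^(n-r)
  for (kk in c(0.5, 2, 9)) {
    N <- 150
    p <- 1 / (1 + kk)
    n <- 100
    res <- lcxlcopt:::.craig_core(N, 1, rep(p, n + 1), p, n + 1L, 0, TRUE)
    expect_lt(max(abs(res$cells - dbinom(0:(N - 1), n, p))), 1e-9)
    expect_lt(res$max_mass_err, 1e-12)
  }
})

test_that("simulator conserves mass at every step", {
  st <- fix_state2(800)
  m <- retention_model("lss", k0 = 8, S = 12)
  g <- fix_gradient2()
  ip <- make_injection_profile(80, 0.8, 2000, 0.5, 0.01)
  prof <- simulate_elution(m, st, g, ip)
  expect_lt(prof$max_mass_err, 1e-9)
  expect_equal(prof$eluted_mass + prof$in_column, prof$injected_mass,
               tolerance = 1e-9)
  expect_equal(prof$injected_mass, 1, tolerance = 1e-9)
  expect_true(all(prof$flux >= 0))
})

test_that("simulator reaches the Gaussian plate-theory limit", {
  # well-retained isocratic solute, tiny matched injection: apex at
  # t0 (1 + k) within a step and plate count recovered from the moments
  st <- fix_state2(1000)
  k <- 25
  m <- retention_model("lss", k0 = k, S = 0)
  g <- gradient_program(0.2, 0.2, t_grad = 1, flow = 2000)
  ip <- make_injection_profile(0.5, 1, 2000, 0.2, 0.2, tail_constant = 0)
  prof <- simulate_elution(m, st, g, ip, horizon = 5)
  mom <- profile_moments(prof)
  # the discrete mode sits one part in N below the mean elution time
  expect_lt(abs(mom$t_apex - st$t0 * (1 + k)), 2 * (1 + k) * prof$dt)
  N_rec <- (mom$t_mean / mom$sigma_moment)^2
  expect_lt(abs(N_rec - st$N) / st$N, 0.05)
  expect_equal(mom$n_maxima, 1)
  # half-height and moment widths agree for a Gaussian peak
  expect_equal(mom$sigma_halfheight, mom$sigma_moment, tolerance = 0.05)
})

test_that("profile moments match closed forms on constructed profiles", {
  dt <- 1e-3
  t <- seq(0, 2, by = dt)
  # Gaussian, sigma = 0.01 min
  f <- stats::dnorm(t, 1, 0.01)
  p <- list(time = t, flux = f, mass = f * dt)
  mom <- profile_moments(p)
  expect_equal(mom$sigma_moment, 0.01, tolerance = 1e-3)
  expect_equal(mom$sigma_halfheight, 0.01, tolerance = 1e-2)
  expect_equal(mom$t_apex, 1, tolerance = dt)
  # rectangular pulse of width w: sigma = w / sqrt(12)
  w <- 0.2
  f2 <- as.numeric(t >= 0.9 & t < 0.9 + w)
  p2 <- list(time = t, flux = f2, mass = f2 * dt)
  expect_equal(profile_moments(p2)$sigma_moment, w / sqrt(12),
               tolerance = 1e-2)
  expect_error(profile_moments(list(time = t, flux = 0 * t, mass = 0 * t)),
               "all-zero")
})

test_that("split detection counts well-separated maxima only", {
  t <- seq(0, 1, by = 1e-3)
  g1 <- stats::dnorm(t, 0.3, 0.02)
  g2 <- stats::dnorm(t, 0.7, 0.02)
  two <- list(time = t, flux = g1 + g2, mass = (g1 + g2) * 1e-3)
  one <- list(time = t, flux = g1, mass = g1 * 1e-3)
  shoulder <- list(time = t, flux = g1 + 0.02 * g2,
                   mass = (g1 + 0.02 * g2) * 1e-3)
  expect_equal(detect_peak_splitting(two), 2)
  expect_equal(detect_peak_splitting(one), 1)
  expect_equal(detect_peak_splitting(shoulder), 1)   # below 5% prominence
  # overlapping shoulder above prominence but with a shallow valley
  g3 <- stats::dnorm(t, 0.34, 0.02)
  sh2 <- list(time = t, flux = g1 + 0.8 * g3, mass = (g1 + 0.8 * g3) * 1e-3)
  expect_equal(detect_peak_splitting(sh2), 1)
})

test_that("strong sample solvent with high fill splits the peak", {
  st <- fix_state2(800)
  m <- retention_model("lss", k0 = 8, S = 12)
  g <- fix_gradient2()
  over <- simulate_elution(m, st, g,
    make_injection_profile(80, 0.8, 2000, 0.5, 0.01))
  ctrl <- simulate_elution(m, st, g,
    make_injection_profile(80, 0.8, 2000, 0.01, 0.01))
  expect_gte(profile_moments(over)$n_maxima, 2)
  expect_equal(profile_moments(ctrl)$n_maxima, 1)
  expect_gt(profile_moments(over)$sigma_moment,
            profile_moments(ctrl)$sigma_moment)
})

test_that("weak sample solvent focuses the band", {
  st <- fix_state2(800)
  m <- retention_model("lss", k0 = 8, S = 12)
  g <- fix_gradient2()
  weak <- simulate_elution(m, st, g,
    make_injection_profile(80, 0.8, 2000, 0, 0.01))
  matched <- simulate_elution(m, st, g,
    make_injection_profile(80, 0.8, 2000, 0.01, 0.01))
  expect_lte(profile_moments(weak)$sigma_moment,
             profile_moments(matched)$sigma_moment)
})

test_that("band broadening grows with loop fill below breakthrough", {
  st <- fix_state2(600)
  m <- retention_model("lss", k0 = 8, S = 12)
  g <- fix_gradient2()
  sig <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(f) {
    prof <- simulate_elution(m, st, g,
      make_injection_profile(80, f, 2000, 0.15, 0.01))
    profile_moments(prof)$sigma_moment
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("simulation is deterministic", {
  st <- fix_state2(400)
  m <- retention_model("lss", k0 = 8, S = 12)
  g <- fix_gradient2()
  ip <- make_injection_profile(80, 0.8, 2000, 0.3, 0.01)
  p1 <- simulate_elution(m, st, g, ip)
  p2 <- simulate_elution(m, st, g, ip)
  expect_identical(p1$flux, p2$flux)
  expect_identical(p1$time, p2$time)
})

test_that("incomplete elution at the horizon is flagged", {
  st <- fix_state2(400)
  m <- retention_model("lss", k0 = 500, S = 1)   # barely eluted by gradient
  g <- gradient_program(0.01, 0.05, t_grad = 0.2, flow = 2000)
  ip <- make_injection_profile(10, 1, 2000, 0.01, 0.01)
  expect_warning(prof <- simulate_elution(m, st, g, ip, horizon = 0.3),
                 "not fully eluted")
  expect_false(prof$complete)
  expect_lt(prof$eluted_mass, 1)
})
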