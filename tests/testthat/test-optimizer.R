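# helper: matched-solvent single-analyte fixture where theory and the Craig
# simulation should agree (flat well-retained 2D, make-up matched solvent)
matched_fixture <- function() {
  ins <- fix_instrument(n_max = 400, strong_d1 = "acn", strong_d2 = "acn")
  an <- analyte("x",
    retention_model("adsorption", k100 = 0.2, n = 1),
    retention_model("lss", k0 = 25 * exp(3), S = 10),
    van_deemter(3, 4, 0.5), van_deemter(3, 4, 0.5))
  list(ins = ins, an = an)
}

test_that("enumeration is the Cartesian product filtered by feasibility", {
  rng <- parameter_ranges(
    f1 = c(13, 17), f2 = 2000, ts = c(0.55, 0.75), fmu = 68,
    loop = c(80, 180),
    d1_gradients = list(list(phi_init = 0.01, phi_final = 0.25, t_grad = 55)),
    d2_gradients = list(list(phi_init = 0.01, phi_final = 0.55, t_grad = NA)))
  cfgs <- enumerate_feasible_configs(rng, fix_d1_column(), fix_d2_column(),
                                     fix_instrument())
  # (17+68)*0.75 = 63.75 <= 80: all 8 combinations feasible
  expect_length(cfgs, 8)
  expect_equal(sum(attr(cfgs, "exclusions")), 0)
})

test_that("loop capacity excludes oversized fractions", {
  # (17+153)*0.75 = 127.5 uL needs more than the 80 uL loop
  rng <- parameter_ranges(
    f1 = 17, f2 = 2000, ts = 0.75, fmu = 153, loop = c(80, 160),
    d1_gradients = list(list(phi_init = 0.01, phi_final = 0.25, t_grad = 55)),
    d2_gradients = list(list(phi_init = 0.01, phi_final = 0.55, t_grad = NA)))
  cfgs <- enumerate_feasible_configs(rng, fix_d1_column(), fix_d2_column(),
                                     fix_instrument())
  expect_length(cfgs, 1)
  expect_equal(cfgs[[1]]$modulation$loop_volume, 160)
  expect_equal(attr(cfgs, "exclusions")[["loop"]], 1)
})

test_that("an unreachable pressure cap yields an explicit empty-set error", {
  rng <- parameter_ranges(
    f1 = 17, f2 = 2000, ts = 0.75, fmu = 68, loop = 80,
    d1_gradients = list(list(phi_init = 0.01, phi_final = 0.25, t_grad = 55)),
    d2_gradients = list(list(phi_init = 0.01, phi_final = 0.55, t_grad = NA)))
  d2 <- lc_column(50, 3.0, 1.8, porosity = 0.55, max_pressure = 1)
  expect_error(
    enumerate_feasible_configs(rng, fix_d1_column(), d2, fix_instrument()),
    "pressure_d2 = 1")
})

test_that("cycle feasibility requires gradient plus re-equilibration", {
  rng <- parameter_ranges(
    f1 = 17, f2 = 2000, ts = 0.5, fmu = 68, loop = 80,
    d1_gradients = list(list(phi_init = 0.01, phi_final = 0.25, t_grad = 55)),
    d2_gradients = list(list(phi_init = 0.01, phi_final = 0.55,
                             t_grad = 0.45)))  # 0.45 + 0.1 > 0.5
  expect_error(
    enumerate_feasible_configs(rng, fix_d1_column(), fix_d2_column(),
                               fix_instrument()),
    "cycle = 1")
})

test_that("pareto front matches the brute-force dominance oracle", {
  set.seed(11)
  for (n in c(5, 50, 500)) {
    nc <- runif(n, 100, 3000)
    tm <- runif(n, 20, 60)
    dl <- runif(n, 2, 10)
    pts <- lapply(seq_len(n), function(i) fix_point(nc[i], tm[i], dl[i]))
    front <- pareto_front(pts)
    expect_setequal(attr(front, "indices"), oracle_front_idx(nc, tm, dl))
  }
})

test_that("duplicated objective vectors are all retained", {
  pts <- list(fix_point(100, 30, 5), fix_point(100, 30, 5),
              fix_point(50, 40, 6))
  front <- pareto_front(pts)
  expect_setequal(attr(front, "indices"), c(1, 2))
})

test_that("adding a dominated point never changes the front", {
  set.seed(22)
  pts <- lapply(1:20, function(i)
    fix_point(runif(1, 100, 3000), runif(1, 20, 60), runif(1, 2, 10)))
  base_idx <- attr(pareto_front(pts), "indices")
  worst <- fix_point(min(sapply(pts, function(p) p$metrics$nc_2d)) - 1,
                     max(sapply(pts, function(p) p$metrics$analysis_time)) + 1,
                     max(sapply(pts, function(p) p$metrics$dilution_total)) + 1)
  expect_setequal(attr(pareto_front(c(pts, list(worst))), "indices"),
                  base_idx)
})

test_that("theoretical and simulated metrics agree for matched solvent and tiny injection", {
  fx <- matched_fixture()
  cfg <- suppressWarnings(experimental_config(
    fix_d1_column(), gradient_program(0.01, 0.25, 30, 5, dwell_volume = 13),
    fix_d2_column(), gradient_program(0.3, 0.3, 0.4, 2000, dwell_volume = 55),
    modulation_settings(0.5, 45, 30, makeup_composition = 0.3), fx$ins))
  th <- suppressWarnings(evaluate_config_theoretical(cfg, list(fx$an)))
  sm <- suppressWarnings(evaluate_config_simulated(cfg, list(fx$an)))
  for (f in c("n1c_corrected", "n2c", "nc_2d", "analysis_time",
              "dilution_total"))
    expect_equal(sm$metrics[[f]], th$metrics[[f]], tolerance = 0.05)
})

test_that("make-up flow scales injected volume and make-up dilution linearly", {
  fx <- matched_fixture()
  mk_cfg <- function(fmu) suppressWarnings(experimental_config(
    fix_d1_column(), gradient_program(0.01, 0.25, 30, 5, dwell_volume = 13),
    fix_d2_column(), gradient_program(0.3, 0.3, 0.4, 2000, dwell_volume = 55),
    modulation_settings(0.5, fmu, 60, makeup_composition = 0.3), fx$ins))
  a <- suppressWarnings(evaluate_config_theoretical(mk_cfg(15), list(fx$an)))
  b <- suppressWarnings(evaluate_config_theoretical(mk_cfg(35), list(fx$an)))
  expect_equal(b$detail$V_inj / a$detail$V_inj, 2)   # (5+35)/(5+15)
  expect_equal(dilution_factor_makeup(5, 35) / dilution_factor_makeup(5, 15),
               2)
})

test_that("refinement leaves a matched-solvent front unchanged", {
  ins <- fix_instrument(n_max = 400, strong_d1 = "acn", strong_d2 = "acn")
  mk_an <- function(name, k0, S, k100, nn) analyte(name,
    retention_model("adsorption", k100 = k100, n = nn),
    retention_model("lss", k0 = k0, S = S),
    van_deemter(3, 4, 0.5), van_deemter(3, 4, 0.5))
  ana <- list(mk_an("a", 300, 19, 0.2, 1), mk_an("b", 60, 13.5, 0.1, 1))
  rng <- parameter_ranges(
    f1 = c(13, 17, 26), f2 = 2000, ts = c(0.5, 0.7), fmu = 200, loop = 200,
    d1_gradients = list(list(phi_init = 0.01, phi_final = 0.25, t_grad = 30)),
    d2_gradients = list(list(phi_init = 0.3, phi_final = 0.3, t_grad = NA)),
    makeup_composition = 0.3)
  h <- suppressWarnings(
    hybrid_optimize(rng, ana, fix_d1_column(), fix_d2_column(), ins))
  expect_length(h$removed, 0)
  cfg_key <- function(p) c(p$config$d1_gradient$flow,
                           p$config$modulation$sampling_time)
  expect_setequal(lapply(unclass(h$refined_front), cfg_key),
                  lapply(unclass(h$preliminary_front), cfg_key))
})

test_that("hybrid refinement matches the full-simulation oracle on a small grid", {
  rng <- fix_ranges_3x3()
  ana <- fix_analytes(3, seed = 42)
  h <- suppressWarnings(
    hybrid_optimize(rng, ana, fix_d1_column(), fix_d2_column(),
                    fix_instrument()))
  fs <- suppressWarnings(
    full_sim_optimize(rng, ana, fix_d1_column(), fix_d2_column(),
                      fix_instrument()))
  # computational-savings contract: simulations only for the stage-1 front
  expect_equal(h$n_simulations, length(h$preliminary_front) * 3)
  expect_lt(length(h$preliminary_front), h$n_configs)

  # overload configs kept by theory alone are removed at stage 3 and are
  # absent from the full-simulation front as well
  expect_gt(length(h$removed), 0)
  cfg_key <- function(p) paste(p$config$d1_gradient$flow,
                               p$config$modulation$sampling_time)
  full_keys <- vapply(unclass(fs$front), cfg_key, character(1))
  for (p in h$removed) expect_false(cfg_key(p) %in% full_keys)

  # every hybrid-front objective vector is within 5% (per objective) of a
  # point on the full-simulation front
  obj <- function(p) c(p$metrics$nc_2d, p$metrics$analysis_time,
                       p$metrics$dilution_total)
  fo <- t(vapply(unclass(fs$front), obj, numeric(3)))
  for (p in unclass(h$refined_front)) {
    po <- obj(p)
    devs <- apply(fo, 1, function(x) max(abs(po - x) / x))
    expect_lt(min(devs), 0.05)
  }
})

test_that("hybrid runs are deterministic end to end", {
  rng <- parameter_ranges(
    f1 = c(17, 26), f2 = 2000, ts = 0.55, fmu = 68, loop = 80,
    d1_gradients = list(list(phi_init = 0.01, phi_final = 0.25, t_grad = 55)),
    d2_gradients = list(list(phi_init = 0.01, phi_final = 0.55, t_grad = NA)))
  ana <- fix_analytes(2, seed = 5)
  h1 <- suppressWarnings(
    hybrid_optimize(rng, ana, fix_d1_column(), fix_d2_column(),
                    fix_instrument()))
  h2 <- suppressWarnings(
    hybrid_optimize(rng, ana, fix_d1_column(), fix_d2_column(),
                    fix_instrument()))
  expect_identical(as.data.frame(h1$refined_front),
                   as.data.frame(h2$refined_front))
})

test_that("front export writes one row per point", {
  pts <- list(fix_point(100, 30, 5), fix_point(50, 40, 6))
  pts[[1]]$config <- pts[[2]]$config <- suppressWarnings(experimental_config(
    fix_d1_column(), gradient_program(0.01, 0.25, 55, 17),
    fix_d2_column(), gradient_program(0.01, 0.55, 0.45, 2000),
    modulation_settings(0.55, 68, 80), fix_instrument()))
  pts[[1]]$evaluation <- pts[[2]]$evaluation <- "theoretical"
  f <- withr::local_tempfile(fileext = ".csv")
  export_front(pts, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("f1", "ts", "loop", "nc_2d", "dilution") %in% names(tab)))
})
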