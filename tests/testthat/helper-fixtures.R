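# Shared fixtures: a HILIC x RP-LC instrument with sub-2-um columns.
# Plate counts are capped low so Craig simulations stay fast; the cap
# warning is expected and silenced where fixtures are built.

fix_d1_column <- function() {
  lc_column(length = 150, id = 1.0, dp = 1.7, porosity = 0.6,
            flow_resistance = 700, max_pressure = 1000)
}

fix_d2_column <- function() {
  lc_column(length = 50, id = 3.0, dp = 1.8, porosity = 0.55,
            flow_resistance = 700, max_pressure = 1200)
}

fix_instrument <- function(n_max = 600, ...) {
  instrument_config(n_max = n_max, ...)
}

# small 2D column state with a forced plate count
fix_state2 <- function(N = 1000, flow = 2000) {
  st <- suppressWarnings(
    column_state(fix_d2_column(), flow, van_deemter(3.6, 0, 0), n_max = N))
  st
}

# paper-style 2D gradient: 1-55% in 0.56 min at 2 mL/min
fix_gradient2 <- function(flow = 2000, dwell = 55) {
  gradient_program(0.01, 0.55, t_grad = 0.56, flow = flow,
                   dwell_volume = dwell)
}

fix_analytes <- function(n = 3, seed = 42) {
  generate_synthetic_analytes(n, seed = seed)
}

fix_ranges_3x3 <- function() {
  parameter_ranges(
    f1 = c(13, 17, 26), f2 = 2000, ts = c(0.55, 0.65, 0.75),
    fmu = 68, loop = 80,
    d1_gradients = list(list(phi_init = 0.01, phi_final = 0.25, t_grad = 55)),
    d2_gradients = list(list(phi_init = 0.01, phi_final = 0.55,
                             t_grad = NA)))
}

# wrap bare objective triples as pareto points for front tests
fix_point <- function(nc, time, dil) {
  structure(list(config = NULL,
                 metrics = list(n1c_corrected = NA_real_, n2c = NA_real_,
                                nc_2d = nc, analysis_time = time,
                                dilution_total = dil),
                 evaluation = "theoretical"),
            class = "pareto_point")
}

# independent brute-force dominance oracle (maximize nc, minimize time/dil)
oracle_front_idx <- function(nc, time, dil) {
  n <- length(nc)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (nc[j] >= nc[i] && time[j] <= time[i] && dil[j] <= dil[i] &&
          (nc[j] > nc[i] || time[j] < time[i] || dil[j] < dil[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}
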