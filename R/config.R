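#' Instrument description
#'
#' System-level constants shared by all candidate methods.
#'
#' @param dwell_d1,dwell_d2 Dwell volumes (uL) of the two gradient pumps
#'   (excluding the sample loop).
#' @param ec_var_d1,ec_var_d2 Extra-column variances (uL^2). Only
#'   post-column broadening is counted in the second dimension, since
#'   focusing at the column inlet nullifies pre-column broadening for
#'   retained solutes.
#' @param max_pressure_d1,max_pressure_d2 Instrument pressure limits (bar).
#' @param temp_d1,temp_d2 Operating temperatures (C), used for viscosity.
#' @param strong_d1,strong_d2 Identity of each dimension's strong solvent,
#'   `"water"` or `"acn"`; needed to look up viscosity (the table is in
#'   acetonitrile fraction) and defaulting to the HILIC x RP-LC pairing.
#' @param V_inj_d1 First-dimension autosampler injection volume (uL).
#' @param reeq_time Second-dimension re-equilibration time (min) that must
#'   fit inside the sampling time together with the gradient.
#' @param n_max Plate-count cap for simulations.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(dwell_d1 = 13, dwell_d2 = 55,
                              ec_var_d1 = 0, ec_var_d2 = 3.8,
                              max_pressure_d1 = Inf, max_pressure_d2 = Inf,
                              temp_d1 = 30, temp_d2 = 60,
                              strong_d1 = "water", strong_d2 = "acn",
                              V_inj_d1 = 5, reeq_time = 0.1, n_max = 20000) {
  stopifnot(dwell_d1 >= 0, dwell_d2 >= 0, ec_var_d1 >= 0, ec_var_d2 >= 0,
            V_inj_d1 > 0, reeq_time >= 0, n_max >= 10,
            strong_d1 %in% c("water", "acn"), strong_d2 %in% c("water", "acn"))
  structure(list(dwell_d1 = dwell_d1, dwell_d2 = dwell_d2,
                 ec_var_d1 = ec_var_d1, ec_var_d2 = ec_var_d2,
                 max_pressure_d1 = max_pressure_d1,
                 max_pressure_d2 = max_pressure_d2,
                 temp_d1 = temp_d1, temp_d2 = temp_d2,
                 strong_d1 = strong_d1, strong_d2 = strong_d2,
                 V_inj_d1 = V_inj_d1, reeq_time = reeq_time, n_max = n_max),
            class = "instrument_config")
}

#' One candidate LC x LC method
#'
#' @param d1_column,d2_column [lc_column()]s.
#' @param d1_gradient,d2_gradient [gradient_program()]s (their `flow`
#'   fields are the dimension flows).
#' @param modulation A [modulation_settings()].
#' @param instrument An [instrument_config()].
#' @return An object of class `experimental_config`.
#' @export
experimental_config <- function(d1_column, d1_gradient,
                                d2_column, d2_gradient,
                                modulation, instrument = instrument_config()) {
  stopifnot(inherits(d1_column, "lc_column"), inherits(d2_column, "lc_column"),
            inherits(d1_gradient, "gradient_program"),
            inherits(d2_gradient, "gradient_program"),
            inherits(modulation, "modulation_settings"),
            inherits(instrument, "instrument_config"))
  structure(list(d1_column = d1_column, d1_gradient = d1_gradient,
                 d2_column = d2_column, d2_gradient = d2_gradient,
                 modulation = modulation, instrument = instrument),
            class = "experimental_config")
}

#' @export
print.experimental_config <- function(x, ...) {
  cat(sprintf(
    "LC x LC method: 1D %.3g uL/min (%.3g-%.3g in %.3g min), 2D %.3g uL/min (%.3g-%.3g in %.3g min)\n",
    x$d1_gradient$flow, x$d1_gradient$phi_init, x$d1_gradient$phi_final,
    x$d1_gradient$t_grad,
    x$d2_gradient$flow, x$d2_gradient$phi_init, x$d2_gradient$phi_final,
    x$d2_gradient$t_grad))
  cat(sprintf("  ts %.3g min, make-up %.3g uL/min, loop %.3g uL\n",
              x$modulation$sampling_time, x$modulation$makeup_flow,
              x$modulation$loop_volume))
  invisible(x)
}

#' Candidate parameter ranges for optimization
#'
#' Candidate value lists whose Cartesian product defines the set of
#' experimental configurations considered.
#'
#' @param f1,f2 Candidate flow rates (uL/min) for the two dimensions.
#' @param ts Candidate sampling times (min).
#' @param fmu Candidate make-up flows (uL/min).
#' @param loop Candidate loop volumes (uL).
#' @param d1_gradients,d2_gradients Lists of `list(phi_init, phi_final,
#'   t_grad)` candidates. A second-dimension `t_grad` of `NA` means
#'   "fill the sampling time": `t_grad = ts - reeq_time`.
#' @param makeup_composition Strong-solvent fraction of the make-up
#'   solvent (2D convention).
#' @return An object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(f1, f2, ts, fmu, loop,
                             d1_gradients, d2_gradients,
                             makeup_composition = 0) {
  stopifnot(length(f1) > 0, length(f2) > 0, length(ts) > 0,
            length(fmu) > 0, length(loop) > 0,
            length(d1_gradients) > 0, length(d2_gradients) > 0,
            all(f1 > 0), all(f2 > 0), all(ts > 0), all(fmu >= 0),
            all(loop > 0))
  structure(list(f1 = f1, f2 = f2, ts = ts, fmu = fmu, loop = loop,
                 d1_gradients = d1_gradients, d2_gradients = d2_gradients,
                 makeup_composition = makeup_composition),
            class = "parameter_ranges")
}

# worst-case viscosity over a gradient's composition span, in the
# dimension's own strong-solvent convention
worst_viscosity <- function(phi_lo, phi_hi, strong, temperature) {
  phis <- seq(min(phi_lo, phi_hi), max(phi_lo, phi_hi), length.out = 21)
  phi_acn <- if (strong == "acn") phis else 1 - phis
  max(solvent_viscosity(phi_acn, temperature))
}

#' Enumerate feasible experimental configurations
#'
#' Builds the full Cartesian product of the candidate lists in `ranges` and
#' keeps the configurations satisfying all instrument restrictions:
#' pressure feasibility in both dimensions (Darcy's law at the worst-case
#' mobile-phase viscosity over the gradient), loop capacity
#' `(F1 + Fmu) * ts <= loop`, and second-dimension cycle feasibility
#' `t_grad2 + reeq_time <= ts`.
#'
#' @param ranges A [parameter_ranges()].
#' @param d1_column,d2_column Fixed [lc_column()]s.
#' @param instrument An [instrument_config()].
#' @return A list of [experimental_config()]s, with an attribute
#'   `exclusions` counting configurations removed per constraint. An empty
#'   feasible set is an error naming the binding constraints.
#' @export
enumerate_feasible_configs <- function(ranges, d1_column, d2_column,
                                       instrument = instrument_config()) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  grid <- expand.grid(i_f1 = seq_along(ranges$f1),
                      i_f2 = seq_along(ranges$f2),
                      i_ts = seq_along(ranges$ts),
                      i_fmu = seq_along(ranges$fmu),
                      i_loop = seq_along(ranges$loop),
                      i_g1 = seq_along(ranges$d1_gradients),
                      i_g2 = seq_along(ranges$d2_gradients))
  excl <- c(loop = 0L, cycle = 0L, pressure_d1 = 0L, pressure_d2 = 0L)
  out <- vector("list", nrow(grid))
  n_ok <- 0L
  for (r in seq_len(nrow(grid))) {
    f1 <- ranges$f1[grid$i_f1[r]]; f2 <- ranges$f2[grid$i_f2[r]]
    ts <- ranges$ts[grid$i_ts[r]]; fmu <- ranges$fmu[grid$i_fmu[r]]
    loop <- ranges$loop[grid$i_loop[r]]
    g1 <- ranges$d1_gradients[[grid$i_g1[r]]]
    g2 <- ranges$d2_gradients[[grid$i_g2[r]]]
    t_grad2 <- if (is.na(g2$t_grad)) ts - instrument$reeq_time else g2$t_grad
    if ((f1 + fmu) * ts > loop) { excl["loop"] <- excl["loop"] + 1L; next }
    if (t_grad2 <= 0 || t_grad2 + instrument$reeq_time > ts) {
      excl["cycle"] <- excl["cycle"] + 1L; next
    }
    eta1 <- worst_viscosity(g1$phi_init, g1$phi_final,
                            instrument$strong_d1, instrument$temp_d1)
    if (!pressure_feasible(d1_column, f1, eta1, instrument$max_pressure_d1)) {
      excl["pressure_d1"] <- excl["pressure_d1"] + 1L; next
    }
    eta2 <- worst_viscosity(g2$phi_init, g2$phi_final,
                            instrument$strong_d2, instrument$temp_d2)
    if (!pressure_feasible(d2_column, f2, eta2, instrument$max_pressure_d2)) {
      excl["pressure_d2"] <- excl["pressure_d2"] + 1L; next
    }
    cfg <- experimental_config(
      d1_column,
      gradient_program(g1$phi_init, g1$phi_final, g1$t_grad, f1,
                       dwell_volume = instrument$dwell_d1),
      d2_column,
      gradient_program(g2$phi_init, g2$phi_final, t_grad2, f2,
                       dwell_volume = instrument$dwell_d2),
      modulation_settings(ts, fmu, loop,
                          makeup_composition = ranges$makeup_composition),
      instrument)
    n_ok <- n_ok + 1L
    out[[n_ok]] <- cfg
  }
  out <- out[seq_len(n_ok)]
  if (n_ok == 0L)
    stop("no feasible configuration; exclusions: ",
         paste(names(excl), excl, sep = " = ", collapse = ", "),
         call. = FALSE)
  attr(out, "exclusions") <- excl
  out
}
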