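#' Modulation settings
#'
#' The interface between the two dimensions: every `sampling_time` minutes
#' the first-dimension effluent (optionally blended with a make-up flow that
#' weakens the sample solvent) collected in a loop is injected onto the
#' second-dimension column.
#'
#' @param sampling_time Modulation period ts (min).
#' @param makeup_flow Make-up flow (uL/min), non-negative.
#' @param loop_volume Sample loop volume (uL).
#' @param makeup_composition Strong-solvent fraction of the make-up solvent
#'   in the second dimension's convention (0 = pure weak solvent, the usual
#'   aqueous make-up for HILIC x RP-LC).
#' @param valve_mode `"counter-current"` (default) or `"co-current"`.
#' @return An object of class `modulation_settings`.
#' @export
modulation_settings <- function(sampling_time, makeup_flow = 0, loop_volume,
                                makeup_composition = 0,
                                valve_mode = c("counter-current", "co-current")) {
  valve_mode <- match.arg(valve_mode)
  stopifnot(sampling_time > 0, makeup_flow >= 0, loop_volume > 0,
            makeup_composition >= 0, makeup_composition <= 1)
  structure(list(sampling_time = as.numeric(sampling_time),
                 makeup_flow = as.numeric(makeup_flow),
                 loop_volume = as.numeric(loop_volume),
                 makeup_composition = as.numeric(makeup_composition),
                 valve_mode = valve_mode),
            class = "modulation_settings")
}

#' Injection-process variance
#'
#' Variance of the sample plug caused by the injection process:
#' \deqn{\sigma_v^2 = \frac{V_{inj}^2}{\delta_{inj}^2}
#'       \left(\frac{1 + k_e}{1 + k_{ss}}\right)^2}
#' where `k_ss` is the analyte's retention factor in the sample solvent
#' (large for a weak sample solvent, giving on-column focusing) and `k_e`
#' the local retention factor at the column exit at elution. The default
#' `delta_sq = 8` corresponds to a plug-like injection; the time variance is
#' `sigma_v^2 / F^2`.
#'
#' An alternative variance expression can be plugged in via `variance_fn`,
#' which receives `(V_inj, F, delta_sq, k_e, k_ss)` and must return the
#' volume variance in uL^2.
#'
#' @param V_inj Injected volume (uL).
#' @param F Flow rate (uL/min).
#' @param k_e Local retention factor at column exit at elution.
#' @param k_ss Retention factor in the sample solvent.
#' @param delta_sq Injection-process parameter, default 8.
#' @param variance_fn Optional replacement for the volume-variance formula.
#' @return List with `sigma_v_sq` (uL^2) and `sigma_t_sq` (min^2).
#' @examples
#' injection_variance(V_inj = 10, F = 2000, k_e = 1, k_ss = 1)  # 12.5 uL^2
#' @export
injection_variance <- function(V_inj, F, k_e, k_ss, delta_sq = 8,
                               variance_fn = NULL) {
  stopifnot(V_inj >= 0, F > 0, delta_sq > 0, k_e >= 0, k_ss >= 0)
  sigma_v_sq <- if (is.null(variance_fn)) {
    (V_inj^2 / delta_sq) * ((1 + k_e) / (1 + k_ss))^2
  } else {
    variance_fn(V_inj, F, delta_sq, k_e, k_ss)
  }
  list(sigma_v_sq = sigma_v_sq, sigma_t_sq = sigma_v_sq / F^2)
}

#' Sample-solvent composition after transfer and make-up dilution
#'
#' Converts the first-dimension effluent composition into the second
#' dimension's strong-solvent convention and blends it with the make-up
#' flow. For mismatched mode pairs such as HILIC x RP-LC the strong solvent
#' of one dimension is the weak solvent of the other, so the
#' second-dimension strong fraction of the effluent is `1 - phi1`; the
#' loop content is then the volume-weighted mean with the make-up solvent:
#' \deqn{\phi_{ss} = \frac{F_1 (1-\phi_1) + F_{mu}\,\phi_{mu}}{F_1+F_{mu}}}
#'
#' @param phi1 First-dimension strong-solvent fraction of the effluent at
#'   transfer.
#' @param F1 First-dimension flow (uL/min).
#' @param Fmu Make-up flow (uL/min), non-negative.
#' @param makeup_composition Make-up solvent strong-fraction (2D convention).
#' @param invert Whether the two dimensions' strong solvents are opposite
#'   (default `TRUE`, the HILIC x RP-LC case). With `FALSE` the effluent
#'   fraction is used as-is.
#' @return Sample-solvent strong fraction in the second dimension.
#' @export
sample_solvent_composition <- function(phi1, F1, Fmu = 0,
                                       makeup_composition = 0, invert = TRUE) {
  stopifnot(F1 > 0, Fmu >= 0, phi1 >= 0, phi1 <= 1)
  eff <- if (invert) 1 - phi1 else phi1
  (F1 * eff + Fmu * makeup_composition) / (F1 + Fmu)
}

#' Modulation geometry
#'
#' Volumes collected per modulation cycle and the loop fill fraction.
#'
#' @param F1 First-dimension flow (uL/min).
#' @param Fmu Make-up flow (uL/min).
#' @param ts Sampling time (min).
#' @param loop_volume Loop volume (uL).
#' @return List with `eluent_fraction` (uL of 1D effluent per cycle),
#'   `total_fraction` (uL including make-up) and `fill_fraction`.
#'   A fill fraction above 1 (loop overflow) is an error.
#' @examples
#' modulation_geometry(F1 = 17, Fmu = 68, ts = 0.75, loop_volume = 80)
#' @export
modulation_geometry <- function(F1, Fmu, ts, loop_volume) {
  stopifnot(F1 > 0, Fmu >= 0, ts > 0, loop_volume > 0)
  eluent <- F1 * ts
  total <- (F1 + Fmu) * ts
  fill <- total / loop_volume
  if (fill > 1)
    stop(sprintf(
      "infeasible modulation: fraction volume %.4g uL exceeds loop volume %.4g uL",
      total, loop_volume), call. = FALSE)
  list(eluent_fraction = eluent, total_fraction = total, fill_fraction = fill)
}

#' Column band-broadening variance under gradient elution
#'
#' Plate-theory peak standard deviation
#' \eqn{\sigma = G\,t_0 (1 + k_e)/\sqrt{N}}, squared. The optional gradient
#' compression factor `G` in (0, 1] (default 1, i.e. off) scales the width;
#' a user-supplied correction can be applied by passing the factor directly.
#'
#' @param t0 Dead time (min).
#' @param N Plate count.
#' @param k_e Local retention factor at the column exit at elution.
#' @param G Gradient compression factor in (0, 1].
#' @return Time variance (min^2).
#' @export
column_variance_gradient <- function(t0, N, k_e, G = 1) {
  stopifnot(t0 > 0, N >= 1, k_e >= 0, G > 0, G <= 1)
  (G * t0 * (1 + k_e) / sqrt(N))^2
}

#' Total peak variance
#'
#' Additive combination of independent variance contributions (column,
#' injection, extra-column), all in the same (time or volume) units.
#'
#' @param ... Non-negative variance contributions.
#' @return Their sum.
#' @export
total_peak_variance <- function(...) {
  v <- c(...)
  stopifnot(all(v >= 0))
  sum(v)
}

#' First-dimension undersampling factor
#'
#' The effective broadening of first-dimension peaks caused by periodic
#' sampling: \eqn{\beta = \sqrt{1 + 0.21\,(t_s/\sigma_1)^2}}. The corrected
#' first-dimension peak capacity is `n1c / beta`.
#'
#' @param ts Sampling time (min).
#' @param sigma1 Mean first-dimension peak standard deviation (min).
#' @return Undersampling factor beta, at least 1.
#' @export
undersampling_factor <- function(ts, sigma1) {
  stopifnot(ts > 0, sigma1 > 0)
  sqrt(1 + 0.21 * (ts / sigma1)^2)
}

#' Peak capacity of one dimension
#'
#' \eqn{n_c = 1 + (t_{last} - t_{first})/(4\,\bar\sigma)}, with the window
#' ending at the predicted retention time of the last-eluting analyte
#' rather than at the programmed gradient end.
#'
#' @param t_first,t_last Window limits (min), `t_last >= t_first`.
#' @param mean_sigma Mean peak standard deviation in the window (min).
#' @return Peak capacity (at least 1).
#' @export
dimension_peak_capacity <- function(t_first, t_last, mean_sigma) {
  stopifnot(t_last >= t_first, mean_sigma > 0)
  1 + (t_last - t_first) / (4 * mean_sigma)
}

#' Two-dimensional peak capacity
#'
#' Product of the undersampling-corrected first-dimension and the
#' second-dimension peak capacities (full-coverage assumption; retention
#' space coverage/orthogonality descriptors are not applied).
#'
#' @param n1c_corrected Corrected first-dimension peak capacity.
#' @param n2c Second-dimension peak capacity.
#' @return `n1c_corrected * n2c`.
#' @export
two_dimensional_peak_capacity <- function(n1c_corrected, n2c) {
  stopifnot(n1c_corrected >= 1, n2c >= 1)
  n1c_corrected * n2c
}

#' Dilution factor of a peak in one dimension
#'
#' Peak-maximum dilution of a Gaussian peak relative to the injected plug:
#' \eqn{DF = \sqrt{2\pi}\,\sigma_v / V_{inj}} with the total peak standard
#' deviation in volume units.
#'
#' @param sigma_v Total peak standard deviation (uL).
#' @param V_inj Injected volume (uL).
#' @return Fold dilution.
#' @export
dilution_factor_dimension <- function(sigma_v, V_inj) {
  stopifnot(sigma_v >= 0, V_inj > 0)
  sqrt(2 * pi) * sigma_v / V_inj
}

#' Make-up flow dilution factor
#'
#' @param F1 First-dimension flow (uL/min).
#' @param Fmu Make-up flow (uL/min).
#' @return `(F1 + Fmu) / F1`.
#' @export
dilution_factor_makeup <- function(F1, Fmu) {
  stopifnot(F1 > 0, Fmu >= 0)
  (F1 + Fmu) / F1
}
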