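# Shared first-dimension evaluation and transfer bookkeeping used by both
# the theoretical and the simulated config evaluators. The first dimension
# is always evaluated theoretically (the autosampler injection is small and
# matched; only the second-dimension injection suffers solvent mismatch).
eval_d1_and_transfer <- function(config, a) {
  ins <- config$instrument
  mod <- config$modulation
  g1 <- config$d1_gradient
  st1 <- column_state(config$d1_column, g1$flow, a$vd_d1, ins$n_max)
  r1 <- predict_gradient_retention(a$model_d1, g1, st1$t0)
  if (!r1$eluted) return(list(eluted = FALSE))
  s1_sq <- total_peak_variance(
    column_variance_gradient(st1$t0, st1$N, r1$k_e),
    ins$ec_var_d1 / g1$flow^2)
  geom <- modulation_geometry(g1$flow, mod$makeup_flow, mod$sampling_time,
                              mod$loop_volume)
  phi1_exit <- composition_at_inlet(g1, max(r1$tR - st1$t0, 0))
  phi_ss <- sample_solvent_composition(
    phi1_exit, g1$flow, mod$makeup_flow, mod$makeup_composition,
    invert = config$instrument$strong_d1 != config$instrument$strong_d2)
  list(eluted = TRUE, st1 = st1, tR1 = r1$tR, k_e1 = r1$k_e,
       sigma1 = sqrt(s1_sq), fraction = floor(r1$tR / mod$sampling_time),
       V_inj = geom$total_fraction, fill = geom$fill_fraction,
       phi1 = phi1_exit, phi_ss = phi_ss)
}

assemble_metrics <- function(config, detail) {
  mod <- config$modulation
  g1 <- config$d1_gradient
  d <- detail[detail$eluted, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no analyte elutes in both dimensions under this configuration",
         call. = FALSE)
  t01 <- d$t01[1]; t02 <- d$t02[1]
  mean_s1 <- mean(d$sigma1); mean_s2 <- mean(d$sigma2)
  n1c <- dimension_peak_capacity(t01, max(d$tR1), mean_s1)
  beta <- undersampling_factor(mod$sampling_time, mean_s1)
  n1c_corr <- n1c / beta
  t_last2 <- min(mod$sampling_time, max(d$tR2))
  n2c <- dimension_peak_capacity(t02, max(t_last2, t02), mean_s2)
  nc2d <- two_dimensional_peak_capacity(max(n1c_corr, 1), max(n2c, 1))
  df_mu <- dilution_factor_makeup(g1$flow, mod$makeup_flow)
  df <- mean(
    dilution_factor_dimension(d$sigma1 * g1$flow, config$instrument$V_inj_d1) *
    df_mu *
    dilution_factor_dimension(d$sigma2 * config$d2_gradient$flow, d$V_inj))
  list(n1c_corrected = n1c_corr, n2c = n2c, nc_2d = nc2d,
       analysis_time = max(d$tR1) + mod$sampling_time,
       dilution_total = df, undersampling = beta)
}

#' Theoretical evaluation of one configuration
#'
#' Predicts, for every analyte, the first-dimension retention time and peak
#' width, the transfer (fraction containing the apex, injected volume,
#' sample-solvent composition after make-up dilution), and the
#' second-dimension retention time and width with the injection-variance
#' contribution; then assembles the three Pareto objectives
#' (two-dimensional peak capacity with undersampling and last-peak window
#' corrections, analysis time, total dilution factor).
#'
#' Analytes not eluting within the horizon in either dimension are flagged
#' and excluded from the averages, with a warning.
#'
#' @param config An [experimental_config()].
#' @param analytes A list of [analyte()]s.
#' @return An object of class `pareto_point`: `config`, `metrics`,
#'   `evaluation = "theoretical"`, `detail` (one row per analyte).
#' @export
evaluate_config_theoretical <- function(config, analytes) {
  stopifnot(inherits(config, "experimental_config"), length(analytes) > 0)
  ins <- config$instrument
  g2 <- config$d2_gradient
  rows <- lapply(analytes, function(a) {
    d1 <- eval_d1_and_transfer(config, a)
    if (!d1$eluted) return(unattained_row(a))
    st2 <- column_state(config$d2_column, g2$flow, a$vd_d2, ins$n_max)
    r2 <- predict_gradient_retention(a$model_d2, g2, st2$t0)
    if (!r2$eluted) return(unattained_row(a))
    k_ss <- safe_k(a$model_d2, d1$phi_ss)
    inj <- injection_variance(d1$V_inj, g2$flow, r2$k_e, k_ss)
    s2_sq <- total_peak_variance(
      column_variance_gradient(st2$t0, st2$N, r2$k_e),
      inj$sigma_t_sq, ins$ec_var_d2 / g2$flow^2)
    data.frame(name = a$name, eluted = TRUE, tR1 = d1$tR1,
               sigma1 = d1$sigma1, fraction = d1$fraction,
               V_inj = d1$V_inj, phi_ss = d1$phi_ss, k_ss = k_ss,
               tR2 = r2$tR, k_e2 = r2$k_e, sigma2 = sqrt(s2_sq),
               split = FALSE, t01 = d1$st1$t0, t02 = st2$t0,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, rows)
  if (any(!detail$eluted))
    warning("analyte(s) not eluting excluded from averages: ",
            paste(detail$name[!detail$eluted], collapse = ", "),
            call. = FALSE)
  structure(list(config = config,
                 metrics = assemble_metrics(config, detail),
                 evaluation = "theoretical", detail = detail),
            class = "pareto_point")
}

unattained_row <- function(a) {
  data.frame(name = a$name, eluted = FALSE, tR1 = NA_real_,
             sigma1 = NA_real_, fraction = NA_real_, V_inj = NA_real_,
             phi_ss = NA_real_, k_ss = NA_real_, tR2 = NA_real_,
             k_e2 = NA_real_, sigma2 = NA_real_, split = NA,
             t01 = NA_real_, t02 = NA_real_, stringsAsFactors = FALSE)
}

#' Simulation-based evaluation of one configuration
#'
#' As [evaluate_config_theoretical()], but the second-dimension retention
#' time and peak width of every analyte are measured from a Craig
#' counter-current elution-profile simulation of the transferred fraction
#' ([simulate_elution()]) instead of from the theoretical plate and
#' injection-variance relations. The apex gives the retention time; the
#' second-moment standard deviation (which remains meaningful for
#' distorted peaks) enters the peak-capacity and dilution metrics, and
#' split peaks are flagged. Post-column extra-column variance is added to
#' the simulated variance.
#'
#' @param config An [experimental_config()].
#' @param analytes A list of [analyte()]s.
#' @param keep_profiles Keep the simulated `elution_profile`s (for
#'   chromatogram construction). Default `FALSE`.
#' @return A `pareto_point` with `evaluation = "simulated"` (and
#'   `profiles` when requested).
#' @export
evaluate_config_simulated <- function(config, analytes, keep_profiles = FALSE) {
  stopifnot(inherits(config, "experimental_config"), length(analytes) > 0)
  ins <- config$instrument
  g2 <- config$d2_gradient
  mod <- config$modulation
  profiles <- list()
  rows <- lapply(analytes, function(a) {
    d1 <- eval_d1_and_transfer(config, a)
    if (!d1$eluted) return(unattained_row(a))
    st2 <- column_state(config$d2_column, g2$flow, a$vd_d2, ins$n_max)
    ip <- make_injection_profile(mod$loop_volume, d1$fill, g2$flow,
                                 sample_solvent = d1$phi_ss,
                                 mobile_phase_init = composition_at_inlet(g2, 0))
    prof <- simulate_elution(a$model_d2, st2, g2, ip)
    if (!prof$complete && prof$eluted_mass < 0.5 * prof$injected_mass)
      return(unattained_row(a))
    mom <- profile_moments(prof)
    if (keep_profiles) profiles[[a$name]] <<- prof
    k_ss <- safe_k(a$model_d2, d1$phi_ss)
    s2_sq <- total_peak_variance(mom$sigma_moment^2,
                                 ins$ec_var_d2 / g2$flow^2)
    data.frame(name = a$name, eluted = TRUE, tR1 = d1$tR1,
               sigma1 = d1$sigma1, fraction = d1$fraction,
               V_inj = d1$V_inj, phi_ss = d1$phi_ss, k_ss = k_ss,
               tR2 = mom$t_apex,
               k_e2 = local_k_at_elution(a$model_d2, g2,
                                         max(mom$t_apex, st2$t0), st2$t0),
               sigma2 = sqrt(s2_sq), split = mom$n_maxima >= 2,
               t01 = d1$st1$t0, t02 = st2$t0, stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, rows)
  if (any(!detail$eluted))
    warning("analyte(s) not eluting excluded from averages: ",
            paste(detail$name[!detail$eluted], collapse = ", "),
            call. = FALSE)
  out <- structure(list(config = config,
                        metrics = assemble_metrics(config, detail),
                        evaluation = "simulated", detail = detail),
                   class = "pareto_point")
  if (keep_profiles) out$profiles <- profiles
  out
}

#' @export
print.pareto_point <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Pareto point (%s): nc_2D = %.1f (1D %.1f x 2D %.1f), time %.1f min, dilution %.2f\n",
    x$evaluation, m$nc_2d, m$n1c_corrected, m$n2c, m$analysis_time,
    m$dilution_total))
  invisible(x)
}
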