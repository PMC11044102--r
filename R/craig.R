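#' Simulate an elution profile with the Craig counter-current model
#'
#' Propagates an analyte through the column as a series of pseudo
#' counter-current distributions on a discrete grid of `N` cells (one per
#' theoretical plate) with one transfer per time step `t0 / N`. Each step
#' shifts the mobile-phase contents (analyte and solvent plug) one cell
#' toward the outlet -- the inlet being fed from the injection profile and
#' then from the dwell-delayed gradient program -- and re-equilibrates each
#' cell so that the mobile fraction is `1/(1 + k(phi_cell))`. The mass
#' leaving the final cell per step is the elution profile.
#'
#' Because the solvent plug propagates with the mobile phase, the model
#' captures injection band broadening under sample-solvent mismatch and
#' volume overload, including breakthrough and split peaks: analyte riding
#' in a strong sample plug migrates nearly unretained until it falls out of
#' the plug. The simulation is fully deterministic.
#'
#' @param model The analyte's second-dimension [retention_model()].
#' @param state A [column_state()] (provides `N` and `t0`).
#' @param gradient The second-dimension [gradient_program()].
#' @param injection An `injection_profile` (see [make_injection_profile()]).
#' @param horizon Simulation time limit (min); default
#'   `10 * (t_grad + t0 + dwell + hold)`. If the analyte has not fully
#'   eluted at the horizon, a partial profile is returned with a warning
#'   and `complete = FALSE`.
#' @param stop_frac Stop once the in-column mass falls below this fraction
#'   of the injected mass (default 1e-9).
#' @return An object of class `elution_profile`: `time` (min), `flux`
#'   (mass/min), `mass` per step, `dt`, `eluted_mass`, `complete`,
#'   `max_mass_err` (largest relative mass-balance error over all steps),
#'   `N`, `t0`.
#' @export
simulate_elution <- function(model, state, gradient, injection,
                             horizon = NULL, stop_frac = 1e-9) {
  stopifnot(inherits(model, "retention_model"),
            inherits(state, "column_state"),
            inherits(gradient, "gradient_program"),
            inherits(injection, "injection_profile"))
  N <- as.integer(round(state$N))
  if (N < 10) stop("Craig simulation needs at least 10 plates", call. = FALSE)
  t0 <- state$t0
  dt <- t0 / N
  if (is.null(horizon)) horizon <- elution_horizon(gradient, t0)
  max_steps <- as.integer(ceiling(horizon / dt))

  inj <- resample_injection(injection, dt)
  n_inj <- length(inj$mass)
  if (n_inj > max_steps)
    stop("injection longer than the simulation horizon", call. = FALSE)

  # inlet composition per step: injection solvent track, then the gradient
  tt <- (seq_len(max_steps) - 1L) * dt
  phi_in <- composition_at_inlet(gradient, tt)
  phi_in[seq_len(n_inj)] <- inj$phi
  k_in <- safe_k(model, phi_in)
  p_in <- 1 / (1 + k_in)
  p0 <- 1 / (1 + safe_k(model, composition_at_inlet(gradient, 0)))

  res <- .craig_core(N, inj$mass, p_in, p0, max_steps, stop_frac, FALSE)
  steps <- res$steps
  complete <- res$in_column <= max(stop_frac, 1e-6) * res$injected
  if (!complete)
    warning(sprintf(
      "analyte not fully eluted within horizon (%.3g of mass still in column)",
      res$in_column / res$injected), call. = FALSE)

  structure(list(time = seq_len(steps) * dt, flux = res$outflux / dt,
                 mass = res$outflux, dt = dt,
                 eluted_mass = res$eluted, injected_mass = res$injected,
                 in_column = res$in_column, complete = complete,
                 max_mass_err = res$max_mass_err,
                 N = N, t0 = t0),
            class = "elution_profile")
}

# retention factor with the adsorption phi = 0 divergence floored; used by
# the simulator and the evaluators, where phi = 0 can legitimately occur in
# a solvent track.
safe_k <- function(model, phi) {
  if (model$kind == "adsorption") phi <- pmax(phi, 1e-6)
  retention_factor(model, phi)
}

#' @export
print.elution_profile <- function(x, ...) {
  m <- profile_moments(x)
  cat(sprintf(
    "Elution profile: N = %d, apex %.4g min, sigma(moment) %.4g min, %d maxima%s\n",
    x$N, m$t_apex, m$sigma_moment, m$n_maxima,
    if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

#' @export
plot.elution_profile <- function(x, ...) {
  graphics::plot(x$time, x$flux, type = "l", xlab = "time (min)",
                 ylab = "mass flux (1/min)", ...)
  invisible(x)
}

#' Moments and width descriptors of an elution profile
#'
#' Computes the apex time, first moment, the standard deviation from the
#' second central moment, the standard deviation from the width at 50%
#' height (`width / 2.3548`, crossings located by linear interpolation
#' around the global apex), and the number of detected maxima.
#'
#' For distorted or split peaks the two width measures diverge: the
#' half-height width sees only the tallest feature, while the second moment
#' integrates all eluted mass.
#'
#' @param profile An `elution_profile` (or any list with `time`, `flux`,
#'   `mass`).
#' @return An object of class `profile_moments`: `t_apex`, `t_mean`,
#'   `sigma_moment`, `sigma_halfheight`, `n_maxima` (all times in min).
#' @export
profile_moments <- function(profile) {
  t <- profile$time
  m <- profile$mass
  f <- profile$flux
  tot <- sum(m)
  if (tot <= 0) stop("all-zero profile", call. = FALSE)
  i_apex <- which.max(f)
  t_apex <- t[i_apex]
  t_mean <- sum(m * t) / tot
  sigma_moment <- sqrt(sum(m * (t - t_mean)^2) / tot)

  # half-height width around the global apex
  half <- f[i_apex] / 2
  left <- NA_real_; right <- NA_real_
  if (i_apex > 1) {
    below <- which(f[seq_len(i_apex - 1)] < half)
    if (length(below)) {
      i <- max(below)
      left <- t[i] + (half - f[i]) / (f[i + 1] - f[i]) * (t[i + 1] - t[i])
    }
  }
  if (i_apex < length(f)) {
    below <- which(f[seq(i_apex + 1, length(f))] < half) + i_apex
    if (length(below)) {
      i <- min(below)
      right <- t[i - 1] + (half - f[i - 1]) / (f[i] - f[i - 1]) * (t[i] - t[i - 1])
    }
  }
  width <- right - left
  sigma_hh <- if (is.na(width)) NA_real_ else width / (2 * sqrt(2 * log(2)))

  structure(list(t_apex = t_apex, t_mean = t_mean,
                 sigma_moment = sigma_moment, sigma_halfheight = sigma_hh,
                 n_maxima = detect_peak_splitting(profile)),
            class = "profile_moments")
}

#' @export
print.profile_moments <- function(x, ...) {
  cat(sprintf(
    "apex %.4g min, mean %.4g min, sigma: %.4g (moment) / %.4g (half-height) min, %d maxima\n",
    x$t_apex, x$t_mean, x$sigma_moment, x$sigma_halfheight, x$n_maxima))
  invisible(x)
}

#' Count resolved maxima of an elution profile (split-peak detection)
#'
#' Local maxima of the flux trace are retained when they exceed
#' `prominence` of the global maximum and adjacent retained maxima are
#' separated by a valley no higher than `valley_ratio` of the lower of the
#' two; otherwise the lower maximum is discarded. A count of 2 or more
#' flags a split or breakthrough peak.
#'
#' @param profile An `elution_profile`.
#' @param prominence Minimum height relative to the global maximum,
#'   in (0, 1). Default 0.05.
#' @param valley_ratio Maximum valley height relative to the lower adjacent
#'   peak for the two to count as separate. Default 0.8.
#' @return Number of retained maxima (at least 1 for a non-zero profile).
#' @export
detect_peak_splitting <- function(profile, prominence = 0.05,
                                  valley_ratio = 0.8) {
  stopifnot(prominence > 0, prominence < 1)
  f <- profile$flux
  n <- length(f)
  if (n < 3 || max(f) <= 0) return(as.integer(max(f) > 0))
  d <- diff(f)
  # local maxima: rising then falling (plateaus collapse onto their start)
  s <- sign(d)
  s_nz <- s
  for (i in seq(2, length(s_nz))) if (s_nz[i] == 0) s_nz[i] <- s_nz[i - 1]
  cand <- which(diff(s_nz) < 0 & s_nz[-length(s_nz)] > 0) + 1L
  if (length(cand) == 0) cand <- which.max(f)
  cand <- cand[f[cand] >= prominence * max(f)]
  if (length(cand) <= 1) return(max(1L, length(cand)))
  cand <- cand[order(f[cand], decreasing = TRUE)]
  kept <- cand[1]
  for (i in cand[-1]) {
    ok <- TRUE
    for (k in kept) {
      valley <- min(f[seq(min(i, k), max(i, k))])
      if (valley > valley_ratio * min(f[i], f[k])) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  length(kept)
}

#' Export an elution profile to CSV
#'
#' Two-column CSV (`time_min`, `mass_flux`).
#'
#' @param profile An `elution_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_profile <- function(profile, path) {
  utils::write.csv(data.frame(time_min = profile$time,
                              mass_flux = profile$flux),
                   path, row.names = FALSE)
  invisible(path)
}
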