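#' Parameterised modulation-valve injection profile
#'
#' Models the band delivered to the second-dimension column when the sample
#' loop is flushed. In the counter-current valve configuration the loop is
#' flushed in reverse, so for partial fills the loop-resident mobile phase
#' elutes first, followed by the sample plug of volume
#' `fill_fraction * loop_volume`. Exponential dispersion with volume
#' constant `tail_constant` (default `0.15 * loop_volume`, a tunable
#' modelling choice, not a measured value) is applied at both plug
#' interfaces, reproducing the asymmetric profiles of real modulation
#' valves. The solvent track carries the sample-solvent composition during
#' the plug and the mobile-phase composition elsewhere.
#'
#' A measured valve profile can be used instead via
#' [injection_profile_from_table()].
#'
#' @param loop_volume Loop volume (uL).
#' @param fill_fraction Filled fraction of the loop, in (0, 1].
#' @param flow Second-dimension flow rate (uL/min).
#' @param sample_solvent Strong-solvent fraction of the loop content (2D
#'   convention).
#' @param mobile_phase_init Strong-solvent fraction of the mobile phase at
#'   injection.
#' @param tail_constant Exponential dispersion volume constant (uL).
#' @param n_grid Number of uniform time steps of the internal grid.
#' @return An object of class `injection_profile`: uniform time grid
#'   (`time`, left edges, min; step `dt`), `mass` per step (sums to 1) and
#'   `phi` per step.
#' @examples
#' ip <- make_injection_profile(loop_volume = 80, fill_fraction = 0.8,
#'                              flow = 2000, sample_solvent = 0.17,
#'                              mobile_phase_init = 0.01)
#' sum(ip$mass)  # 1
#' @export
make_injection_profile <- function(loop_volume, fill_fraction, flow,
                                   sample_solvent, mobile_phase_init,
                                   tail_constant = 0.15 * loop_volume,
                                   n_grid = 4000) {
  stopifnot(loop_volume > 0, fill_fraction > 0, flow > 0,
            tail_constant >= 0, n_grid >= 10)
  if (fill_fraction > 1)
    stop("fill_fraction must not exceed 1", call. = FALSE)
  stopifnot(sample_solvent >= 0, sample_solvent <= 1,
            mobile_phase_init >= 0, mobile_phase_init <= 1)

  t_loop <- loop_volume / flow                    # min to flush the loop
  a <- (1 - fill_fraction) * t_loop               # mobile phase precedes plug
  b <- t_loop                                     # plug ends with the loop
  tau <- tail_constant / flow                     # time constant
  t_end <- b + if (tau > 0) 10 * tau else 0
  dt <- t_end / n_grid
  t <- seq(0, by = dt, length.out = n_grid)       # left edges
  tm <- t + dt / 2                                # midpoints

  estep <- function(x) ifelse(x < 0, 0, if (tau > 0) 1 - exp(-x / tau) else 1)
  ind <- estep(tm - a) - estep(tm - b)            # smeared plug indicator
  mass <- ind / sum(ind)                          # exact unit mass
  phi <- mobile_phase_init + (sample_solvent - mobile_phase_init) *
    pmin(pmax(ind, 0), 1)

  structure(list(time = t, dt = dt, mass = mass, phi = phi,
                 loop_volume = loop_volume, fill_fraction = fill_fraction,
                 flow = flow, sample_solvent = sample_solvent,
                 mobile_phase_init = mobile_phase_init,
                 tail_constant = tail_constant),
            class = "injection_profile")
}

#' Injection profile from a measured valve table
#'
#' Builds an [make_injection_profile()]-compatible object from a measured
#' two- or three-column table (`time_min`, `relative_concentration`, and
#' optionally `phi_ss`). The concentration track is normalised to unit
#' mass; a missing solvent track defaults to the constant `sample_solvent`.
#'
#' @param table A data frame with columns `time_min`,
#'   `relative_concentration` and optionally `phi_ss`.
#' @param sample_solvent Constant solvent composition used when the table
#'   has no `phi_ss` column.
#' @return An `injection_profile`.
#' @export
injection_profile_from_table <- function(table, sample_solvent = NULL) {
  stopifnot(is.data.frame(table),
            all(c("time_min", "relative_concentration") %in% names(table)))
  tt <- table$time_min
  cc <- table$relative_concentration
  if (any(cc < 0)) stop("relative concentration must be non-negative",
                        call. = FALSE)
  n <- length(tt)
  stopifnot(n >= 2)
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("measured profile must be on a uniform time grid", call. = FALSE)
  dt <- dt[1]
  mass <- cc / sum(cc)
  phi <- if ("phi_ss" %in% names(table)) table$phi_ss
         else {
           if (is.null(sample_solvent))
             stop("sample_solvent required when table has no phi_ss column",
                  call. = FALSE)
           rep(sample_solvent, n)
         }
  structure(list(time = tt - tt[1], dt = dt, mass = mass, phi = phi,
                 loop_volume = NA_real_, fill_fraction = NA_real_,
                 flow = NA_real_, sample_solvent = sample_solvent,
                 mobile_phase_init = NA_real_, tail_constant = NA_real_),
            class = "injection_profile")
}

#' @export
print.injection_profile <- function(x, ...) {
  cat(sprintf(
    "Injection profile: %d steps of %.3g min, duration %.4g min, mass %.6f\n",
    length(x$mass), x$dt, length(x$mass) * x$dt, sum(x$mass)))
  invisible(x)
}

# Mass-preserving resampling of an injection profile onto a new uniform
# step. Mass per new bin is the difference of the linearly interpolated
# cumulative mass at the bin edges; the solvent track is the mass-weighted
# mean composition of the bin (nearest-bin composition where a bin holds no
# mass).
resample_injection <- function(profile, dt_new) {
  stopifnot(inherits(profile, "injection_profile"), dt_new > 0)
  edges_old <- c(profile$time, profile$time[length(profile$time)] + profile$dt)
  cum_mass <- c(0, cumsum(profile$mass))
  cum_mphi <- c(0, cumsum(profile$mass * profile$phi))
  t_end <- edges_old[length(edges_old)]
  n_new <- ceiling(t_end / dt_new)
  edges_new <- seq(0, by = dt_new, length.out = n_new + 1L)
  cm <- stats::approx(edges_old, cum_mass, xout = pmin(edges_new, t_end),
                      rule = 2)$y
  cp <- stats::approx(edges_old, cum_mphi, xout = pmin(edges_new, t_end),
                      rule = 2)$y
  mass <- diff(cm)
  mphi <- diff(cp)
  phi <- ifelse(mass > 0, mphi / pmax(mass, .Machine$double.xmin), NA_real_)
  # fill composition of empty bins from the nearest non-empty neighbour
  if (anyNA(phi)) {
    idx <- seq_along(phi)
    ok <- !is.na(phi)
    if (!any(ok)) stop("empty injection profile", call. = FALSE)
    phi <- stats::approx(idx[ok], phi[ok], xout = idx, rule = 2,
                         method = "constant", f = 0)$y
  }
  mass <- mass / sum(mass)
  list(mass = mass, phi = pmin(pmax(phi, 0), 1), dt = dt_new)
}
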