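#' Linear gradient program
#'
#' Describes a linear solvent gradient delivered by the pump: composition
#' ramps from `phi_init` to `phi_final` over `t_grad` minutes, after an
#' optional initial isocratic hold, and is held at `phi_final` indefinitely
#' afterwards. The programmed composition reaches the column inlet delayed
#' by the dwell time `dwell_volume / flow`.
#'
#' @param phi_init,phi_final Strong-solvent fractions at gradient start/end,
#'   in `[0, 1]`.
#' @param t_grad Gradient time (min), positive.
#' @param flow Flow rate (uL/min), positive.
#' @param dwell_volume Pre-column dwell volume (uL), non-negative.
#' @param hold_init Initial isocratic hold at `phi_init` (min), default 0.
#' @return An object of class `gradient_program`.
#' @examples
#' g <- gradient_program(0.01, 0.25, t_grad = 55, flow = 17, dwell_volume = 13)
#' composition_at_inlet(g, c(0, 30, 60))
#' @export
gradient_program <- function(phi_init, phi_final, t_grad, flow,
                             dwell_volume = 0, hold_init = 0) {
  stopifnot(phi_init >= 0, phi_init <= 1, phi_final >= 0, phi_final <= 1,
            t_grad > 0, flow > 0, dwell_volume >= 0, hold_init >= 0)
  structure(list(phi_init = as.numeric(phi_init),
                 phi_final = as.numeric(phi_final),
                 t_grad = as.numeric(t_grad), flow = as.numeric(flow),
                 dwell_volume = as.numeric(dwell_volume),
                 hold_init = as.numeric(hold_init)),
            class = "gradient_program")
}

#' @export
print.gradient_program <- function(x, ...) {
  cat(sprintf(
    "Gradient: %.3g-%.3g in %.3g min at %.3g uL/min (dwell %.3g uL, hold %.3g min)\n",
    x$phi_init, x$phi_final, x$t_grad, x$flow, x$dwell_volume, x$hold_init))
  invisible(x)
}

#' Mobile-phase composition at the column inlet
#'
#' The programmed composition delayed by the dwell time and any initial
#' hold: `phi_init` until `dwell_volume/flow + hold_init`, then a linear
#' ramp over `t_grad` minutes, then `phi_final`. Vectorised over `t`.
#'
#' @param gradient A [gradient_program()].
#' @param t Time(s) since injection (min), non-negative.
#' @return Strong-solvent fraction(s) at the inlet.
#' @export
composition_at_inlet <- function(gradient, t) {
  stopifnot(inherits(gradient, "gradient_program"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  delay <- gradient$dwell_volume / gradient$flow + gradient$hold_init
  frac <- pmin(pmax((t - delay) / gradient$t_grad, 0), 1)
  gradient$phi_init + frac * (gradient$phi_final - gradient$phi_init)
}

# Horizon beyond which an analyte is reported as not eluted.
elution_horizon <- function(gradient, t0) {
  10 * (gradient$t_grad + t0 + gradient$dwell_volume / gradient$flow +
          gradient$hold_init)
}

#' Predict gradient-elution retention time
#'
#' Solves the general gradient-elution relation
#' \deqn{\int_0^{t_R - t_0} \frac{dt}{t_0\,k(\phi_{inlet}(t))} = 1}
#' for the retention time `tR` by adaptive trapezoid quadrature of the
#' cumulative migration integral with bisection on the crossing, refining
#' the step until the located retention time is stable to `tol_tR`. When
#' the gradient is flat this reduces to the isocratic result
#' `tR = t0 * (1 + k)`.
#'
#' Composition seen by the migrating band is approximated by the inlet
#' composition (dwell-delayed); after the programmed ramp the composition is
#' held at `phi_final`, so late eluters leave under the final isocratic
#' condition. If the migration integral does not reach 1 within `horizon`
#' minutes the analyte is reported as not eluted rather than clipped.
#'
#' @param model A [retention_model()].
#' @param gradient A [gradient_program()].
#' @param t0 Column dead time (min), positive.
#' @param horizon Time limit (min); default `10 * (t_grad + t0 + dwell +
#'   hold)`.
#' @param tol_tR Convergence tolerance on tR (min).
#' @return A list with `tR` (min, `NA` if not eluted), `eluted` (logical),
#'   and `k_e`, the local retention factor at the column exit at elution.
#' @examples
#' m <- retention_model("lss", k0 = 100, S = 10)
#' g <- gradient_program(0, 1, t_grad = 10, flow = 1000)
#' predict_gradient_retention(m, g, t0 = 1)
#' @export
predict_gradient_retention <- function(model, gradient, t0,
                                       horizon = NULL, tol_tR = 1e-4) {
  stopifnot(inherits(model, "retention_model"),
            inherits(gradient, "gradient_program"), t0 > 0)
  if (is.null(horizon)) horizon <- elution_horizon(gradient, t0)

  # adsorption law: floor composition to avoid the phi = 0 divergence when a
  # program legitimately starts at phi = 0 (k is then effectively infinite).
  kfun <- function(t) {
    phi <- composition_at_inlet(gradient, t)
    if (model$kind == "adsorption") phi <- pmax(phi, 1e-6)
    retention_factor(model, phi)
  }

  # migration speed (integrand) 1 / (t0 * k); k = Inf -> 0 speed
  speed <- function(t) {
    k <- kfun(t)
    ifelse(is.finite(k) & k > 0, 1 / (t0 * k), ifelse(k == 0, Inf, 0))
  }

  # unretained (k == 0 at start): elutes with the dead time
  if (kfun(0) == 0) {
    return(list(tR = t0, eluted = TRUE, k_e = 0))
  }

  # composition-independent k (flat program, or S = 0 / n = 0): the
  # migration integral is linear in t and the isocratic closed form is exact
  flat_model <- (model$kind == "lss" && model$S == 0) ||
    (model$kind == "adsorption" && model$n == 0)
  if (flat_model || gradient$phi_init == gradient$phi_final) {
    k <- kfun(0)
    tR <- t0 * (1 + k)
    if (tR > horizon + t0)
      return(list(tR = NA_real_, eluted = FALSE, k_e = NA_real_))
    return(list(tR = tR, eluted = TRUE, k_e = k))
  }

  solve_at <- function(n_step) {
    tt <- seq(0, horizon, length.out = n_step + 1L)
    sp <- speed(tt)
    if (any(!is.finite(sp))) sp[!is.finite(sp)] <- 0
    dt <- tt[2] - tt[1]
    cum <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * dt))
    if (cum[length(cum)] < 1) return(NA_real_)
    i <- which(cum >= 1)[1]
    # bisection within [tt[i-1], tt[i]] on the trapezoid-interpolated integral
    lo <- tt[i - 1]; hi <- tt[i]; base <- cum[i - 1]; slo <- sp[i - 1]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      val <- base + (slo + speed(mid)) / 2 * (mid - lo)
      if (val < 1) { base <- val; lo <- mid; slo <- speed(mid) } else hi <- mid
      if (hi - lo < tol_tR / 16) break
    }
    (lo + hi) / 2
  }

  n <- 512L
  prev <- solve_at(n)
  repeat {
    n <- n * 2L
    cur <- solve_at(n)
    if (is.na(prev) && is.na(cur)) {
      return(list(tR = NA_real_, eluted = FALSE, k_e = NA_real_))
    }
    if (!is.na(prev) && !is.na(cur) && abs(cur - prev) < tol_tR) break
    prev <- cur
    if (n > 2^20) break
  }
  tR <- cur + t0
  k_e <- local_k_at_elution(model, gradient, tR, t0)
  list(tR = tR, eluted = TRUE, k_e = k_e)
}

#' Local retention factor at the column exit at elution
#'
#' Evaluates the retention law at the mobile-phase composition present at
#' the column exit when the analyte elutes at `tR`: the inlet composition at
#' time `tR - t0`, since unretained solvent needs one dead time to traverse
#' the column.
#'
#' @param model A [retention_model()].
#' @param gradient A [gradient_program()].
#' @param tR Retention time (min), at least `t0`.
#' @param t0 Column dead time (min).
#' @return Local retention factor `k_e`.
#' @export
local_k_at_elution <- function(model, gradient, tR, t0) {
  stopifnot(tR >= t0)
  phi <- composition_at_inlet(gradient, tR - t0)
  if (model$kind == "adsorption") phi <- max(phi, 1e-6)
  retention_factor(model, phi)
}
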