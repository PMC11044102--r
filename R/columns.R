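#' Column description
#'
#' Geometry and packing properties of an LC column.
#'
#' @param length Column length (mm).
#' @param id Internal diameter (mm).
#' @param dp Particle size (um).
#' @param porosity Total porosity (dimensionless, in (0, 1)).
#' @param flow_resistance Dimensionless flow-resistance factor in Darcy's
#'   law (typically 500-1000 for packed beds).
#' @param max_pressure Maximum operating pressure (bar).
#' @return An object of class `lc_column`.
#' @examples
#' lc_column(length = 50, id = 3.0, dp = 1.8, porosity = 0.55,
#'           flow_resistance = 700, max_pressure = 1200)
#' @export
lc_column <- function(length, id, dp, porosity = 0.55,
                      flow_resistance = 700, max_pressure = 600) {
  stopifnot(length > 0, id > 0, dp > 0,
            porosity > 0, porosity < 1, flow_resistance > 0, max_pressure > 0)
  structure(list(length = as.numeric(length), id = as.numeric(id),
                 dp = as.numeric(dp), porosity = as.numeric(porosity),
                 flow_resistance = as.numeric(flow_resistance),
                 max_pressure = as.numeric(max_pressure)),
            class = "lc_column")
}

#' @export
print.lc_column <- function(x, ...) {
  cat(sprintf("Column %g x %g mm, dp %g um (porosity %.2f, max %g bar)\n",
              x$length, x$id, x$dp, x$porosity, x$max_pressure))
  invisible(x)
}

#' Hydrodynamic and efficiency state of a column at a given flow
#'
#' Derives void volume, dead time, chromatographic linear velocity and plate
#' count for a column operated at a flow rate.
#'
#' `V0 = porosity * pi * (id/2)^2 * length` (uL for mm inputs),
#' `t0 = V0 / flow`, `u = length / t0` (converted to mm/s), and
#' `N = plate_count(curve, u, length)` from the analyte's van Deemter curve.
#'
#' @param column An [lc_column()].
#' @param flow Flow rate (uL/min).
#' @param curve A [van_deemter()] curve used for the plate count.
#' @param n_max Plate-count cap (the Craig simulator cost grows with N^2);
#'   a warning is issued when the cap binds. Default 20000.
#' @return An object of class `column_state` with `N`, `t0` (min), `V0`
#'   (uL), `u` (mm/s), plus the column and flow.
#' @export
column_state <- function(column, flow, curve, n_max = 20000) {
  stopifnot(inherits(column, "lc_column"), flow > 0)
  V0 <- column$porosity * pi * (column$id / 2)^2 * column$length
  t0 <- V0 / flow
  u <- column$length / (t0 * 60)           # mm/s
  N <- plate_count(curve, u, column$length)
  if (N > n_max) {
    warning(sprintf("plate count %.0f capped at %d", N, n_max), call. = FALSE)
    N <- n_max
  }
  structure(list(N = N, t0 = t0, V0 = V0, u = u,
                 column = column, flow = flow),
            class = "column_state")
}

#' @export
print.column_state <- function(x, ...) {
  cat(sprintf("Column state: N = %.0f, t0 = %.4g min, V0 = %.4g uL, u = %.3g mm/s\n",
              x$N, x$t0, x$V0, x$u))
  invisible(x)
}

# Default viscosity table for water/acetonitrile mixtures (mPa s).
# Columns: phi_acn, eta at 30 C, eta at 60 C. Values interpolated linearly;
# users may supply their own table of the same shape.
.default_viscosity_table <- data.frame(
  phi_acn = seq(0, 1, by = 0.1),
  eta_30  = c(0.80, 0.89, 0.92, 0.90, 0.82, 0.72, 0.61, 0.51, 0.43, 0.37, 0.33),
  eta_60  = c(0.47, 0.53, 0.56, 0.55, 0.51, 0.45, 0.39, 0.33, 0.28, 0.25, 0.22)
)

#' Mobile-phase viscosity by interpolation
#'
#' Linear interpolation of a viscosity table eta(phi_ACN, T). The shipped
#' default covers water/acetonitrile at 30 and 60 degrees C; temperatures
#' between the two table columns are interpolated linearly, values outside
#' are clamped to the nearest column.
#'
#' @param phi_acn Acetonitrile volume fraction(s) in `[0, 1]`.
#' @param temperature Temperature (C), default 30.
#' @param table Optional replacement table with columns `phi_acn`,
#'   `eta_30`, `eta_60`.
#' @return Viscosity in mPa s.
#' @export
solvent_viscosity <- function(phi_acn, temperature = 30,
                              table = .default_viscosity_table) {
  stopifnot(all(phi_acn >= 0 & phi_acn <= 1))
  e30 <- stats::approx(table$phi_acn, table$eta_30, xout = phi_acn)$y
  e60 <- stats::approx(table$phi_acn, table$eta_60, xout = phi_acn)$y
  w <- min(max((temperature - 30) / 30, 0), 1)
  (1 - w) * e30 + w * e60
}

#' Column pressure drop (Darcy's law)
#'
#' \eqn{\Delta P = \phi_{res}\,\eta\,L\,u / d_p^2}, evaluated in SI and
#' reported in bar. With the package's units (eta mPa s, L mm, u mm/s, dp
#' um) the conversion factor is 1e-2:
#' `dP_bar = flow_resistance * eta * L * u / dp^2 / 100`.
#'
#' @param column An [lc_column()].
#' @param flow Flow rate (uL/min).
#' @param viscosity Mobile-phase viscosity (mPa s).
#' @return Pressure drop in bar.
#' @examples
#' col <- lc_column(50, 3.0, 1.8, porosity = 0.55)
#' pressure_drop(col, flow = 2000, viscosity = 0.5)
#' @export
pressure_drop <- function(column, flow, viscosity) {
  stopifnot(inherits(column, "lc_column"), flow > 0, viscosity > 0)
  V0 <- column$porosity * pi * (column$id / 2)^2 * column$length
  u <- column$length / (V0 / flow) / 60    # mm/s
  column$flow_resistance * viscosity * column$length * u / column$dp^2 / 100
}

#' Pressure feasibility of a column at a flow rate
#'
#' @param column An [lc_column()].
#' @param flow Flow rate (uL/min).
#' @param viscosity Worst-case mobile-phase viscosity over the gradient
#'   (mPa s).
#' @param instrument_max Instrument pressure limit (bar), default `Inf`.
#' @return `TRUE` when the Darcy pressure drop is within both the column
#'   and instrument limits.
#' @export
pressure_feasible <- function(column, flow, viscosity, instrument_max = Inf) {
  dp <- pressure_drop(column, flow, viscosity)
  dp <= column$max_pressure && dp <= instrument_max
}
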