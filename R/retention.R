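#' Retention models for gradient elution
#'
#' Construct a retention model describing how an analyte's retention factor
#' depends on the volume fraction `phi` of the dimension's strong eluting
#' solvent. Two laws are supported:
#'
#' * **Linear solvent strength (LSS)**, the usual law for reversed-phase LC:
#'   \eqn{k(\phi) = k_0 e^{-S\phi}}, where `k0` is the extrapolated retention
#'   factor in pure weak solvent and `S` the (dimensionless) slope of
#'   \eqn{\ln k} versus \eqn{\phi}.
#' * **Adsorption**, the usual law for HILIC:
#'   \eqn{k(\phi) = k_{100}\,\phi^{-n}}, where `k100` is the retention factor
#'   in pure strong solvent and `n` the number of strong-solvent molecules
#'   displaced by the solute.
#'
#' @param kind `"lss"` or `"adsorption"`.
#' @param k0,S LSS parameters (`k0 > 0`, `S >= 0`). Only for `kind = "lss"`.
#' @param k100,n Adsorption parameters (`k100 > 0`, `n >= 0`). Only for
#'   `kind = "adsorption"`.
#' @return An object of class `retention_model`.
#' @examples
#' rp <- retention_model("lss", k0 = 100, S = 10)
#' retention_factor(rp, 0.3)            # 100 * exp(-3)
#' hilic <- retention_model("adsorption", k100 = 0.5, n = 2)
#' retention_factor(hilic, 1)           # 0.5
#' @export
retention_model <- function(kind = c("lss", "adsorption"),
                            k0 = NULL, S = NULL, k100 = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (kind == "lss") {
    if (is.null(k0) || is.null(S))
      stop("lss model requires k0 and S", call. = FALSE)
    stopifnot(k0 > 0, S >= 0)
    m <- list(kind = "lss", k0 = as.numeric(k0), S = as.numeric(S))
  } else {
    if (is.null(k100) || is.null(n))
      stop("adsorption model requires k100 and n", call. = FALSE)
    stopifnot(k100 > 0, n >= 0)
    m <- list(kind = "adsorption", k100 = as.numeric(k100), n = as.numeric(n))
  }
  class(m) <- "retention_model"
  m
}

#' @export
print.retention_model <- function(x, ...) {
  if (x$kind == "lss")
    cat(sprintf("Retention model: LSS  k(phi) = %.4g * exp(-%.4g * phi)\n",
                x$k0, x$S))
  else
    cat(sprintf("Retention model: adsorption  k(phi) = %.4g * phi^-%.4g\n",
                x$k100, x$n))
  invisible(x)
}

#' Retention factor at a given solvent composition
#'
#' Evaluates the retention law of a [retention_model()] at strong-solvent
#' fraction `phi`. Vectorised over `phi`.
#'
#' @param model A `retention_model`.
#' @param phi Strong-solvent volume fraction(s) in `[0, 1]`. The adsorption
#'   law diverges at `phi = 0`, which is an error.
#' @return Retention factor(s), strictly positive.
#' @export
retention_factor <- function(model, phi) {
  stopifnot(inherits(model, "retention_model"))
  if (any(phi < 0 | phi > 1))
    stop("phi must lie in [0, 1]", call. = FALSE)
  if (model$kind == "lss") {
    model$k0 * exp(-model$S * phi)
  } else {
    if (any(phi == 0))
      stop("adsorption retention diverges at phi = 0", call. = FALSE)
    model$k100 * phi^(-model$n)
  }
}

#' Van Deemter plate-height curve
#'
#' Plate height as a function of mobile-phase linear velocity,
#' \eqn{H(u) = a + b/u + c\,u}, with `H` in micrometres and `u` in mm/s.
#'
#' @param a Plate-height offset (um).
#' @param b Longitudinal diffusion term (um mm/s).
#' @param c Mass-transfer term (um s/mm).
#' @return An object of class `van_deemter`.
#' @export
van_deemter <- function(a, b, c) {
  stopifnot(a >= 0, b >= 0, c >= 0, a + b + c > 0)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
            class = "van_deemter")
}

#' Plate height at a linear velocity
#'
#' @param curve A [van_deemter()] curve.
#' @param u Linear velocity (mm/s), positive.
#' @return Plate height in um.
#' @export
plate_height <- function(curve, u) {
  stopifnot(inherits(curve, "van_deemter"))
  if (any(u <= 0)) stop("linear velocity must be positive", call. = FALSE)
  curve$a + curve$b / u + curve$c * u
}

#' Column plate count from a van Deemter curve
#'
#' `N = L / H(u)`, with the column length in mm and the plate height in um.
#'
#' @param curve A [van_deemter()] curve.
#' @param u Linear velocity (mm/s), positive.
#' @param length Column length (mm), positive.
#' @return Plate count (dimensionless, at least 1).
#' @examples
#' plate_count(van_deemter(2, 0, 0), u = 1, length = 50)  # 25000
#' @export
plate_count <- function(curve, u, length) {
  stopifnot(length > 0)
  H <- plate_height(curve, u)              # um
  max(1, length * 1000 / H)                # mm -> um
}

#' Analyte description
#'
#' Bundles the retention models and plate-height curves of one analyte in
#' both dimensions of an LC x LC separation.
#'
#' @param name Analyte label.
#' @param model_d1,model_d2 [retention_model()]s for the first and second
#'   dimension.
#' @param vd_d1,vd_d2 [van_deemter()] curves for the first and second
#'   dimension.
#' @return An object of class `analyte`.
#' @export
analyte <- function(name, model_d1, model_d2, vd_d1, vd_d2) {
  stopifnot(inherits(model_d1, "retention_model"),
            inherits(model_d2, "retention_model"),
            inherits(vd_d1, "van_deemter"),
            inherits(vd_d2, "van_deemter"))
  structure(list(name = as.character(name),
                 model_d1 = model_d1, model_d2 = model_d2,
                 vd_d1 = vd_d1, vd_d2 = vd_d2),
            class = "analyte")
}

#' Fit retention parameters from multi-gradient experiments
#'
#' Recovers the two parameters of a retention law from retention times
#' observed under several linear gradients of different slope (the classic
#' multi-gradient calibration, with gradient times typically differing by a
#' factor of three between runs). The sum of squared residuals between
#' observed and predicted retention times is minimised with Nelder-Mead
#' simplex search, seeded from a coarse log-grid scan.
#'
#' @param observations A list of `list(gradient = , tR = )` pairs, where
#'   `gradient` is a [gradient_program()] and `tR` the observed retention
#'   time (min). At least two observations with distinct gradient slopes are
#'   required.
#' @param kind Retention law to fit, `"lss"` or `"adsorption"`.
#' @param t0 Column dead time (min).
#' @param grid_points Points per axis in the log-grid seeding scan.
#' @return An object of class `retention_fit` with elements `model` (the
#'   fitted [retention_model()]), `residuals` (min), `fitted`, `observed`,
#'   `rss`, `converged`.
#' @export
fit_retention_parameters <- function(observations,
                                     kind = c("lss", "adsorption"),
                                     t0, grid_points = 8) {
  kind <- match.arg(kind)
  stopifnot(t0 > 0)
  if (length(observations) < 2)
    stop("at least two gradient observations are required", call. = FALSE)
  slopes <- vapply(observations, function(o) {
    g <- o$gradient
    (g$phi_final - g$phi_init) / g$t_grad
  }, numeric(1))
  if (length(unique(signif(slopes, 10))) < 2)
    stop("observations must include at least two distinct gradient slopes",
         call. = FALSE)
  tR_obs <- vapply(observations, function(o) o$tR, numeric(1))

  make_model <- function(p) {
    if (kind == "lss") retention_model("lss", k0 = p[1], S = p[2])
    else retention_model("adsorption", k100 = p[1], n = p[2])
  }
  predict_all <- function(p) {
    m <- make_model(p)
    vapply(observations, function(o) {
      r <- predict_gradient_retention(m, o$gradient, t0)
      if (!r$eluted) return(NA_real_)
      r$tR
    }, numeric(1))
  }
  obj <- function(lp) {
    p <- exp(lp)
    pred <- try(predict_all(p), silent = TRUE)
    if (inherits(pred, "try-error") || anyNA(pred)) return(1e10)
    sum((pred - tR_obs)^2)
  }

  # coarse log-grid seeding: k-parameter and slope parameter
  kg <- if (kind == "lss") exp(seq(log(0.5), log(5000), length.out = grid_points))
        else exp(seq(log(0.01), log(100), length.out = grid_points))
  sg <- exp(seq(log(0.2), log(80), length.out = grid_points))
  grid <- expand.grid(p1 = kg, p2 = sg)
  vals <- apply(grid, 1, function(p) obj(log(as.numeric(p))))
  start <- log(as.numeric(grid[which.min(vals), ]))

  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- exp(opt$par)
  fitted <- predict_all(p)
  structure(list(model = make_model(p),
                 residuals = fitted - tR_obs,
                 fitted = fitted, observed = tR_obs,
                 rss = opt$value, converged = opt$convergence == 0,
                 kind = kind, t0 = t0),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat("Retention-parameter fit (", x$kind, ")\n", sep = "")
  print(x$model)
  cat(sprintf("RSS = %.4g min^2 over %d gradients; converged: %s\n",
              x$rss, length(x$observed), x$converged))
  invisible(x)
}

#' @export
coef.retention_fit <- function(object, ...) {
  m <- object$model
  if (m$kind == "lss") c(k0 = m$k0, S = m$S) else c(k100 = m$k100, n = m$n)
}

#' @export
residuals.retention_fit <- function(object, ...) object$residuals
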