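#' Slice a first-dimension peak into modulation fractions
#'
#' The mass shares of a Gaussian first-dimension peak collected into
#' consecutive sampling fractions `[i ts, (i+1) ts)`: Gaussian integrals
#' over the fraction windows. Fractions receiving less than `min_share` of
#' the mass are dropped and the remaining shares renormalised to 1 so that
#' mass is conserved through chromatogram assembly. When a gradient and
#' dead time are supplied, each fraction also carries the mean
#' strong-solvent fraction of the effluent at the column exit over the
#' fraction window.
#'
#' @param tR1 First-dimension retention time (min).
#' @param sigma1 First-dimension peak standard deviation (min).
#' @param ts Sampling time (min).
#' @param window Total first-dimension window considered (min); default
#'   covers `tR1 + 6 sigma1`.
#' @param gradient Optional first-dimension [gradient_program()].
#' @param t0 First-dimension dead time (min), required with `gradient`.
#' @param min_share Drop threshold, default 1e-4.
#' @return A data frame with `fraction` (0-based index), `share`, and
#'   `phi1_mean` (`NA` without a gradient).
#' @export
slice_first_dimension <- function(tR1, sigma1, ts, window = NULL,
                                  gradient = NULL, t0 = NULL,
                                  min_share = 1e-4) {
  stopifnot(sigma1 > 0, ts > 0, tR1 >= 0)
  if (is.null(window)) window <- tR1 + 6 * sigma1
  n_frac <- ceiling(window / ts)
  edges <- (0:n_frac) * ts
  shares <- stats::pnorm(edges[-1], tR1, sigma1) -
    stats::pnorm(edges[-length(edges)], tR1, sigma1)
  keep <- shares >= min_share
  if (!any(keep)) keep[which.max(shares)] <- TRUE
  frac <- which(keep) - 1L
  shares <- shares[keep] / sum(shares[keep])
  phi <- rep(NA_real_, length(frac))
  if (!is.null(gradient)) {
    stopifnot(!is.null(t0))
    phi <- vapply(frac, function(i) {
      tt <- seq(i * ts, (i + 1) * ts, length.out = 21)
      mean(composition_at_inlet(gradient, pmax(tt - t0, 0)))
    }, numeric(1))
  }
  data.frame(fraction = frac, share = shares, phi1_mean = phi)
}

#' Build a predicted two-dimensional chromatogram
#'
#' Assembles a retention-plane intensity grid from per-fraction simulated
#' second-dimension elution profiles. For every analyte the theoretical
#' first-dimension peak is sliced into modulation fractions
#' ([slice_first_dimension()]); each populated fraction is simulated in
#' the second dimension with the sample-solvent composition of that
#' fraction (mean effluent composition over the fraction window, blended
#' with the make-up flow), and the resulting profile, scaled by the
#' fraction's mass share, is placed at the fraction's first-dimension
#' coordinate (fraction midpoint). Intensities are summed over analytes;
#' per-analyte contributions are retained.
#'
#' @param config An [experimental_config()].
#' @param analytes A list of [analyte()]s.
#' @param n_t2 Number of second-dimension grid points, default 400.
#' @return An object of class `chromatogram_2d`: `t1` (fraction midpoints,
#'   min), `t2` (second-dimension grid, min), `intensity` (matrix
#'   `length(t2) x length(t1)`, cell mass units), `contributions` (named
#'   list of per-analyte matrices), `config`.
#' @export
build_2d_chromatogram <- function(config, analytes, n_t2 = 400) {
  stopifnot(inherits(config, "experimental_config"), length(analytes) > 0)
  ins <- config$instrument
  g1 <- config$d1_gradient
  g2 <- config$d2_gradient
  mod <- config$modulation
  ts <- mod$sampling_time
  t2 <- seq(0, ts, length.out = n_t2)
  dt2 <- t2[2] - t2[1]

  slices <- list()
  max_frac <- 0L
  for (a in analytes) {
    d1 <- eval_d1_and_transfer(config, a)
    if (!d1$eluted) {
      warning("analyte ", a$name, " does not elute in the first dimension",
              call. = FALSE)
      next
    }
    sl <- slice_first_dimension(d1$tR1, d1$sigma1, ts,
                                gradient = g1, t0 = d1$st1$t0)
    slices[[a$name]] <- list(analyte = a, d1 = d1, slices = sl)
    max_frac <- max(max_frac, max(sl$fraction))
  }
  if (length(slices) == 0) stop("no analyte elutes", call. = FALSE)
  n_frac <- max_frac + 1L
  t1 <- ((seq_len(n_frac) - 1L) + 0.5) * ts

  contributions <- list()
  for (nm in names(slices)) {
    s <- slices[[nm]]
    a <- s$analyte
    st2 <- column_state(config$d2_column, g2$flow, a$vd_d2, ins$n_max)
    m <- matrix(0, nrow = n_t2, ncol = n_frac)
    for (r in seq_len(nrow(s$slices))) {
      fr <- s$slices$fraction[r]
      share <- s$slices$share[r]
      phi_ss <- sample_solvent_composition(
        s$slices$phi1_mean[r], g1$flow, mod$makeup_flow,
        mod$makeup_composition,
        invert = ins$strong_d1 != ins$strong_d2)
      ip <- make_injection_profile(mod$loop_volume, s$d1$fill, g2$flow,
                                   sample_solvent = phi_ss,
                                   mobile_phase_init = composition_at_inlet(g2, 0))
      prof <- simulate_elution(a$model_d2, st2, g2, ip)
      if (is.null(prof))
        stop("missing simulation for analyte ", nm, " fraction ", fr,
             call. = FALSE)
      flux <- stats::approx(prof$time, prof$flux, xout = t2, rule = 2,
                            yleft = 0, yright = 0)$y
      cell_mass <- flux * dt2
      # later-eluting mass (beyond one cycle) folds into the column total so
      # that the per-analyte mass balance holds exactly
      tot <- sum(cell_mass)
      if (tot > 0) cell_mass <- cell_mass * (share / tot)
      m[, fr + 1L] <- m[, fr + 1L] + cell_mass
    }
    contributions[[nm]] <- m
  }
  intensity <- Reduce(`+`, contributions)
  structure(list(t1 = t1, t2 = t2, intensity = intensity,
                 contributions = contributions, config = config),
            class = "chromatogram_2d")
}

#' @export
print.chromatogram_2d <- function(x, ...) {
  cat(sprintf(
    "2D chromatogram: %d fractions x %d 2D points, %d analyte(s), total mass %.4f\n",
    ncol(x$intensity), nrow(x$intensity), length(x$contributions),
    sum(x$intensity)))
  invisible(x)
}

#' @export
plot.chromatogram_2d <- function(x, nlevels = 30, ...) {
  graphics::filled.contour(x$t1, x$t2, t(x$intensity),
                           nlevels = nlevels,
                           xlab = "1D time (min)", ylab = "2D time (min)",
                           ...)
  invisible(x)
}

#' Export a 2D chromatogram grid
#'
#' Writes a long-format CSV (`t1_min`, `t2_min`, `intensity`) and a dense
#' matrix CSV (rows = second-dimension grid, columns = fractions, first
#' column `t2_min`).
#'
#' @param chrom A `chromatogram_2d`.
#' @param path_long Path for the long-format CSV.
#' @param path_dense Path for the dense-matrix CSV (optional).
#' @return `path_long`, invisibly.
#' @export
export_grid <- function(chrom, path_long, path_dense = NULL) {
  stopifnot(inherits(chrom, "chromatogram_2d"))
  long <- data.frame(
    t1_min = rep(chrom$t1, each = length(chrom$t2)),
    t2_min = rep(chrom$t2, times = length(chrom$t1)),
    intensity = as.vector(chrom$intensity))
  utils::write.csv(long, path_long, row.names = FALSE)
  if (!is.null(path_dense)) {
    dense <- data.frame(t2_min = chrom$t2, chrom$intensity)
    names(dense) <- c("t2_min", sprintf("t1_%g", chrom$t1))
    utils::write.csv(dense, path_dense, row.names = FALSE)
  }
  invisible(path_long)
}
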