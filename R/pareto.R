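objective_matrix <- function(points) {
  t(vapply(points, function(p) c(nc_2d = p$metrics$nc_2d,
                                 analysis_time = p$metrics$analysis_time,
                                 dilution_total = p$metrics$dilution_total),
           numeric(3)))
}

#' Pareto front of evaluated configurations
#'
#' Removes all dominated points from a set of evaluated configurations.
#' The three objectives are: maximize the two-dimensional peak capacity,
#' minimize the analysis time, minimize the total dilution factor. A point
#' is dominated when another point is at least as good in every objective
#' and strictly better in at least one; points with identical objective
#' vectors are all retained. The front is returned ordered by analysis
#' time, then by decreasing peak capacity.
#'
#' @param points A list of `pareto_point`s (see
#'   [evaluate_config_theoretical()]).
#' @return An object of class `pareto_front`: the non-dominated sublist,
#'   with attribute `indices` giving the positions of the retained points
#'   in the input.
#' @export
pareto_front <- function(points) {
  stopifnot(length(points) >= 1)
  obj <- objective_matrix(points)
  # dominance in minimization orientation
  m <- cbind(-obj[, 1], obj[, 2], obj[, 3])
  n <- nrow(m)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    geq <- m[, 1] <= m[i, 1] & m[, 2] <= m[i, 2] & m[, 3] <= m[i, 3]
    strict <- m[, 1] < m[i, 1] | m[, 2] < m[i, 2] | m[, 3] < m[i, 3]
    dominated[i] <- any(geq & strict)
  }
  idx <- which(!dominated)
  ord <- order(obj[idx, 2], -obj[idx, 1])
  idx <- idx[ord]
  structure(points[idx], indices = idx, class = c("pareto_front", "list"))
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front with %d point(s):\n", length(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.pareto_front <- function(x, ...) {
  front_table(unclass(x))
}

# Table-1-like summary of a list of pareto points
front_table <- function(points) {
  do.call(rbind, lapply(points, function(p) {
    cfg <- p$config; m <- p$metrics
    data.frame(
      f1 = cfg$d1_gradient$flow, f2 = cfg$d2_gradient$flow,
      ts = cfg$modulation$sampling_time, fmu = cfg$modulation$makeup_flow,
      loop = cfg$modulation$loop_volume,
      t_grad1 = cfg$d1_gradient$t_grad, t_grad2 = cfg$d2_gradient$t_grad,
      eluent_fraction = cfg$d1_gradient$flow * cfg$modulation$sampling_time,
      n1c_corrected = m$n1c_corrected, n2c = m$n2c, nc_2d = m$nc_2d,
      analysis_time = m$analysis_time, dilution = m$dilution_total,
      evaluation = p$evaluation, stringsAsFactors = FALSE)
  }))
}

#' Export a Pareto front to CSV
#'
#' One row per front point with the configuration fields and metrics.
#'
#' @param front A `pareto_front` (or plain list of `pareto_point`s).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_front <- function(front, path) {
  utils::write.csv(front_table(front), path, row.names = FALSE)
  invisible(path)
}

#' Hybrid theoretical-then-simulated Pareto optimization
#'
#' The full simulation of every candidate configuration is computationally
#' prohibitive (one Craig simulation per plate per analyte per candidate),
#' so the optimizer proceeds in three stages:
#'
#' 1. every feasible configuration is evaluated with the fast theoretical
#'    relations and a preliminary Pareto front is constructed;
#' 2. only the configurations on the preliminary front are re-evaluated
#'    with the elution-profile simulator;
#' 3. a final Pareto front is constructed over the re-evaluated points.
#'
#' Configurations that looked optimal under the theoretical injection
#' model but are dominated once the simulator reveals additional injection
#' band broadening are removed at stage 3 and reported in `removed`.
#'
#' @param ranges A [parameter_ranges()].
#' @param analytes A list of [analyte()]s.
#' @param d1_column,d2_column Fixed [lc_column()]s.
#' @param instrument An [instrument_config()].
#' @return An object of class `hybrid_result`: `preliminary_front`
#'   (theoretical), `refined_front` (simulated), `simulated_points` (all
#'   stage-2 evaluations), `removed` (stage-1 front points dominated after
#'   re-evaluation), `comparison` (before/after metrics per stage-1 front
#'   point), `n_configs`, `n_simulations`.
#' @export
hybrid_optimize <- function(ranges, analytes, d1_column, d2_column,
                            instrument = instrument_config()) {
  configs <- enumerate_feasible_configs(ranges, d1_column, d2_column,
                                        instrument)
  theor <- lapply(configs, evaluate_config_theoretical, analytes = analytes)
  front1 <- pareto_front(theor)
  sim <- lapply(unclass(front1),
                function(p) evaluate_config_simulated(p$config, analytes))
  front3 <- pareto_front(sim)
  kept <- attr(front3, "indices")
  removed_idx <- setdiff(seq_along(sim), kept)
  comparison <- data.frame(
    front_point = seq_along(sim),
    nc_2d_theoretical = vapply(unclass(front1),
                               function(p) p$metrics$nc_2d, numeric(1)),
    nc_2d_simulated = vapply(sim, function(p) p$metrics$nc_2d, numeric(1)),
    dilution_theoretical = vapply(unclass(front1),
                                  function(p) p$metrics$dilution_total,
                                  numeric(1)),
    dilution_simulated = vapply(sim, function(p) p$metrics$dilution_total,
                                numeric(1)),
    removed = seq_along(sim) %in% removed_idx)
  structure(list(preliminary_front = front1, refined_front = front3,
                 simulated_points = sim, removed = sim[removed_idx],
                 comparison = comparison,
                 n_configs = length(configs),
                 n_simulations = length(sim) * length(analytes)),
            class = "hybrid_result")
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf(
    "Hybrid optimization: %d feasible configs -> preliminary front %d -> refined front %d (%d removed, %d simulations)\n",
    x$n_configs, length(x$preliminary_front), length(x$refined_front),
    length(x$removed), x$n_simulations))
  invisible(x)
}

#' Full-simulation Pareto optimization
#'
#' Evaluates every feasible configuration with the elution-profile
#' simulator and builds the Pareto front. Only practical for small grids;
#' serves as the reference against which [hybrid_optimize()] is judged.
#'
#' @inheritParams hybrid_optimize
#' @return A list with `front` (a `pareto_front`) and `points` (all
#'   simulated evaluations).
#' @export
full_sim_optimize <- function(ranges, analytes, d1_column, d2_column,
                              instrument = instrument_config()) {
  configs <- enumerate_feasible_configs(ranges, d1_column, d2_column,
                                        instrument)
  pts <- lapply(configs, evaluate_config_simulated, analytes = analytes)
  list(front = pareto_front(pts), points = pts)
}
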