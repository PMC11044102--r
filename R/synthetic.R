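#' Synthetic analyte sets
#'
#' Draws analyte parameter tables with the structure of a typical
#' HILIC x RP-LC calibration: an adsorption-law first dimension (HILIC,
#' `k100` and `n`) and an LSS second dimension (RP-LC, `k0` and `S`),
#' each with its own van Deemter curve. All parameters are drawn
#' log-uniformly within the requested ranges; a seed makes the draw
#' reproducible. The defaults emulate small polar metabolites such as
#' phenolic compounds on sub-2-um columns: second-dimension retention
#' spanning weakly retained (injection-sensitive) to well retained, and
#' plate heights of a few particle diameters.
#'
#' @param n_analytes Number of analytes.
#' @param seed Random seed fixing the draw.
#' @param ranges Named list of `c(lo, hi)` ranges for `k100`, `n_ads`
#'   (adsorption exponent), `k0`, `S`, `vd_a` (um), `vd_b` (um mm/s),
#'   `vd_c` (um s/mm). Missing entries fall back to the defaults.
#' @return A list of [analyte()]s (empty for `n_analytes = 0`).
#' @examples
#' as <- generate_synthetic_analytes(3, seed = 1)
#' as[[1]]$model_d2
#' @export
generate_synthetic_analytes <- function(n_analytes, seed,
                                        ranges = list()) {
  stopifnot(n_analytes >= 0)
  def <- list(k100 = c(0.05, 0.6), n_ads = c(0.5, 2),
              k0 = c(5, 500), S = c(10, 40),
              vd_a = c(2, 4), vd_b = c(2, 8), vd_c = c(0.3, 1.5))
  for (nm in names(ranges)) def[[nm]] <- ranges[[nm]]
  stopifnot(all(vapply(def, function(r) all(r > 0) && r[2] >= r[1],
                       logical(1))))
  if (n_analytes == 0) return(list())
  set.seed(seed)
  runif_log <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  draw <- function(nm, n) runif_log(n, def[[nm]])
  lapply(seq_len(n_analytes), function(i) {
    analyte(
      name = sprintf("syn%02d", i),
      model_d1 = retention_model("adsorption",
                                 k100 = draw("k100", 1), n = draw("n_ads", 1)),
      model_d2 = retention_model("lss", k0 = draw("k0", 1), S = draw("S", 1)),
      vd_d1 = van_deemter(draw("vd_a", 1), draw("vd_b", 1), draw("vd_c", 1)),
      vd_d2 = van_deemter(draw("vd_a", 1), draw("vd_b", 1), draw("vd_c", 1)))
  })
}

.analyte_columns <- c("name", "d1_kind", "d1_p1", "d1_p2",
                      "d1_vd_a", "d1_vd_b", "d1_vd_c",
                      "d2_kind", "d2_p1", "d2_p2",
                      "d2_vd_a", "d2_vd_b", "d2_vd_c")

#' Write an analyte table to CSV
#'
#' One row per analyte with the schema `name, d1_kind, d1_p1, d1_p2,
#' d1_vd_a, d1_vd_b, d1_vd_c, d2_kind, d2_p1, d2_p2, d2_vd_a, d2_vd_b,
#' d2_vd_c`. For `kind = "lss"` the parameters are `(k0, S)`; for
#' `kind = "adsorption"` they are `(k100, n)`. Van Deemter coefficients
#' are in um, um mm/s and um s/mm. A header comment documents the units.
#'
#' @param analytes A list of [analyte()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analytes <- function(analytes, path) {
  rows <- lapply(analytes, function(a) {
    p <- function(m) if (m$kind == "lss") c(m$k0, m$S) else c(m$k100, m$n)
    d1 <- p(a$model_d1); d2 <- p(a$model_d2)
    data.frame(name = a$name,
               d1_kind = a$model_d1$kind, d1_p1 = d1[1], d1_p2 = d1[2],
               d1_vd_a = a$vd_d1$a, d1_vd_b = a$vd_d1$b, d1_vd_c = a$vd_d1$c,
               d2_kind = a$model_d2$kind, d2_p1 = d2[1], d2_p2 = d2[2],
               d2_vd_a = a$vd_d2$a, d2_vd_b = a$vd_d2$b, d2_vd_c = a$vd_d2$c,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
         else as.data.frame(stats::setNames(
           rep(list(character(0)), length(.analyte_columns)),
           .analyte_columns))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# analyte parameter table",
    "# kinds: lss (p1 = k0, p2 = S) | adsorption (p1 = k100, p2 = n)",
    "# van Deemter: a (um), b (um mm/s), c (um s/mm)"), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Load an analyte table from CSV
#'
#' Reads and validates a CSV written in the [write_analytes()] schema.
#' Unknown columns are rejected; malformed rows raise errors naming the
#' row and field.
#'
#' @param path Input file path.
#' @return A list of [analyte()]s.
#' @export
load_analytes <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  unknown <- setdiff(names(tab), .analyte_columns)
  if (length(unknown))
    stop("unknown column(s) in analyte table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(.analyte_columns, names(tab))
  if (length(missing))
    stop("missing column(s) in analyte table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    mk_model <- function(kind, p1, p2, dim) {
      if (!kind %in% c("lss", "adsorption"))
        stop(sprintf("row %d, %s_kind: unknown retention law '%s'",
                     i, dim, kind), call. = FALSE)
      for (nm in c("p1", "p2")) {
        v <- if (nm == "p1") p1 else p2
        if (!is.finite(v) || v <= 0)
          stop(sprintf("row %d, %s_%s: must be a positive number", i, dim, nm),
               call. = FALSE)
      }
      if (kind == "lss") retention_model("lss", k0 = p1, S = p2)
      else retention_model("adsorption", k100 = p1, n = p2)
    }
    mk_vd <- function(a, b, c, dim) {
      for (nm in c("a", "b", "c")) {
        v <- get(nm)
        if (!is.finite(v) || v < 0)
          stop(sprintf("row %d, %s_vd_%s: must be a non-negative number",
                       i, dim, nm), call. = FALSE)
      }
      van_deemter(a, b, c)
    }
    analyte(row$name,
            mk_model(row$d1_kind, row$d1_p1, row$d1_p2, "d1"),
            mk_model(row$d2_kind, row$d2_p1, row$d2_p2, "d2"),
            mk_vd(row$d1_vd_a, row$d1_vd_b, row$d1_vd_c, "d1"),
            mk_vd(row$d2_vd_a, row$d2_vd_b, row$d2_vd_c, "d2"))
  })
}

#' Load an optimization configuration from YAML
#'
#' Reads a structured configuration file with three blocks:
#'
#' * `instrument`: fields of [instrument_config()] (all optional);
#' * `columns`: `d1` and `d2`, each with the fields of [lc_column()];
#' * `ranges`: candidate lists `f1`, `f2`, `ts`, `fmu`, `loop` (plus
#'   optional `makeup_composition`) and gradient candidate blocks
#'   `d1_gradients` / `d2_gradients`, each a list of
#'   `{phi_init, phi_final, t_grad}` (a second-dimension `t_grad` of
#'   `.na` or `null` means "fill the sampling time").
#'
#' Second-dimension flows may be given in mL/min under `f2_ml_min` and are
#' converted to uL/min on input.
#'
#' @param path YAML file path.
#' @return A list with `instrument` ([instrument_config()]), `d1_column`,
#'   `d2_column` ([lc_column()]s) and `ranges` ([parameter_ranges()]).
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (blk in c("instrument", "columns", "ranges")) {
    if (is.null(y[[blk]]))
      stop("config is missing the '", blk, "' block", call. = FALSE)
  }
  instrument <- do.call(instrument_config, y$instrument)
  mk_col <- function(b, nm) {
    if (is.null(b)) stop("columns block is missing '", nm, "'", call. = FALSE)
    do.call(lc_column, b)
  }
  d1_column <- mk_col(y$columns$d1, "d1")
  d2_column <- mk_col(y$columns$d2, "d2")
  r <- y$ranges
  if (!is.null(r$f2_ml_min)) {
    r$f2 <- as.numeric(r$f2_ml_min) * 1000
    r$f2_ml_min <- NULL
  }
  norm_grad <- function(g) {
    lapply(g, function(e) list(
      phi_init = e$phi_init, phi_final = e$phi_final,
      t_grad = if (is.null(e$t_grad)) NA_real_ else as.numeric(e$t_grad)))
  }
  ranges <- parameter_ranges(
    f1 = as.numeric(r$f1), f2 = as.numeric(r$f2), ts = as.numeric(r$ts),
    fmu = as.numeric(r$fmu), loop = as.numeric(r$loop),
    d1_gradients = norm_grad(r$d1_gradients),
    d2_gradients = norm_grad(r$d2_gradients),
    makeup_composition = if (is.null(r$makeup_composition)) 0
                         else as.numeric(r$makeup_composition))
  list(instrument = instrument, d1_column = d1_column,
       d2_column = d2_column, ranges = ranges)
}
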