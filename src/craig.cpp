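#include <Rcpp.h>
using namespace Rcpp;

// Craig counter-current propagation of one analyte through a column of
// n_cells theoretical plates. One call step = one transfer of duration
// t0 / n_cells (handled by the R wrapper):
//   1. the mobile-phase content of every cell (analyte mobile fraction and
//      solvent plug) shifts one cell toward the outlet; the inlet cell is
//      fed from the injection profile / gradient program;
//   2. every cell re-equilibrates: mobile fraction 1/(1+k), stationary
//      k/(1+k).
// Because the solvent propagates unretained and unmixed, the composition of
// cell i at step j is the inlet composition of step j - i - 1 (or the
// initial column composition for j - i - 1 < 0), so the per-cell mobile
// fractions p = 1/(1+k) are precomputed per inlet step in R and looked up
// here by index difference -- no retention-law evaluation in the loop.
//
// inlet_mass: analyte mass entering per step (0 after the injection ends;
//   padded to max_steps by the wrapper with zeros).
// p_inlet: mobile fraction of the solvent parcel entering at each step,
//   length max_steps.
// p_init: mobile fraction in the pre-equilibrated column.
// Early termination once the injection is over and the in-column mass falls
// below stop_frac of the injected mass.
// [[Rcpp::export(name = ".craig_core")]]
List craig_core(int n_cells, NumericVector inlet_mass, NumericVector p_inlet,
                double p_init, int max_steps, double stop_frac,
                bool record_cells) {
  if (n_cells < 1) stop("n_cells must be >= 1");
  if (p_inlet.size() < max_steps) stop("p_inlet shorter than max_steps");
  std::vector<double> mob(n_cells, 0.0), sta(n_cells, 0.0);
  std::vector<double> out;
  out.reserve(4096);
  const int n_inj = inlet_mass.size();
  double injected = 0.0, eluted = 0.0, in_col = 0.0;
  double max_mass_err = 0.0;
  int steps = 0;
  for (int j = 0; j < max_steps; ++j) {
    // shift mobile phase one cell toward the outlet
    double outflux = mob[n_cells - 1];
    for (int i = n_cells - 1; i > 0; --i) mob[i] = mob[i - 1];
    double fed = (j < n_inj) ? inlet_mass[j] : 0.0;
    mob[0] = fed;
    injected += fed;
    eluted += outflux;
    // re-equilibrate each cell with the solvent parcel it now holds
    in_col = 0.0;
    for (int i = 0; i < n_cells; ++i) {
      int idx = j - i;
      double p = (idx >= 0) ? p_inlet[idx] : p_init;
      double tot = mob[i] + sta[i];
      mob[i] = tot * p;
      sta[i] = tot - mob[i];
      in_col += tot;
    }
    out.push_back(outflux);
    double err = std::fabs(injected - eluted - in_col);
    if (injected > 0.0) err /= injected;
    if (err > max_mass_err) max_mass_err = err;
    steps = j + 1;
    if (j >= n_inj && injected > 0.0 && in_col < stop_frac * injected) break;
  }
  List res = List::create(
      _["outflux"] = NumericVector(out.begin(), out.end()),
      _["injected"] = injected, _["eluted"] = eluted,
      _["in_column"] = in_col, _["steps"] = steps,
      _["max_mass_err"] = max_mass_err);
  if (record_cells) {
    NumericVector cells(n_cells);
    for (int i = 0; i < n_cells; ++i) cells[i] = mob[i] + sta[i];
    res["cells"] = cells;
  }
  return res;
}
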