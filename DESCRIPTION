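Package: lcxlcopt
Title: Predictive Method Optimization for Online Comprehensive
    Two-Dimensional Liquid Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predictive method development in online comprehensive
    two-dimensional liquid chromatography (LC x LC). Implements gradient
    retention prediction under linear solvent strength and adsorption
    retention laws, retention-parameter fitting from multi-gradient
    experiments, theoretical performance metrics (peak capacity with
    undersampling and last-peak corrections, dilution factors, pressure
    feasibility), a Craig counter-current distribution simulator of
    second-dimension elution profiles under sample-solvent mismatch and
    volume overload (including split-peak prediction), three-objective
    Pareto front construction, and a hybrid optimizer that refines a
    theoretically derived front with elution-profile simulations.
    Predicted two-dimensional chromatograms can be assembled from the
    simulated profiles for method selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
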