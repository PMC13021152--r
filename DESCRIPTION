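Package: CellPatternSim
Title: Simulation of Spatial Single-Cell Point Patterns and Benchmarking
    of Spatial Summary Statistics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates biologically motivated spatial single-cell molecular
    data without reference datasets: homogeneous Poisson point patterns are
    overlaid with Gaussian-kernel probability surfaces that assign tissue
    compartments, non-cellular holes, cell phenotype positivity, and
    continuous marker values (e.g. protein or gene expression). Per-cell
    tables can be exported in a simple or HALO-like CSV dialect. The package
    also provides translation- and border-corrected estimators of Ripley's
    K(r), the nearest-neighbour distance distribution G(r), and the pair
    correlation function g(r), together with a label-permutation test for the
    degree of clustering, and a scenario runner for benchmarking the
    sensitivity of these summary functions on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
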