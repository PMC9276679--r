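Package: biopsam
Title: Agent-Based Simulation of Tumour-Immune Biopsies with Spatial
    Agreement Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts digitised-pathology CD8 cell maps into lattice tiles,
    simulates tumour-immune dynamics with a stochastic agent-based model on a
    periodic 100x100 lattice, and scores the agreement between simulated and
    observed biopsies with a spatial agreement measure (SAM/VarSAM) built on
    the lattice radial distribution function. Includes one-at-a-time
    sensitivity analysis, rejection-based parameter calibration with
    per-patient voting, a last-observation-carried-forward null benchmark,
    holdout validation, and a synthetic cell-map generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
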