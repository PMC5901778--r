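Package: biofilmCA
Title: Stochastic Lattice Model of Bacterial Surface Colonization Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Probabilistic cellular automaton of two-strain bacterial surface
    colonization under laminar flow, with adhesion-dependent shoving, drafting-
    protected flow detachment and downstream relocation on a periodic lattice.
    Includes the spatial analysis stack used to quantify clonal lineage
    segregation in two-colour occupation patterns: radially averaged two-point
    autocorrelation with a brute-force reference oracle, first-zero clonal
    correlation length, ensemble summaries, adaptive (Abramson) kernel density
    estimation of correlation-length distributions, parameter sweeps over
    adhesiveness, founder density and flow intensity, reference-pattern fixture
    generation, and minimal two-channel image ingestion.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
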