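Package: hemiconn
Title: Hemispheric Structural-Connectome Asymmetry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for hemispheric asymmetry of weighted
    structural connectomes in unilateral brain lesion cohorts. Provides a
    seeded synthetic glioma-cohort generator (mirror-symmetric whole-brain
    templates, lesion-localized ipsilesional weight reduction, clinical
    covariates with realistic marginals), ipsilesional/contralesional
    hemispheric splitting with homotopic alignment, threshold-free
    network-based statistics (TFNBS) with Freedman-Lane permutation
    family-wise error control, weighted graph-topology metrics
    (efficiencies, small-worldness, rich club, hierarchy, assortativity,
    betweenness), and cohort-level statistics (paired hemisphere tests,
    FDR-corrected Spearman clinical correlations, cross-algorithm
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
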