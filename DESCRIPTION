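Package: lesionlad
Title: Lesion Segregation Analysis and Inference of Tumor-Initiation Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing segregating DNA lesions in clonal expansions.
    Implements a discrete-generation branching-process simulator of tumor
    initiation with lesion repair and translesion replication, an analytic
    distribution of Lesion-to-Ancestor Divisions (LAD), a hidden Markov model
    that estimates per-tumor LAD from multiallelic variants (MAVs), grid
    fitting of minimum driver selection coefficients against observed LAD
    distributions with Poisson confidence intervals, chromosome-count bounds
    on LAD for sparse-MAV samples, MAV enrichment/spectrum/phasing statistics
    for bulk tumors, and detection of lesion footprints (MAVs, phylogeny
    violating variants, Watson-Crick strand anticorrelation) on single-cell
    phylogenies. Includes synthetic-data generators with known ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
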