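Package: chromoseg
Title: Long-Range Segmentation of Prokaryotic Chromosomes by Gene Age
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and modeling long-range clustering of ancient,
    young and essential genes on circular prokaryotic chromosomes. Classifies
    genes into age tertiles from genus-wide pangenome commonality, segments a
    circular binary gene string into alternating enriched/depleted regions via
    a smoothed skew profile refined by greedy BIC merging, quantifies patterns
    with a chi-square uniformity test, multiscale structural complexity
    profiles and circular autocorrelation, and simulates two generative models
    of gene-order evolution (Moran-process selection against multi-gene
    disruption of essential genes, and differential gene mobility with
    translocation attractors) together with a staged random/grid-search
    fitting procedure and synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, ComparativeGenomics, Phylogenetics, Software
RoxygenNote: 7.3.3
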