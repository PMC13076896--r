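Package: clonescape
Title: Clonal Evolution Analysis from Multi-Region Tumor Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the subclonal architecture of tumors
    sampled in multiple regions, motivated by the progression of cystic
    pancreatic precursor lesions (IPMN) to invasive pancreatic cancer.
    Computes cancer cell fractions (CCF) from read counts, purity and
    allele-specific copy number; clusters mutations across regions with a
    Bayesian Dirichlet-process binomial mixture (Gibbs sampling); builds
    clone trees with pigeonhole/sum and crossing rules and classifies
    evolutionary trajectories (single versus multiple ancestral clones,
    linear versus branching growth); refits SBS96/ID83/CN48 mutational
    signatures by non-negative least squares and annotates tree branches;
    times mutations (clonal-early/late/subclonal); scores bulk expression
    (squamous-classical gradient, stromal/immune enrichment, constrained
    least-squares cell-fraction deconvolution); and provides the permutation
    and exact tests used in such studies. A synthetic multi-region cohort
    generator with known ground truth makes every stage testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
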