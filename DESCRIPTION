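Package: imscreen
Title: Clonality-Aware Analysis of Retroviral Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for high-throughput retroviral insertional
    mutagenesis screens in which shear-ligation sequencing marks each
    tumor-host junction with a unique ligation point (LP), so the LP count
    of an insertion measures its relative clonality within a tumor. The
    package calls insertions from fragment-level junction records, applies
    the single-LP background filter, detects common insertion sites (CIS)
    by multi-scale Gaussian kernel convolution with a permutation-calibrated
    per-chromosome significance threshold, tests pairwise co-occurrence and
    mutual exclusivity of CISs and their association with host genotype or
    strain, and orders CIS gene families into a directed tumor-progression
    graph by exact binomial comparison of within-tumor clonality scores.
    A synthetic-cohort generator with planted ground truth (CIS loci, gene
    families, within-family mutual exclusivity, and an early-to-late event
    order expressed through LP counts) makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
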