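Package: psgscan
Title: Branch-Site Scans for Positive Selection and Aging-Expression
    Pleiotropy in Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting positively selected genes
    (PSGs) on longevity-associated phylogenetic branches and relating them to
    gene-expression changes during aging. Implements the branch-site codon
    model (Model A) with maximum-likelihood fitting, likelihood-ratio testing
    against the chi-square reference, naive empirical Bayes site posteriors,
    Benjamini-Hochberg candidate calling with convergence control reruns,
    reciprocal-best-hit orthology with isoform selection, a minimal negative
    binomial differential-expression stage, quadrant-based antagonistic
    pleiotropy tests (one-sided Fisher and Lancaster combination), gene-set
    enrichment statistics, and simulators that generate codon alignments,
    count matrices and CDS catalogs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
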