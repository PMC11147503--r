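Package: ampedit
Title: Amplicon-Based Quantification of CRISPR Editing Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing single-stranded oligodeoxynucleotide (ssODN)
    homology-directed repair (HDR) donors with silent PAM- and spacer-breaking
    mutations, and for quantifying precise-edit and NHEJ outcomes from amplicon
    sequencing reads. Includes a seeded read simulator with a nanopore-like
    error model, a banded end-free affine-gap aligner, per-site pileup
    summaries with base- and mapping-quality filters, filtered per-target
    variant statistics with FDR-corrected paired comparisons, restriction
    digest (RFLP) and insertion size-shift quantification, a donor-mixture
    zygosity model with maximum-likelihood fitting, and single-hit Poisson
    limiting-dilution frequency estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
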