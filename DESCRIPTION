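Package: dupreloc
Title: Subcellular Relocalization and Asymmetric Evolution of Duplicated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for protein subcellular relocalization in
    recently duplicated gene pairs. Discovers two-member duplicate clades from
    bootstrap gene-family trees, assigns outgroup orthologs by reciprocal best
    hit with dS triangulation, tests each duplicate pair for asymmetric
    protein-sequence evolution (clock versus free-rate likelihood ratio test
    under the JTT model) and for positive selection (branch-site codon model
    with Bayes Empirical Bayes site identification), classifies localization
    divergence from GFP compartment annotations, and tests whether relocalized
    pairs are enriched for asymmetric evolution (one-tailed Fisher exact test
    and Monte Carlo DIF randomization) and for isoelectric-point shifts.
    Includes a sequence and cohort simulator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
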