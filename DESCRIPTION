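Package: ctppdesign
Title: Genetic-Algorithm Design of Confronting Two-Pair Primer Sets for
    SNP Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs confronting two-pair primer (CTPP) sets that genotype a
    defined biallelic SNP by PCR and gel electrophoresis alone, without
    restriction enzymes or probes.  A six-integer chromosome (two primer
    lengths and a product length per primer pair) is optimized by a
    steady-state genetic algorithm against a weighted fitness built from
    standard primer constraints: primer length difference, GC proportion,
    GC clamp, salt-adjusted melting temperature and pairwise temperature
    differences, cross- and self-dimer and hairpin screens, template
    specificity, and electrophoresis-friendly product-length ratios.
    Includes single-SNP and batch design workflows, plain-text reports,
    synthetic template generators with plantable features, and exhaustive
    small-instance search oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
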