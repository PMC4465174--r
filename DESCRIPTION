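Package: semiperm
Title: Multilocus Analysis of Semi-Permeable Species Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying gene flow across semi-permeable species
    boundaries from phased multilocus haplotype alignments. Computes
    per-population nucleotide polymorphism statistics (segregating sites,
    haplotype diversity, mean pairwise differences, nucleotide diversity,
    Watterson's theta), pairwise population divergence (Dxy, Da, Hudson's
    FST) with neighbor-joining population networks and site-bootstrap
    support, classifies introgressed alleles by a sympatry/allopatry
    diagnostic rule and tests the introgression-versus-divergence trend
    with an exact permutation Spearman correlation, and contrasts
    polymorphism between sympatric and allopatric populations
    (Mann-Whitney U with Benjamini-Hochberg FDR). A structured-coalescent
    isolation-with-migration simulator with locus-specific boundary
    permeability generates validation datasets with known truth.
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
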