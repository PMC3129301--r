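Package: retroclock
Title: Dating and Grouping LTR Retrotransposon Insertions from LTR Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular-clock dating of long terminal repeat (LTR)
    retrotransposon insertions from the divergence between an element's two
    LTRs, and phylogenetic grouping of family members by genome of origin.
    Detects the terminal direct repeats of an element by seed-and-extend
    self-comparison anchored on the canonical 5'-TG...CA-3' motifs, aligns
    the two LTRs with an exact affine-gap global aligner, estimates their
    Kimura two-parameter divergence with standard error, and converts it to
    an insertion age via T = D/2r. Builds neighbor-joining trees with
    column-resampling bootstrap support from aligned family domains,
    classifies clades into genome-specific and mixed groups, produces
    Table-style composition accounting of annotated BAC sequence
    (category fractions, gene-island geometry, gene density, CDS-derived
    protein lengths) and in-silico PCR checks for insertion-site based
    polymorphism markers. Includes a seeded K80 sequence-evolution simulator
    that emits element families with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
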