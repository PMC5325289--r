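Package: smartbias
Title: Quantify and Filter Poly dA/dT Priming Bias in Template-Switching
    DNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Library-preparation quality control for template-switching
    (SMART) DNA sequencing libraries. Incomplete terminal-transferase
    tailing lets the poly(dA) adapter primer anneal to genomic poly(dT)
    runs, so sequenced fragments end preferentially next to long
    homopolymer tracts. The package scans genomes for exact and
    mismatch-tolerant homopolymer tracts, extracts strand-aware fragment
    ends from alignments, measures read-end adjacency enrichment with
    chi-squared goodness-of-fit statistics and Cramer's phi effect sizes,
    provides shift-based randomization nulls and a random-fragment
    simulation, implements the recommended mismatch-tolerant adjacency
    filter, and ships a truth-labeled genome and library simulator that
    reproduces the internal-priming mechanism for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
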