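Package: snsplice
Title: Spliceosomal snRNA Abundance and Alternative Splicing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for studying how spliceosomal snRNA
    (U1, U2, U4, U5, U6) abundance shapes alternative splicing. Provides
    qPCR snRNA-panel quantification (delta-Ct / delta-delta-Ct with
    amplification-efficiency correction and replicate confidence
    intervals), percent-spliced-in (PSI) estimation from junction-spanning
    and exon-intron boundary reads, Bayes-factor differential-splicing
    calls (BIC approximation), cis/trans feature association (splice-site
    strength, GC, branchpoints, Pol II occupancy, k-mer enrichment,
    metagene coverage), and cohort-level enrichment of snRNA-sensitive
    missplicing in matched tumor/normal pairs. A synthetic-data module
    generates toy genomes, gene models, read counts, qPCR panels,
    coverage tracks and patient cohorts with the statistical structure
    the analysis assumes, so the whole pipeline runs end-to-end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomicAlignments,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
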