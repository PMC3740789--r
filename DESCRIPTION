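Package: methylannot
Title: Expanded Probe Annotation for Infinium-Style DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Magda", "Prentice", email = "mprentice@example.org", role = c("aut", "cre"))
Description: Builds an expanded annotation for Infinium-style DNA methylation
    array probes: derivation of probe genomic intervals from manifest MAPINFO
    coordinates, detection of documented SNPs in the target CpG, an in-silico
    bisulfite cross-hybridization screen over four converted genome variants,
    high/intermediate-density CpG island (HC/IC/ICshore/LC) and UCSC-style
    island/shore/shelf/sea classification, nine-way gene-feature annotation
    with closest-TSS distances, and downstream methylation statistics
    (beta/M transforms, variability screens, Kolmogorov-Smirnov comparisons,
    tissue differential methylation z-scores, relative enrichment, and a
    sex-difference screen). Ships deterministic synthetic-fixture generators
    so the full pipeline is testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    limma,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
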