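Package: epicross
Title: Chromatin Structure, Regulatory Annotation and Cross-Species
    Conservation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analyses for multi-assay functional annotation of
    animal genomes: Hi-C contact-map balancing (ICE), distance correction,
    A/B compartment calling by the sign of the first principal component,
    directionality index and insulation-score profiles, and replicate
    consistency; positional classification of assembled transcripts
    against a reference annotation; ATAC-seq peak genomic-domain
    classification, TSS density profiles, promoter accessibility and
    expression/accessibility correlation; cross-species conservation via
    best-hit selection, collinear block chaining, similarity clusters,
    syntenic lncRNA detection, a compartment-conservation chi-squared
    test and permutation overlap tests. Includes seeded synthetic-data
    generators emulating the statistical structure of these assays so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
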