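Package: divtss
Title: Primary Transcriptome Mapping and Bidirectional Promoter Screening
    from dRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies transcription start sites (TSS) from
    differential RNA-seq (TEX-treated versus untreated) 5'-end coverage,
    characterises archaeal promoter architecture (BRE, TATA box, initiator)
    with TSS-anchored position weight matrices, and screens primary TSS for
    divergent antisense transcripts produced by bidirectional transcription
    from a shared TATA element. Includes metagene coverage profiling,
    transcription-unit inference from TSS and fragmented-library coverage,
    antisense TSS mapping around insertion-sequence elements, k-mer spectrum
    comparison of assemblies, and a synthetic-data generator that plants
    promoters, TSS and coverage tracks with a machine-readable truth table
    so every stage can be validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
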