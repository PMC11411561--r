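Package: hydroplume
Title: Catabolic Energetics and Chemolithoautotroph Profiling in Hydrothermal Plumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for studying chemolithoautotrophy in deep-sea
    hydrothermal plumes. Computes Gibbs free-energy yields of aerobic hydrogen
    and sulfide oxidation along a seawater:vent-fluid dilution gradient,
    classifies CTD bottle samples into plume stages from the turbidity anomaly,
    normalizes functional-gene sequencing depths by genome equivalents derived
    from universal single-copy marker genes, computes RPKM and TPM
    abundance/transcription metrics with a housekeeping-gene baseline, and
    classifies carbon monoxide dehydrogenase (cox) operons into form I/II by
    active-site motif and subunit order. A seeded synthetic-data module
    generates CTD casts, mock communities, cox operon fixtures and transcript
    count tables with ground truth, so the full pipeline runs and is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
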