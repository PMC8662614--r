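Package: sterileX
Title: X-Linked Hybrid Sterility Genomics: Macrosatellite Architecture,
    Copy Number, Methylation and Ancestry Fine-Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the computational procedures used to
    dissect an X-linked hybrid male sterility locus centred on a
    DXZ4-like compound macrosatellite: CTCF-motif scanning with mismatch
    tolerance, tandem-array segmentation and repeat-unit extraction, CpG
    island detection by a two-state hidden Markov model, p-distance
    summaries and neighbour-joining trees of repeat units, read-depth
    copy-number estimation over collapsed repeat arrays with single-copy
    controls, female-coverage-based Y-contig classification, RRBS
    sliding-window differential methylation with lambda spike-in
    conversion estimation, chromosome-level differential-expression
    enrichment with permutation nulls, and X-linked ancestry
    fine-mapping in a backcross cohort. A synthetic-data generator
    emulates every input so all stages run without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
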