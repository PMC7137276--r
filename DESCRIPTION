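Package: gbskaryo
Title: Read-Depth Karyotyping of Aneuploidy and Chromosomal Deletions from
    Genotyping-by-Sequencing Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects aneuploidy, terminal and segmental chromosomal
    deletions from genotyping-by-sequencing (GBS) alignments by read-depth
    analysis. Uniquely mapped GBS tag positions are counted in sliding
    genomic windows, normalized across samples and to the per-bin median so
    that the disomic expectation equals one, classified into copy-number
    dosage classes (0x-6x), summarized into whole-chromosome and segmental
    event calls, and rendered as color-coded karyotype ideograms. Includes
    a seeded tag-sampling simulator with known dosage truth so the whole
    pipeline is verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
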