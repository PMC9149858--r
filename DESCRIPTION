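Package: sRNAtlas
Title: Profiling and Classification of Unusually Short RNA Fragments from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for small RNA sequencing libraries covering the
    extended 8-30 nt length window, including the unusually short 8-15 nt range
    that standard size selection discards. Collapses reads into unique
    (sequence, length) species with reads-per-million normalization, assigns
    each unique read one biotype through a prioritized hierarchical search of
    per-biotype reference sets (rRNA and tRNA before piRNA, exact match first,
    one-substitution rescue second), and profiles the result: length
    distributions, short-versus-standard window shares, per-window biotype
    composition, dominant-sequence tables, and exact one-dimensional k-means
    clustering of log-abundance. Fragment families are grouped on a minimal
    common seed sequence to expose 5' and 3' extensions and staircase-like
    degradation ladders, and unique sequences can be intersected across species.
    A seeded simulator generates reference sets, FASTQ reads and ground-truth
    tables reproducing this fragment structure, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
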