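Package: wescnv
Title: Exome Copy-Number Variant Discovery from Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls copy-number variants (deletions and duplications) from
    whole-exome sequencing read depth in sample cohorts. Computes per-target
    mean coverage from coordinate-sorted alignments, removes systematic
    biases by subtracting the top K principal components of the centred
    read-depth matrix -- with K chosen by an iterative truncated-SVD
    relative-variance rule -- and segments per-sample z-scores with a
    three-state hidden Markov model (log-space Viterbi, scaled
    forward/backward), reporting phred-scaled call qualities in the .xcnv
    table format. Includes a synthetic-cohort generator with known embedded
    CNVs for end-to-end validation and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
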