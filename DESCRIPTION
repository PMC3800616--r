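Package: exocascade
Title: Iterative Cascade Mapping and Quantification of Exosomal Small RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies the RNA cargo of exosome and parental-sample small
    RNA-seq libraries with an iterative mapping cascade. Provides 3' quality
    and adapter trimming with a 17-nt length floor, per-library quality
    summaries, a k-mer-seeded Smith-Waterman local aligner with SAM output,
    sequential mapping against ordered class-annotated reference sets
    (miRNA hairpin/tRNA/rRNA, then RefSeq-style transcripts, then other
    noncoding RNA), per-transcript counting, percent-of-mapped
    normalization, top-N ranking with rank-overlap statistics, RNA-class
    composition profiles, and descriptive differential-representation
    reports. Includes a deterministic truth-labelled read simulator and
    packaged top-10 mean-count tables for HeLa and serum libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    Rsamtools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
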