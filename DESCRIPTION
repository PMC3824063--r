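Package: mirforge
Title: Novel miRNA Discovery from Small RNA-Seq with Hairpin Filtering and
    Random-Forest Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discovery pipeline for novel microRNAs from small RNA deep
    sequencing data. Reads are trimmed and collapsed, aligned sequentially to
    annotation tiers (mature miRNA, mature-star, unobserved star, hairpin,
    mRNA, non-coding RNA families) and finally to the genome; genome-aligned
    reads are grouped into strand-specific clusters, expanded into candidate
    precursor windows, folded into secondary structures and filtered on
    hairpin criteria. Ten molecular features per surviving precursor feed a
    random-forest classifier (1000 trees, 66% sample bags, 3 features per
    tree) with out-of-bag evaluation and permutation feature importance.
    Positive predictions are post-filtered on minimum free energy and
    chromosome, merged into a catalog of novel miRNA calls, and quantified as
    reads per million under stringent alignment criteria. A companion module
    implements signal-to-noise permutation testing for microarray differential
    expression, and a synthetic-data generator plants ground-truth hairpins so
    every stage is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    rpart,
    limma,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest,
    jsonlite,
    optparse
Config/testthat/edition: 3
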