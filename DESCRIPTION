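Package: crestreg
Title: Regulatory Element Dynamics, Motif Co-Occurrence and lncRNA
    Discovery for Developmental ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising cis-regulatory elements from
    stage-resolved chromatin accessibility (ATAC-seq) data in developing
    embryos. Builds a consensus peakset across developmental stages and
    classifies peaks into promoter, exonic, intronic and intergenic sets
    with strand-aware promoter-flank, curated-promoter reassignment and
    gene-proximity rules; bins accessibility signal around peak centres
    and clusters profiles by k-means to identify dynamically opening
    ("EMT") element clusters via an early-versus-late offset test; scans
    sequences with position weight matrices, builds binary motif presence
    matrices over fixed windows and tests pairwise motif co-occurrence
    against a control cluster with a chi-squared test under Bonferroni
    control; and applies a rule-based cascade (coding overlap, protein
    similarity, splicing, antisense proximity, length) to nominate long
    non-coding RNA candidates. Includes a synthetic-data generator with
    planted ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
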