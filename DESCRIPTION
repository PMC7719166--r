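Package: skipmeth
Title: Exon-Skipping Rates and Whole-Genome Bisulfite Methylome Analysis
    for Two-Condition Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a matched methylome/transcriptome comparison between
    two conditions (e.g. wild-type versus knockout liver): per-CpG methylation
    calling from aligned bisulfite reads by C>T transition frequency, global
    and regional mCG summaries, 50-bin metagene methylation profiles over gene
    functional elements, a Fisher-exact sliding-window caller for
    differentially methylated regions (DMRs) with length and direction
    filters and gene-element annotation, splice-junction based exon-skipping
    rate estimation (Rs/(Ri+Rs)) with read- and sample-exclusion rules, and
    correlation of gene-body DMR length with expression fold change. Includes
    a fully deterministic synthetic-data generator (genome, annotation,
    bisulfite and junction reads, expression) with recorded ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
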