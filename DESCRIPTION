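Package: retroscape
Title: Detection, Dating and Expression Analysis of mRNA Retrocopies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A genome-wide retrocopy (processed pseudogene / retrogene)
    analysis toolkit. Detects intronless genomic copies of multiexonic
    protein-coding genes from transcript-to-genome chained alignments,
    infers cross-species orthology of insertions from non-repetitive
    syntenic flanking sequence, assigns origin branches on a dated species
    tree and estimates per-branch origination/fixation rates, scores
    selection on retrocopy-parent pairs with Nei-Gojobori Ka/Ks under a
    Jukes-Cantor correction, calls expressed retrocopies from RNA-seq-like
    read alignments via chimeric-junction and unique-alignment strategies
    with tissue-specificity (tau) and genomic-context statistics, and
    profiles LINE-1 subfamily composition. A synthetic-data module
    generates multi-species genomes with planted retrocopies and
    tissue-stratified reads so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    ape,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
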