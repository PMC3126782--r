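Package: chemoseq
Title: Tissue-Enhancement Profiling of Chemosensory Appendage RNA-Seq
Version: 1.0.0
Authors@R:
    person("chemoseq", "developers", email = "chemoseq@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for calling tissue-enhanced gene expression
    from single-end short-read RNA-seq of paired appendage/whole-body
    libraries, modelled on transcriptome surveys of mosquito chemosensory
    organs (antennae and maxillary palps of both sexes).  Reads are trimmed,
    mapped to a gene-condensed transcriptome with a mismatch-tolerant k-mer
    seed index, multi-mapping reads are apportioned into weighted per-gene
    counts, expression is normalized to RPKM, and per-gene enhancement is
    called by a two-sided Fisher's exact test on read counts with Bonferroni
    family-wise error control and a fold-change filter.  Comparative tools
    cover enhanced-set overlaps, Pfam/chemosensory family tallies,
    sensilla- and co-receptor-based cross-sex normalization, and recovery
    scoring against the bundled read simulator's ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
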