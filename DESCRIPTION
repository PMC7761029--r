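Package: gbanet
Title: Guilt-by-Association Candidate Gene Discovery from Multi-Tissue RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational chain used to
    nominate monoterpene indole alkaloid (MIA) biosynthesis candidate genes
    from multi-tissue RNA-seq of Vinca minor: TPM normalization and
    low-expression filtering, replicate quality control, greedy redundancy
    clustering of merged transcript assemblies, negative-binomial exact
    tests for differential expression with UpSet-style set overlaps and
    hypergeometric keyword enrichment, homology-based conservation tiering
    against bait genes, and a Highest-Reciprocal-Rank (HRR) co-expression
    network with fast-greedy modularity communities and bait-anchored
    candidate reports. A seeded synthetic-data generator emulates the
    study design (four tissues, two replicates, negative-binomial counts
    at common dispersion 0.168531, planted co-expression modules, planted
    differential expression, redundant transcript variants, and
    bait-homolog sequences at controlled identity) so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    withr
Config/testthat/edition: 3
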