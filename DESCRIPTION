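Package: rankcmp
Title: Rank-Based Comparison of Differential Gene Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares full differential gene-expression profiles across
    studies and platforms using rank-based statistics. Converts fold-change
    tables into ranked profiles, merges replicate profiles into a prototype
    ranked list by iterative closest-pair aggregation (Spearman's footrule
    distance with the Borda mean rule), computes rank-rank hypergeometric
    overlap (RRHO) maps of signed log10 tail probabilities with per-pixel
    overlap gene lists, measures GSEA-style enrichment-score distances
    (total enrichment score) between profiles, and turns the resulting
    distance matrices into thresholded similarity networks and affinity
    propagation clusterings. A command-line interface exposes every step
    for scripted pipelines.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
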