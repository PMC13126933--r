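Package: solenoidscan
Title: Detection of Alpha-Solenoid Organellar Trans-Acting Factors in
    Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three complementary procedures for detecting candidate
    alpha-solenoid RNA-binding proteins (OPR, PPR and related organellar
    trans-acting factors) in protein sequence sets: an iterative
    profile-based motif-discovery loop that grows a degenerate repeat-motif
    collection by alternating Markov clustering, profile construction and
    proteome search; a decision-tree filter chain over structural
    annotations (tandem repeats, helix-pair linkers, secondary structure,
    transmembrane helices, organelle-targeting votes); and a random-forest
    classifier over a 61-variable physico-chemical descriptor built from
    repeat geometry, amino-acid frequencies, disorder content and Z-scale
    auto-cross-correlation terms.  Downstream tools cluster candidates into
    protein families with phylostratigraphic classes and quantify
    positional bias of motif clusters along proteins.  A deterministic
    synthetic-fixture generator makes every stage testable without external
    predictor binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
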