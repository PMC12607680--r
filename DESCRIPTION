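Package: transomic
Title: Trans-Omic Upstream Regulator Discovery from Transcriptome and
    Proteome Differential Tables
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering upstream regulators from
    paired transcriptome and proteome differential-expression tables.
    Builds significant up/down feature sets with Benjamini-Hochberg control
    and classifies transcript-protein concordance; scans fixed-window
    promoter sequences with position weight matrices and tests Yes-versus-No
    binding-site enrichment; searches for composite cis-regulatory modules
    (weighted motif clusters in a sliding window) with a genetic algorithm
    that minimises a Wilcoxon separation p-value; walks a directed signaling
    network upstream of the discovered transcription factors to score and
    rank candidate master regulators against an empirical resampling null;
    and ranks candidate drug targets with curated and predicted druggability
    scores. A seeded synthetic-data module generates differential tables,
    motif-implanted promoter sets, planted-regulator networks and toy drug
    tables so that every stage is testable without proprietary databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
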