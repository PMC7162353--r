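Package: respiromics
Title: Species-Level Respiratory Tract Microbiome Profiling from Long-Read rRNA Operon Hits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for species-level profiling of the human
    respiratory microbiome from long-read (nanopore) rRNA operon sequencing.
    Consumes BLAST-style tabular top-hit tables, applies read-length and
    identity/alignment quality windows, aggregates multi-rank taxonomic count
    tables, normalizes per-participant compartment counts and calls
    lung-enriched species by paired read-count differencing against mouth and
    nose, classifies inside-out versus outside-in abundance gradients along
    the respiratory tract using the throat as the intermediate compartment,
    summarizes community similarity with Bray-Curtis dissimilarities and
    ordination, and estimates reagent ("kitome") contamination from PCR
    negative libraries. Includes a Dirichlet-multinomial multi-compartment
    community simulator with planted gradient structure so the whole pipeline
    is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
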