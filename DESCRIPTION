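Package: pathomics
Title: Multi-Omics Integration for De Novo Biosynthetic Pathway Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates paired untargeted metabolomics (LC-MS mass features)
    and transcriptomics (normalized expression) to predict candidate
    biosynthetic pathways de novo. Builds mutual-rank correlation networks
    between transcripts and mass features, detects overlapping functional
    clusters of genes and metabolites, annotates features with candidate
    structures by adduct arithmetic and ppm matching against a metabolite
    structure table, connects features through enzyme-supported
    retrosynthesis reaction rules via their mass transitions (optionally
    inserting unmeasured ghost intermediates), and extracts ranked pathway
    predictions as longest paths through directed acyclic reaction graphs.
    Reaction likelihoods are scored from per-atom site-of-metabolism scores
    restricted to reaction-center atoms. Ships a deterministic synthetic
    data generator with a planted pathway so the full workflow is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
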