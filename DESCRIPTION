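Package: crossPPI
Title: Partner-Aware Prediction of Protein-Protein Interaction Sites by
    Cross-Attention over Residue Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Residue-level prediction of protein-protein interaction sites
    conditioned on a specific interaction partner. A multi-head
    cross-attention layer lets every residue of a query protein attend to
    all residues of a partner sequence; the attended representation is
    normalised and passed through a small classifier to yield per-residue
    interaction probabilities. The package provides the full supporting
    stack: deterministic and file-based embedding backends, overlapping
    -window chunked inference with max-pool aggregation for long sequences,
    training with early stopping, interface annotation from multi-chain
    structures via the change in relative solvent accessibility on complex
    separation, redundancy-aware dataset curation with leakage-free grouped
    splits, imbalance-aware residue-level evaluation including a
    scrambled-partner control, and partner-ensemble interface scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
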