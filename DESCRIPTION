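Package: plmbind
Title: Per-Residue Protein Ligand-Binding Prediction from Language Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts, for every residue of a protein, whether it binds a
    metal ion, a nucleic acid (DNA/RNA), or a small molecule, using
    pre-computed per-residue protein language model embeddings as the only
    input. Provides a shallow two-layer convolutional sequence labeller
    trained with a class-weighted binary cross-entropy loss, a
    homology-based annotation-transfer engine built on local alignment with
    E-value and percent-identity rules, a combiner that routes each query to
    homology transfer when an annotated homolog exists and to the learned
    model otherwise, a per-protein evaluation framework (precision, recall,
    F1, MCC, their negative-class analogues, coverage measures, and normal
    or bootstrap confidence intervals), reliability indices and probability
    cutoff sweeps, and seeded synthetic-data generators with planted binding
    signal and homolog families for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
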