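Package: molrank
Title: Pairwise Learning-to-Rank for Molecular Conformer Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Siamese pairwise learning-to-rank framework for ordering
    conformers and isomers of the same molecule by a scalar property.
    Structures are scored by a distance-based graph neural network with
    radial-basis distance expansion, a learnable quintic cutoff, and a
    skip-connection prediction layer; a logistic-difference head turns
    score differences into ranking probabilities.  Includes pairwise
    cross-entropy, pairwise squared, and pointwise training objectives
    (with hand-written gradients and an Adam optimiser), an MLP head for
    precomputed molecular embeddings, extended-XYZ input/output,
    molecule-level data splitting, a four-metric ranking evaluation suite
    (rank MAE, Spearman, nDCG, top-1 frequency) with confidence
    intervals, and a seeded synthetic conformer-ensemble generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
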