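Package: peptriad
Title: Intra-Protein Binding Peptide Triads and Duos from Structure and Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates short same-length peptide fragment pairs (duos) and
    triples (triads) within protein chains, labels them binding or
    non-binding by center-residue minimum-distance cutoffs (5.0 and 30
    Angstrom), one-hot encodes their sequences, and classifies binding from
    sequence alone with a feedforward neural network (four 256-unit ReLU
    hidden layers, softmax output) trained by mini-batch ADAM on a
    cross-entropy loss with L2 regularization. Ships the negative and
    specificity controls that validate the learned signal (label
    randomization and column-wise triad swapping), a linear no-hidden-layer
    model with per-amino-acid weight maps, amino-acid composition
    comparison, ROC/AUC benchmarking, and seeded generators for toy
    coordinate files with planted contacts and for labeled sequence
    datasets with implanted, noise-controllable pairing rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
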