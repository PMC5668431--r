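# peptriad

Do short peptide fragments that bind each other *inside* a folded protein
carry intrinsic sequence patterns — something like base pairing, but for
peptides? `peptriad` implements the full computational argument as a
tested R package, for structural bioinformaticians who want to extract
intra-protein fragment tuples from coordinate data, train a sequence-only
classifier on them, and run the controls that tell real signal from
pipeline artifacts.

## What it computes

**Extraction.** A *peptide triad* (*duo*) is a set of three (two)
same-length, non-overlapping fragments from one chain. With
d(r, r′) = min over non-hydrogen atom pairs of the Euclidean distance, and
fragment distance = mean of d over center-residue pairs (one center for odd
lengths, two averaged for even), a tuple is

- **binding** if every pairwise fragment distance < 5.0 Å,
- **non-binding** if every pairwise fragment distance > 30 Å,

with stride-1 enumeration, a 9-residue dedup window, a minimum
center-separation of 10 residues, and exclusion of duos contained in
binding triads. `parse_structure()` reads PDB text (first model, highest-
occupancy alternate locations, no hydrogens, no HETATM).

**Classification.** Tuples are one-hot encoded (20 bits per residue,
alphabetical order: `A` → bit 1, `Y` → bit 20; a 3×7 triad is a 420-bit
vector with 21 ones) and classified by a feedforward network — input, four
256-unit ReLU hidden layers, 2-unit softmax — trained with mini-batch ADAM
(batch 128) on the loss

    H = -(1/n) Σ_i log y_{i,c(i)}  +  λ Σ (w² + θ²)

with λ = 2.5e-6 and starting learning rate 6e-4 by default, 80/10/10
train/validation/test splits and early stopping on validation accuracy.
A no-hidden-layer linear variant plus a per-amino-acid weight map
(`train_linear()`, `linear_weight_map()`) probes how non-additive the
signal is.

**Controls.** `randomize_labels()` (labels → Bernoulli(0.5); a sound
pipeline falls to accuracy/AUC ≈ 0.5) and `swap_triads()` (column-wise
fragment permutation: composition bit-identical, combinations destroyed).
`composition_profile()` / `composition_ttest()` document that binding and
non-binding classes are compositionally indistinguishable, and
`classification_metrics()` / `roc_curve()` provide accuracy, AUC-ROC
(rank formulation), F1, precision and recall.

**Synthetic data.** Everything runs without downloads:
`make_toy_structure()` writes PDB text with planted contacts at exact
target distances over an extended backbone, and
`simulate_pattern_dataset()` generates balanced labeled tuple sets whose
binding class follows a configurable hydrophobic/charged/polar pairing
rule corrupted at a noise rate ε.

## Worked example

```r
library(peptriad)

## a 60-residue toy chain with one planted 3-way contact at 4.5 A
spec <- geometry_spec(chain_lengths = 60, contacts = list(
  list(chain = 1, starts = c(5, 25, 45), length = 7, distance = 4.5)),
  seed = 3)
s <- parse_structure(make_toy_structure(spec), "toy")
tri <- extract_tuples(s, arity = 3, extraction_config(fragment_length = 7))
tri[tri$label == 1, c("start1", "start2", "start3", "seq1", "seq2", "seq3")]
#>    start1 start2 start3    seq1    seq2    seq3
#> 11      5     25     45 MIYLISI IWGIRLM TKFVGIM
sum(tri$label == 0)   # plus 20 non-binding triads from the extended axis
#> [1] 20
```

Exactly the planted triad is recovered as binding. Training the classifier
on 20,000 implanted-rule triads:

```r
ps  <- pattern_spec(n_binding = 10000, noise = 0, seed = 7)
ds  <- encode_tuples(simulate_pattern_dataset(ps))
sp  <- split_dataset(ds, seed = 11)
fit <- mlp_train(sp, train_config(seed = 5))
fit
#> mlp_fit: layers 420-256-256-256-256-2, 54 checkpoints, best val accuracy 0.9625 (ckpt 34)
classification_metrics(predict(fit, sp$test), sp$test$y)
#> n = 2000  accuracy 0.970  AUC-ROC 0.994  F 0.970  precision 0.952  recall 0.989
```

The held-out implanted pairing rule is recovered at 97% test accuracy; on
the same data with `randomize_labels()` the identical protocol stays at
accuracy and AUC ≈ 0.5, and `train_linear()` stays near chance because the
rule is combination-dependent, not additive.

The numbered scripts under `analysis/` run the full story — structural
extraction corpus, classifier training, both controls, the linear model and
the composition comparison — writing tables under `results/`.

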