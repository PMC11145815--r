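---
title: "Multimodal fusion prediction of protein-ligand binding affinity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion prediction of protein-ligand binding affinity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plafusion)
```

## The problem and the model

Binding affinity between a small-molecule ligand and a protein is expressed
here in pK units, the negative decadic logarithm of a dissociation or
inhibition constant; 6 pK is micromolar, 9 pK nanomolar, and larger means
tighter binding. `plafusion` predicts the pK of a pocket/ligand complex from
three complementary views of the same structure:

1. **Ligand descriptors.** A frozen registry of 196 named 2D
   physicochemical and topological descriptors computed from the molecular
   graph (element composition, ring and bond-order counts, formal charges,
   degree statistics, hydrogen-bond donor/acceptor counts, Wiener/Zagreb/
   Randic/Balaban indices, connectivity and kappa shape indices,
   electrotopological-state sums, Moreau-Broto autocorrelations at
   topological lags 1-8, and crude additive logP/MR/PSA estimates). The
   registry is versioned and its version string is stamped into every
   trained model, so a model can refuse (or warn about) descriptor matrices
   produced by a different registry.

2. **Pocket CTD descriptors.** The classical 147-element
   composition/transition/distribution vector of the pocket's one-letter
   sequence: for each of seven physicochemical properties (hydrophobicity,
   normalized van der Waals volume, polarity, polarizability, charge,
   secondary-structure propensity, solvent accessibility) the 20 amino
   acids are partitioned into three classes, and the sequence is summarized
   by 3 class percentages, 3 adjacent-pair transition percentages, and 15
   positional quantiles (first and 25/50/75/100% occurrence positions per
   class, as percent of sequence length). 7 x (3 + 3 + 15) = 147.

3. **A spatial interaction graph.** Nodes are the pooled heavy atoms of
   ligand and pocket, each carrying a 19-dimensional feature vector
   (one-hot element over 11 symbols, one-hot covalent degree 0-5, formal
   charge, ligand flag). Covalent edges come from the ligand bond table,
   typed by bond order; pocket-internal covalent edges are inferred with
   the covalent-radius rule (d <= r_i + r_j + 0.4 A) because pocket PDB
   files carry no connectivity; non-covalent edges connect every remaining
   atom pair within a distance threshold, 4.5 A by default.

The two descriptor vectors are z-scored with training-set statistics and
encoded by **1D-convolutional towers**: three blocks of convolution,
batch normalization and PReLU, each followed by width-2 max pooling, then
global mean pooling and a linear projection to a common token width. The
graph is encoded by a **staged gated graph sequence network**: node
features are embedded, then updated by GRU-gated message-passing steps
that first propagate along covalent edges only (bonded structure), then
along all edges including the non-covalent contacts (interaction
structure); a gated per-node embedding is summed over the ligand atoms
(a ligand-only gather readout) and projected to the token width. The three
modality tokens are balanced by a **scaled dot-product self-attention
layer over the three tokens** — attention weight rows sum to one, so the
layer reweights rather than rescales — and the flattened attended tokens
feed a fully connected head that outputs a single pK value.

Ablation variants drop one modality and attend over the remaining two
tokens: `"LI"` (no pocket tower), `"IP"` (no ligand tower), `"LP"` (no
interaction graph). They are strict parameter subsets of the full `"LIP"`
model, which the test suite verifies by parameter counting.

## Training protocol

Training minimizes the smooth L1 loss (quadratic below `beta` = 1 pK,
linear above, so mislabeled or hard complexes do not dominate) with Adam
(default learning rate 2e-3, multiplicative decay 0.98 per epoch) over
seeded minibatches. After every epoch the model is evaluated on a
validation set; the returned model is the parameter snapshot with the
*minimum validation loss*, never simply the last epoch, and early stopping
triggers after 25 epochs without improvement. `split_train_val()`
implements the 80/20 protocol (a pool of 3,772 complexes splits into 3,018
training and 754 validation items, the arithmetic of the PDBbind refined
set). `repeat_experiments()` re-runs training under 10 different seeds by
default and reports per-seed PCC/MAE/RMSE with mean and standard
deviation, flagging the seed with the lowest validation loss — the
selection rule used to pick a model for screening.
`hyperparameter_search()` is a seeded uniform random search over a
declared space; the trial sequence is replayable from the seed alone.

Everything is deterministic per seed on a given platform: parameter
initialization, minibatch composition, dropout masks and label noise all
derive from user-supplied seeds, and the RNG state of the caller is never
disturbed. Bitwise reproducibility across BLAS implementations or thread
counts is not promised.

## What the synthetic generator emulates

Real affinity collections pair a cropped binding-pocket PDB with a ligand
SDF and a curated pK label. The generator emulates exactly that layout: a
pocket of 30-60 residues as C-alpha-like carbons with exact 3.8 A spacing
along a smooth random Lissajous space curve (compact, so a ligand near the
centroid is in atomic contact with the pocket), and a ligand of 10-30
heavy atoms over C/N/O/S grown as a random tree with occasional cycles,
bond lengths within 1.2-1.8 A and valence-style degree caps. The planted
label is a weighted sum of three standardized terms — ligand heavy-atom
count, hydrophobic-class fraction of the pocket sequence, and the count of
ligand-pocket atom pairs within 4.5 A — mapped onto the pK scale (centered
at 7, three population standard deviations spanning +/- 5 pK), plus
Gaussian noise of 0.3 pK, clamped to the realistic range [2, 12]. The
default weights (1, 1, 2) put the largest share of signal on the
interaction term, so the graph-free `"LP"` ablation has a strictly lower
performance ceiling than the full model — the property the ablation tests
exercise. Standardization constants use closed forms for the first two
terms and a frozen seeded Monte Carlo for the contact term, so labels are
independent across samples.

The chemistry is deliberately cartoonish: no aromaticity perception, no
stereochemistry, no protonation, no docked-pose realism. Passing tests on
this generator demonstrate that the pipeline — parsing, featurization,
graph construction, training, selection, evaluation — is correct and that
the architecture can recover a planted structure-dependent signal; they do
not certify accuracy on real affinity data, which has far weaker and
noisier structure-activity relationships.

## Study conditions and problem sizes

The learnability checks run at the generator's default conditions: 500
complexes, of which 100 are held out as a test set and the remaining 400
split 80/20 into 320 training and 80 validation items; three training
seeds; the full model must reach a median held-out PCC of at least 0.8,
and the graph-free ablation must show a higher RMSE in at least 2 of the
3 seeds. The overfit contract trains on 10 complexes for 500 epochs
without decay or dropout and requires a training RMSE below 0.1 pK — a
capacity check that the network and its hand-written gradients can drive
the loss to zero. The default network is sized for these conditions
(tower channels 16/32/64, graph hidden width 24, one covalent and two
full message-passing steps, gather width 48, token width 64, head
128/32); every dimension is exposed in `model_config()` and can be
raised for larger collections. Gradients are clipped to a global norm of
5 by default, which removes the occasional late-training instability of
the gated graph stages.

## Numerical choices

* Descriptor z-scoring uses training-set statistics; constant descriptors
  get unit scale so they pass through as zeros rather than NaN.
* Non-finite descriptor values (possible on degenerate graphs, e.g.
  disconnected fragments) are imputed to 0 with a once-per-name warning.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1) in inference; inference is therefore
  deterministic, and dropout is inference-disabled.
* The distribution block's quantile convention is
  `ceiling(k * n_g / 4)`-th occurrence for k = 1..4 plus the first
  occurrence; it is frozen by golden tests.
* Attention ties (identical tokens) give exactly uniform weights; the
  softmax is computed with max-shifting for stability.
* PCC of a constant vector is reported as an explicit undefined marker,
  not silently zero; MAE <= RMSE always holds.
* The 2D principal-component projection fixes each axis sign so the
  largest-magnitude loading is positive, making plots reproducible.
* Gradients of every layer are hand-written reverse-mode matrix algebra
  (with C++ kernels for the elementwise hot paths) and are verified
  against central finite differences in the test suite; the check uses
  smooth random inputs because max-pooling and PReLU have measure-zero
  kink points where one-sided derivatives legitimately differ.

## Design choices where the design was open

* **Edge typing.** Non-covalent contacts form a single edge type rather
  than distance-binned types; the bin scheme would be an extra free
  parameter with no principled default at these problem sizes.
* **Attention granularity.** Self-attention operates over the three
  modality tokens (balancing whole representations), not over individual
  scalar positions of the concatenated vector; with three tokens the
  attention matrix is interpretable as a modality-importance table.
* **Nonstandard residues.** MSE maps to M, SEC to C, anything else is
  dropped with a message; the CTD alphabet requires exactly 20 letters.
* **AltLoc handling.** The first alternate-location variant of each atom
  is kept; occupancy-weighted averaging would blur coordinates feeding
  the distance threshold.
* **Ligand-only readout.** The gather sums over ligand atoms so the
  interaction feature scales with ligand contact surface; a mean readout
  is available (`readout = "mean"`) for collections with very variable
  ligand sizes.
* **Search toolkit.** Hyperparameter search is a seeded uniform random
  search; replayability from a single seed was preferred over adaptive
  samplers with heavier dependencies.

## Known limitations

* Descriptor identities are this package's own frozen registry; other
  toolkits' "196 descriptors" will differ in identity and scale, which is
  why the registry version travels with every model.
* The graph featurization recipe (19 dimensions) is a reconstruction of
  common practice; richer recipes (hybridization, aromaticity flags,
  partial charges) would need chemistry perception that the parser does
  not attempt.
* Training is CPU-only and full-precision; collections beyond a few
  thousand complexes will want larger batch sizes and more epochs than
  the desk-scale defaults.
* Hydrogens are excluded from the graph by default because pocket
  structures rarely resolve them; including ligand-only hydrogens would
  bias the ligand mask and the contact counts.
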