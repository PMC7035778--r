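---
title: "Attentive message passing for molecular property regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentive message passing for molecular property regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
fixture generator does and does not emulate, and the numerical and design
choices made where the method leaves room.

## The chemical graph and its features

A molecule is represented as its heavy-atom graph (hydrogens implicit):
atoms are nodes, every bond contributes **two opposed directed edges**, so
the directed-edge count is exactly twice the bond count. Four index lists
carry the topology — Edge2Node (source/target atom per edge), Node2Edge
(incoming edges per atom), Edge2Revedge (the opposed edge: a fixed-point
free involution), and Node2NeiNode (neighbour atoms). Node2Edge stores
*incoming* edges because that is the direction the readout aggregates.

Atom feature vectors are 139 long: a one-hot over atomic number 1–118
("all known elements", so no unknown bucket is needed), heavy-neighbour
degree buckets 0–5 (counts above 5 are clamped to the last bucket with a
warning — chemically they essentially do not occur in organic sets),
formal charge −2…+2 (clamped likewise), chirality (R, S, unspecified,
unrecognized), hybridization (sp, sp², sp³, sp³d, sp³d²) and an aromatic
flag. Bond vectors are 11 long: order (single/double/triple/aromatic),
ring membership, stereo (none/any/Z/E/cis/trans).

Parsing, canonicalization, aromaticity perception and 2D depiction
coordinates come from OpenBabel (through ChemmineOB); the canonical-SMILES
dialect is therefore OpenBabel's, and duplicate detection in
`cleanDataset()` uses canonical *structure* identity, never raw string
equality, keeping per property the maximum observed value of a duplicate
group. Two toolkit-pragmatic reductions are worth stating plainly:

* **Chirality** buckets are filled from tetrahedral parity in the V2000
  block (parity 1 → "R" bucket, 2 → "S"), not from full CIP priorities,
  which the installed stack cannot compute. Unmarked centres are
  "unspecified".
* **Bond stereo** is assigned only when the input SMILES carries
  directional bonds, and then geometrically from the generated 2D
  coordinates (substituents on the same side of the double-bond axis →
  cis, opposite → trans). Z/E in the CIP sense is not computed, so those
  two buckets stay empty in practice.

Ring membership of a bond is decided by a bridge test (the bond lies on a
cycle iff its endpoints stay connected after removing it), which is exact.

## The encoder

Messages live on directed edges. With `f_x ‖ f_xy` the concatenated
source-atom and bond features (length 150):

$$M_{xy}^{1} = \mathrm{Re}\!\left(W_{inp}\,(f_x \| f_{xy})\right), \qquad
M_{xy}^{d} = \mathrm{Re}\!\left(W_{inp}\,(f_x \| f_{xy}) +
W_h \!\!\sum_{z \in N(x)\setminus y}\!\! M_{zx}^{d-1}\right)$$

$$h_y = \mathrm{Re}\!\left(W_o\left(W_{ah} f_y +
\sum_{z \in N(y)} M_{zy}^{d}\right)\right)$$

Choices made here:

* **Synchronous (Jacobi) updates.** All edges advance from the complete
  `M^{d−1}` simultaneously; the "x may only send to y after hearing from
  all neighbours except y" gating is satisfied because every `M^{d−1}` is
  available when `M^d` is formed. The excluded-neighbour sum is computed
  as (all messages into x) minus the reverse message — O(edges) with a
  sparse incidence matrix rather than O(edges²).
* **No bias terms** in the four encoder products — the equations are pure
  matrix products. (The head layers do carry biases.)
* **Activations**: ReLU default; Tanh, ELU, LeakyReLU, PReLU, SELU are
  selectable to cover the hyperparameter grid. PReLU uses a *fixed* slope
  of 0.25 rather than a learned one — the grid needs the choice to exist,
  and a learnable per-channel slope is out of proportion for this engine.
* **Dropout placement**: the description lists a dropout rate but not its
  location; here it is applied to messages after each activation and to
  head activations, during training only (inverted dropout).
* Everything runs in 64-bit doubles (R's native numeric). The test suite
  pins the vectorized encoder against an explicit-loop brute-force
  implementation of the three equations at 1e-10 on all generated
  molecules with ≤ 6 atoms.

After depth *d*, `h_y` summarizes the radius-*d* neighbourhood of atom *y*
— the locality test in the suite verifies that edits at graph distance
> *d* leave `h_y` bit-for-bit unchanged.

## The self-attention readout

$$W_{att} = \mathrm{softmax}(G\,G^{\mathsf T}), \qquad E_G = W_{att}\,G$$

* The softmax is row-wise and **unscaled** — no 1/√H factor — following
  the readout equation exactly as displayed rather than the scaled transformer
  convention. There are no learned query/key/value projections and no
  multiple heads; `G` attends to itself directly.
* The molecule latent vector is the arithmetic mean (global average
  pooling) over atoms of `G + E_G`, not a sum.
* An atom's **weight score** is defined as the mean of its *column* of
  `W_att` — the attention the atom receives. The source description does
  not fix rows versus columns; both are implemented
  (`attentionCoefficients(..., aggregate = "row")`), column-mean is the
  documented default, and exports record the choice. The coefficient is
  the score minus the molecular mean, so coefficients always sum to zero.
* In batched forward passes the attention is computed per molecule block:
  atoms never attend across molecules (asserted in the suite).

The MPN ablation replaces this stage with plain average pooling of `G`;
every other configuration stays identical, which is what makes the
SAMPN-vs-MPN comparison an ablation of the attention mechanism alone.

## Training

Targets are z-scored per property on training-partition statistics (the
standard choice for these regressors); the loss is MSE on the normalized
scale, masked to the observed entries for multi-target data; metrics are
always reported on the original scale. Optimization is Adam (β₁ 0.9, β₂
0.999) under a warm-up/decay schedule: linear warm-up over 2 epochs from
`initLR` to `maxLR`, then exponential decay to `finalLR` at the last step.

Defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| hidden size H | 64 | enough capacity for fixture-scale studies; grid spans 32–512 |
| depth d | 3 | radius-3 substructures; grid spans 2–6 |
| activation | ReLU | the readout equations' stated nonlinearity |
| FFN layers | 2 | one hidden layer lets the head model interactions of latent features; grid spans 1–3 |
| dropout | 0 | the fixture studies are small and under-, not over-fitted |
| epochs / batch | 30 / 50 | not intrinsic to the method; engineering choices, CLI-exposed |
| initLR → maxLR → finalLR | 5e-4 → 5e-3 → 5e-4 | see below |

The peak learning rate deserves a note: with a few hundred training
molecules and batch 50, a full training run is only ~100–300 gradient
steps, and a 1e-3 peak (the convention inherited from large-corpus
property predictors) demonstrably underfits — the training loss is still
descending steeply when the budget ends. The package therefore defaults to
a 5× larger schedule with the same warm-up/decay shape; all five schedule
numbers remain configurable, and users fitting thousands of molecules for
many epochs may prefer the smaller classical values.

The best checkpoint is selected by validation RMSE (the same criterion the
grid search ranks by). Runs are deterministic given the seed: weight
initialisation (Glorot uniform), per-epoch shuffling and dropout all
derive from it. Output layers are initialised per output unit, filled
row-by-row, so a K-target head nests the K=1 head — a multi-target model
with one property fully masked reproduces the single-target run's
first-epoch loss exactly, which the suite asserts at 1e-6.

## Evaluation protocol

Stratified k-fold cross-validation for a *continuous* target is read, as
is standard for regression, as quantile binning: records are split into 10
quantile bins, each bin is shuffled and divided into k near-equal chunks;
fold f takes chunk f as test, the cyclically next chunk as validation, and
the rest as training — ~80/10/10 for k = 10 with every record tested
exactly once. Each experiment repeat re-splits with its own seed (whether
the original protocol re-randomized bins per repeat is unstated; re-split
is the conservative reading). Train/test partitions share no canonical
structure by construction, since splitting follows deduplication.

The grid search enumerates the lattice {Tanh, ELU, LeakyReLU, ReLU, PReLU,
SELU} × depth 2–6 × hidden 32–512 (step 32) × dropout 0.0–0.4 (step 0.05)
× FFN 1–3, samples a user-set budget of distinct points, and returns the
argmin of validation RMSE with the full trial table. Exhaustive
enumeration (25 920 points) is supported but not the default.

The classical baseline is a 500-tree random forest on circular
(Morgan-style) fingerprints of fixed length 1024, radius 2 — the
conventional ECFP4-equivalent; length and radius are the field's
customary defaults. No installed R
package emits this fingerprint, so the package implements the standard
iterative neighbourhood-hashing construction directly (initial atom
invariants: atomic number, degree, formal charge, aromaticity, ring
membership; two rounds of sorted (bond-type, neighbour-id) hashing; all
identifiers folded modulo 1024). It is a faithful member of the ECFP
family rather than a bit-for-bit clone of any particular toolkit's hash.

## The synthetic fixture generator

The generator exists so that every stage — cleaning, featurization,
training, cross-validation, attention export — is exercisable without
downloading the real lipophilicity/solubility sets. It assembles molecules
from a fixed fragment grammar: alkyl chains (2–10 carbons), benzene,
pyridine and cyclohexane cores, and a phenyl-alkyl combination, decorated
with hydroxyl, amine, halide, methoxy, nitrile, carbonyl and carboxyl
substituents; everything stays under 30 heavy atoms so the brute-force
encoder oracle stays fast. Substitution rates were set once so that 600
draws yield comfortably more than 300 unique canonical structures (the
deliberate duplicates exercise structure-level deduplication).

The default property is *linear in element counts*,
`y = Σ_e c_e·n_e + ε`, with coefficients (C 0.5, N −0.4, O 0.8, F −0.25,
Cl 0.3, Br 0.9) spanning positive and negative contributions of realistic
magnitude on a log-property scale, and ε ~ N(0, 0.1) from a noise stream
seeded independently of molecule generation. A depth-≥1 network can
represent such a property, and with zero noise an ordinary linear
regression on element counts explains it exactly (asserted in the suite)
— bounding what the network should approach. The secondary property for
multi-target exercises is the ring-atom fraction, observed on a partial,
disjoint missingness pattern so every record keeps at least one target.

What the generator does **not** emulate: real logP/logS value
distributions, activity cliffs, tautomerism, charged species at assay pH,
stereochemistry-dependent properties, or molecules outside the fragment
grammar. Passing the fixture study therefore shows that the machinery
learns a planted, learnable structure–property signal end to end — it
does not certify accuracy on experimental chemistry data, for which the
cross-validation pipeline should be run on real tables via the CLI.

Problem sizes used by the shipped studies: the headline fixture study uses
600 generated molecules (≈330 unique after cleaning), depth 3, hidden 64,
20 epochs, batch 50; the split-protocol checks use a 200-record set; unit
tests use far smaller models. These sizes were chosen to make the full
suite a matter of minutes while keeping the statistics stable.

## Attention heatmaps

`renderHeatmap()` draws the 2D depiction with atoms coloured on a
symmetric diverging scale: the midpoint (white) is exactly coefficient 0
and the endpoints are ±max|c|, so hue encodes sign and saturation encodes
relative magnitude. Raw coefficients are used (no re-normalization beyond
the symmetric scaling), and the legend records the property and sign
convention, which is property-specific: for lipophilicity blue =
lipophilic-increasing and red = anti-lipophilic; for solubility red =
soluble-increasing and blue = anti-soluble. SVG output is deterministic
text (identical input → identical bytes); PNG uses the raster device. For
multi-target models the attention stage is shared, so the same coefficient
vector is rendered per property with that property's colour orientation.

## Known limitations

* Aromaticity, canonicalization and 2D layout follow OpenBabel's models;
  other toolkits will disagree on edge cases (the caffeine canonical
  SMILES famously differs across toolkits).
* Chirality and bond stereo are the reduced forms described above.
* The training engine is plain R on BLAS matrix ops: fine for
  fixture-scale and small experimental sets (thousands of molecules),
  not intended for hundred-thousand-molecule corpora.
* No uncertainty estimation, classification heads, ensembling, 3D
  conformers or reaction SMILES.
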