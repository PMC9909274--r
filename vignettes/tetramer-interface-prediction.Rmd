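---
title: "Predicting chain interactions and interface residue pairs in tetramer protein complexes"
author: "tetraPPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chain interactions and interface residue pairs in tetramer protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraPPI)
```

# The problem

A tetramer protein complex has four chains and therefore six unordered
chain pairs. Two questions arise naturally when its quaternary
structure is unknown: which chain pairs actually touch, and, for a pair
that touches, which residue pairs form the interface. tetraPPI answers
both with a two-stage pipeline: a convolutional classifier on a
chain-pair "feature map" for the first question, and a ranked
under-sampled SVM ensemble on residue-pair descriptors for the second.

Interface ground truth inside the package is defined geometrically:
residue pair (i, j) on two different chains is an interface pair when
its Cα–Cα distance is at most a cutoff (8 Å by default), and a chain
pair interacts when it has at least one interface pair. A distance rule
is the standard surrogate for Voronoi contact-area criteria; with
Cα-only coordinates an 8 Å cutoff approximates heavy-atom contact at
about 5 Å. The cutoff is a plain argument of `labelContacts()`, so any
other convention can be substituted. With only Cα coordinates retained
by the readers, no heavy-atom mode is offered; that would require a
full-atom container this package deliberately does not carry.

# Stage 1: chain matrices, feature maps, CNN

## Change sequences and the 20 × 24 chain matrix

For one amino-acid type x occurring n times in a chain of length L at
positions α₁ < … < αₙ, the position change sequence is the successive
difference sequence; five geometry change sequences do the same to the
per-residue values of ASA, RASA, ECA, ICA and EVA at those positions.
Three degenerate conventions matter and are fixed as follows:

* **n = 1**: the single "change" is the position (or value) minus the
  chain mean of all positions (or of the whole value sequence). This
  keeps a lone occurrence informative about where it sits.
* **n = 0**: the change sequence is the single value 0, and all derived
  statistics are 0, so the matrix row of an absent amino acid is
  exactly zero.
* **Frequency**: F_x is implemented directly as n / L. The length of
  the change sequence is n − 1 for n > 1, so "length + 1 over L" and
  n / L agree there, but the degenerate single-value sequences of the
  n ≤ 1 branches would corrupt a length-based implementation; n / L is
  the reading consistent with the worked example (F = 7/15 for seven
  A's in fifteen residues).
* **Means divide by n**, not by the sequence length n − 1; again the
  convention the worked example fixes (13/7, 8/7).
* **The ratio R_x^i = A_x^i / A_x** is set to 0 when A_x = 0 rather
  than dividing by zero. (A_x = 0 is possible: a lone occurrence
  exactly at the chain's centre position.)

Rows of the chain matrix follow the fixed alphabetical 20-letter order;
columns are F, A, B, M followed by A, B, M, R per property. Any fixed
order would do; this one is frozen so that serialised models and maps
are comparable across runs. Residues with nonstandard names map to `X`,
keep their position (so L and the positions of other letters are
unchanged) but own no row.

## The pair feature map

A chain pair is represented by S = |Q_a − Q_b|, standardised over all
480 entries to zero mean and unit *population* standard deviation —
per sample, not per dataset, so every map carries its pattern rather
than its absolute scale. A constant S (e.g. two identical chains)
standardises to the all-zero map rather than dividing by σ = 0. The
map is symmetric in the chains, matching the unordered chain pair.

## The network

The classifier is intentionally small: 3 × 3 valid convolution (2
kernels by default) → ReLU → 2 × 2 valid convolution (2 kernels) →
ReLU → 2 × 2 max-pool with stride 2 (floor division) → flatten →
fully connected layer → 2 softmax logits, cross-entropy loss, Adam
(0.9/0.999, ε = 1e−8). On the 20 × 24 input the spatial dimensions are
18 × 22, 17 × 21 and 8 × 10; with two kernels the flattened vector has
160 entries. Channels are per-sample feature planes equal to the
kernel count of the layer — batching happens outside the sample, so
the flattened length never depends on the dataset size.

Defaults follow the selected operating point of the original model:
learning rate 0.000801, batch size 128, 20 epochs, decision threshold
0.5, no class weighting. `searchHyperparams()` replaces the original
Bayesian hyperparameter optimisation with a seeded random search over
learning rate (log-uniform in [1e−5, 1e−3]) and kernel counts (1–4 per
layer, the single published kernel count applied to both layers but
configurable independently), selecting by validation AUC with ties
broken toward the smaller model. The 100-epoch cap quoted alongside the
search is treated as the search ceiling and 20 as the selected value.

Networks this small are not free of optimisation pathologies: a small
fraction of random initialisations collapses into a dead basin and
stays above the base-rate loss (the backward pass is
numerical-gradient checked, so this is a property of the loss surface,
not of the code). `cnnConfig(restarts = k)` therefore trains k
independently seeded copies and keeps the one with the best validation
(or training) loss. The default remains a single run; the synthetic
end-to-end tests use three restarts.

# Stage 2: residue descriptors and the SVM ensemble

## 155 sequence features

Five physicochemical scales (hydrophobicity, polarizability, polarity,
secondary-structure propensity, codon diversity) map the sequence to
five value sequences. For each scale and k = 1..10 the forward and
backward k-interval product factors Φ_j Φ_{j∓k} / k and the k-average
cumulation factor (the mean of the 2k+1 values centred at j) are
computed on the *circularised* sequence — the head-to-tail convention
applies to sequence features only. Forward and backward factors are
emitted as two separate features; 5 × (20 + 10) + 5 raw values = 155.
The arithmetic of this count is what fixes the otherwise ambiguous
pairing of the forward/backward definitions.

The shipped default table (`defaultPhyschemTable()`) uses standard
published scales (Kyte–Doolittle, Charton–Charton, Grantham,
Chou–Fasman, synonymous-codon counts); it is an input, not a constant —
every function takes the table as an argument and the unit tests use
explicit fixture tables so correctness never depends on these values.

## 305 structure features

For each residue the other L − 1 residues are sorted by ascending
Cα distance, ties broken by ascending sequence position. For each
geometric property and k = 1..20: the neighbour product factor
φ_j φ_{λ_k} / k, the neighbour cumulation factor (mean over the central
residue and its k nearest), and the weighted value ω_ξ φ_{λ_ξ} with

  ω_ξ = exp(− d_ξ² (k+1) / Σ_{ξ=1}^{k+1} d_ξ²),   k = 20.

Two numerical choices: the exponent uses the scale-invariant
normalisation above (a literal exp(−d²) · (k+1)/Σd² underflows at
protein scale, d ≈ 10–30 Å; both are monotone in d, and the literal
form stays available via `neighborWeights(..., literal = TRUE)`), and
the normalising sum runs over the 21 nearest *other* residues
per central residue — the central residue itself (d = 0) is not a
term. Duplicate coordinates (d = 0) are an error. With
5 × (20 + 20 + 20) + 5 raw values the structure block has 305 features,
and descriptors need at least 21 neighbours, i.e. chains of ≥ 22
residues. Structure features depend on coordinates only through
pairwise distances and are therefore rigid-motion invariant (tested).

A residue pair is the order-sensitive concatenation (chain-1 residue
first) of two 460-vectors: 920 features.

## Under-sampling, ensemble, ranking

Interface pairs are rare (about 1 in 700 candidate pairs in real
tetramer sets), so each of the 10 members trains on all positives plus
an equal number of negatives sampled without replacement within the
set; sets are drawn independently by default (a disjoint mode exists
behind `disjointSets = TRUE`). Members are C-classification SVMs with
an RBF kernel and probability outputs; the kernel width defaults to the
median heuristic on the standardised training union (the original
work states no width), C defaults to 1. Feature standardisation
statistics are fitted on the union of the positives and all sampled
negatives and stored with the ensemble. The fused score is the sum of
member probabilities; the reported score divides by the member count so
it lies in [0, 1] — the ranking, and hence every top-t metric, is
identical under either scale. Candidate pairs are ranked by descending
score with deterministic (chain-1 index, chain-2 index) tie-breaks;
`rankInterface()` returns all candidates with a warning when t exceeds
them.

# Evaluation

Confusion metrics, midrank AUC, the per-complex PT vector
(a, b) = (correct interactions, correct non-interactions) with its L1
norm, the NPIRP 6-vector of true interface pairs retrieved in the top-t
per chain pair with L0/L1 norms, and Accuracy4t = 100 · NCTP / NTP
where NCTP counts complexes with ≥ z interfaces hit and NTP counts
complexes with ≥ z native interfaces. Metrics with zero denominators
are reported as NaN with a warning, never silently as 0. The published
per-complex result tables are shipped as plain-text fixtures and the
aggregation is regression-tested against their printed summary
percentages; the printed denominators are only arithmetically
consistent for z ∈ {1, 2} (NTP = 28), so only those rows are asserted.

# The synthetic generator

`simulateComplex()` builds a complete test complex: four chains with
sequences, Cα coordinates, per-residue property tables and
geometrically recomputed labels. What it emulates, and how:

* **Interaction pattern.** A latent divergence coordinate u_c ∈ [0, 1]
  per chain; a pair is designated interacting when |u_i − u_j| ≤ θ with
  θ = 1 − √f for a target non-interacting fraction f (default 0.2,
  mirroring the sparse non-interactions of real tetramer sets). Draws
  within 0.08 of θ are rejected so every designation has a margin.
* **Sequences.** Chain composition interpolates between a
  hydrophobic-core-rich and a polar-surface-rich pole along u; residues
  are drawn independently from that blend. Interacting (close) chains
  thus have similar composition — the homo/paralog character of most
  real tetramers — which is the planted, learnable stage-1 signal.
* **Geometry.** Chains are compact self-avoiding Cα walks (3.8 Å
  steps, 3.2 Å exclusion) confined to spheres of radius 3.6 L^(1/3);
  sphere centres are stress-embedded to target distances
  0.78 (r_i + r_j) for interacting pairs (enough overlap to touch) and
  r_i + r_j + 6 Å for non-interacting ones (just out of contact range,
  as in real assemblies). The realised complex is kept only if
  `labelContacts()` reproduces the designated pattern with the required
  interface size; otherwise geometry is redrawn (bounded retries).
  Labels are therefore always recomputed, never asserted.
* **Properties.** ICA grows with same-chain packing (neighbours within
  10 Å), ECA with cross-chain packing, ASA falls with burial, EVA falls
  with cross-chain contact; RASA is ASA scaled by per-residue maxima.
  Gaussian noise scales with (0.5 + u): surface-like chains are more
  exposed and more variable. The elevated cross-chain contact of
  interface residues is the planted stage-2 signal — it enters through
  geometry, not through any label leak into the features.
* **Chain lengths** are drawn per chain from 25–60 (the lower end is
  the smallest length the structure descriptors accept).

What it does **not** emulate: real secondary structure, side chains,
realistic interface chemistry, the long-tailed size distribution of PDB
tetramers, or Voronoi contact areas. Passing the end-to-end tests
therefore demonstrates that the pipeline is implemented coherently and
can recover a planted signal of realistic strength — not that it
reaches any particular accuracy on real complexes.

# Problem sizes and frozen test protocols

The end-to-end tests train the CNN on 60 synthetic complexes (360
maps), select on 20 and test on 20, with learning rate 1e−3, 40 epochs
and 3 restarts — a slightly longer schedule than the stage-1 default
because the synthetic maps are a fresh learning problem, not the one
the published operating point was tuned on. The ensemble protocol
featurises 6 training and 3 test complexes and subsamples each chain
pair to at most 40 positives / 80 negatives for training (250 for
testing) before fitting the 10 members; the thresholds asserted are
chain-pair AUC > 0.65 and interface-pair AUC > 0.8. These sizes are the
package's chosen compromise between statistical resolution and a test
suite that runs in minutes on one CPU.

# Known limitations

* Cα-only structure handling end to end; no heavy-atom contact mode.
* The probability calibration of the SVM members is the library's
  internal Platt-style fit; its exact values are backend-dependent,
  which is why seeds are pinned and scores should be compared by rank.
* `searchHyperparams()` is a random search, not Bayesian optimisation;
  with small validation sets its AUC estimates are noisy, so prefer
  larger validation splits over larger budgets.
* The stage-1 classifier sees only per-chain summaries, so its
  information about a *pair* is limited to how the two summaries
  differ; ceiling performance on both synthetic and real data is
  accordingly modest.
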