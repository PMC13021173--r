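---
title: "pepForge: models, parameters and design choices"
author: "pepForge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepForge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pepForge models anticancer peptides (ACPs) — short peptides of 8–50
residues with selective activity against tumour cells — from two sides of
the same fused feature space: a multiclass classifier that assigns a
peptide to one of nine cancer-type classes, and a conditional
denoising-diffusion generator that proposes new candidate peptides for a
chosen class. This vignette documents the models, their tunable
parameters, the numerical choices, and what the bundled synthetic data can
and cannot tell you about behaviour on real data.

## The fused feature space

Every peptide is represented by the concatenation of

* a **1024-dimensional sequence embedding**. The default backend hashes
  overlapping 3-mers into 4096 count buckets and projects them through a
  fixed-seed Gaussian matrix, followed by L2 normalisation. It is fully
  deterministic, needs no model download, and preserves enough local
  composition structure for the desk-scale experiments here. An adapter
  slot exists for a pretrained protein language model producing the same
  1024 numbers (mean-pooled hidden states); when its weights are absent
  the package raises an explicit error rather than silently substituting.
* a **430-dimensional physicochemical descriptor block**: 20 amino-acid
  composition fractions, 400 dipeptide frequencies (row-major over the
  alphabetical residue order), and 10 global properties — length,
  monoisotopic mass, Henderson–Hasselbalch net charge at pH 7,
  isoelectric point, mean hydrophobicity, helical hydrophobic moment,
  Guruprasad instability index, aromaticity, basic-residue fraction, and
  the count of aromatic–basic residue pairs within three positions.

The fused 1454-dimensional vector is standardized per column and reduced
to 200 dimensions by exact-SVD PCA. The reduction is always fitted on
training partitions only and applied to held-out data; component signs
are fixed by making each component's largest-magnitude loading positive
so that refits are bit-reproducible.

### Ionization constants

The net-charge model sums `1/(1+10^(pH−pKa))` over basic groups
(N-terminus, H, K, R) and subtracts `1/(1+10^(pKa−pH))` over acidic
groups (C-terminus, D, E, C, Y). The default constants (N-terminus 8.0,
C-terminus 3.1, D 3.65, E 4.25, C 8.3, H 6.0, Y 10.07, K 10.5, R 12.5)
reproduce the reference charges of the published example peptides to two
decimals; they are exposed through `defaultPKaSet()` and every charge
function accepts a replacement set. The isoelectric point is found by
bisection on (0, 14); the charge is strictly decreasing in pH and the two
termini guarantee a sign change, so the root is unique. Bisection stops
at `|charge| < 1e-4`.

Hydrophobicity defaults to the Eisenberg consensus scale (Kyte–Doolittle
is bundled as an alternative). The published per-peptide "H" values could
not be attributed to either standard scale, so mean hydrophobicity and
hydrophobic moment are reported as configurable quantities rather than
asserted against the printed table.

## The noise-conditioned classifier

Reduced features are reshaped to single-row grids `(B, 8, 1, 25)` and
pass through a multiscale attention block (MECS):

1. *global perception* — a 1×1 convolution with GELU;
2. *channel attention* — mean, max and median pooling over spatial
   positions, a shared Conv–ReLU–Conv bottleneck (reduction ratio 4),
   sigmoid per branch, branch sum (so every weight lies in (0, 3));
3. *spatial attention* — a 5×5 depthwise convolution feeding three
   asymmetric depthwise pairs (1×7·7×1, 1×11·11×1, 1×21·21×1), summed; a
   1×1 convolution forms the spatial map that gates the channel-weighted
   features before the output 1×1 convolution.

The displayed form of the fusion equation nests the output convolution
outside the product of the spatial map with the channel-enhanced
features; the prose around it swaps the two weight symbols, and we follow
the displayed equation. Median pooling uses the lower median on even
counts; all convolutions zero-pad to preserve spatial dims and carry
zero-initialized biases.

The encoded features are projected to a 64-dimensional state and summed
with (i) a learned cancer-type embedding and (ii) a linear projection of
a sinusoidal embedding of a stochastic time scalar `t ~ U(0,1)` drawn per
minibatch — a diffusion-inspired regularizer that perturbs the feature
space during training. Because the class label is unknown at prediction
time, a dedicated null-condition row is learned and substituted for the
true label with probability 0.2 during training; inference always uses
the null condition with `t = 0`, making predictions deterministic. The
backbone is `y = F(x) + Σ w_i G_i(x)` with a residual MLP `F`, parallel
feature-axis convolutions `G_i` at kernel sizes 3/5/7 and learnable
scalar fusion weights, followed by a 9-way softmax head.

Training is stratified K-fold (default 5): per fold the PCA is refitted
on the training split, the reduced training features are SMOTE-balanced
(each synthetic point interpolates a sample toward one of its five
same-class nearest neighbours), and the network is trained with Adam on
class-weighted cross-entropy, the weights inversely proportional to the
*pre-balancing* class frequencies and normalized to mean 1. Early
stopping monitors validation macro-F1 with patience 10, and the
best-validation fold's parameters are retained.

SMOTE has two plausible homes — inside each minibatch or once per
training split. We apply it once per fold before batching: it keeps the
neighbour pools stable, makes runs reproducible, and the balanced stream
the network sees is equivalent in expectation.

**Learning rate and batch size.** The Adam step size defaults to 1e-2
with minibatches of 32. At the dataset sizes this package targets
(hundreds of peptides, a handful of minibatch updates per epoch) a 1e-3
rate repeatedly converged to visibly worse validation macro-F1
(≈0.81–0.85 against ≈0.93–0.97 on identical folds), and halving the
batch from 64 lifted every fold's validation score by giving the
optimizer twice the updates per epoch. Both knobs remain exposed in
`classifierConfig()`.

All gradients come from a small reverse-mode tape implemented in the
package (dense layers, the two convolution families, the pooling and
broadcast operations, softmax cross-entropy and MSE); the forward
operations used in training are the same code paths exposed as public
functions, and the test suite checks the tape against central finite
differences.

## The conditional diffusion generator

The generator diffuses in the 420-dimensional composition+dipeptide
subspace of the descriptor block (standardized internally). This is a
deliberate reconstruction decision: those two blocks are the only part of
the feature vector that can be inverted to sequences — the composition
block yields an initial-residue distribution and the dipeptide block a
first-order Markov transition matrix — so the decode step is an honest
inverse of the representation rather than a black box.

The forward process is the standard variance-preserving one:
`x_t = √(ᾱ_t)·x₀ + √(1−ᾱ_t)·ε` with a linear β schedule from 1e-4 to
0.02 over T = 1000 steps. The denoiser predicts ε with an MSE loss; per
optimizer step each sample draws its own uniform timestep. Conditioning
is scale-and-shift per channel: the sinusoidal time embedding maps to a
per-channel gain `1 + γ(t)` (γ zero-initialized, so conditioning starts
as the identity) and shift `β(t)`, to which a learned label embedding is
added. The output linear layer is zero-initialized, so the untrained
network predicts zero noise and the initial loss sits at the analytic
level E‖ε‖²/D = 1 — a property the tests assert. In line with the
residual-backbone design, a time-gated linear skip runs from the noisy
input to the output (gate zero-initialized): the proportional component
of the optimal noise prediction is then directly representable instead of
having to be synthesized through the attention stack, which measurably
removes a sampling-time mean bias. The returned weights are the Polyak
average over the last 30% of optimizer steps, suppressing minibatch
jitter in the learned bias terms — without it the generated sample mean
wanders by several times the Monte-Carlo floor.

Inside the denoiser, the **BFM** applies parallel channel-mixing 1-D
convolutions (kernels 3/7/15) over the conditioned map and adds them to a
residual connection. The **TFAM** fuses two temporal states — here the
conditioned input map and the BFM output, since the model operates on 1-D
peptide features rather than images — through ReLU-activated convolutions
at kernels 3/5/7, channel attention (spatial mean+max descriptors of both
branches through two parallel 1-D convolutions, softmaxed *across the two
branches*) and spatial attention (channel mean+max maps through two
identical 2-D convolutions, softmaxed the same way). The fusion
coefficients `β_i = 1 + α_c(i) + α_s(i)` therefore satisfy
`β₁ + β₂ = 4` everywhere, an identity the test suite checks for random
parameters. Choosing the softmax across branches (rather than within a
map) is what makes that conservation identity hold and matches the paired
bracket notation of the defining equations.

Sampling is a deterministic first-order ODE update on a uniform log-SNR
grid (default 25 steps against T = 1000, well within the "several-fold
fewer steps" regime), closed by an x₀-prediction step that removes the
residual noise floor at the final knot. Written in `(α, σ)` form the
update is `x_s = (α_s/α_t)·x_t − σ_s·(e^h − 1)·ε̂` with `h` the log-SNR
increment; with an exact denoiser for a point mass this recovers x₀ to
machine precision, which the tests assert. (An equivalent formulation
published with a sign flipped on the ε̂ term fails that exactness check;
we use the form that passes it.)

Decoding clamps negative recovered probabilities to zero, adds 1e-3
additive smoothing, renormalises, draws the length uniformly from
[8, 50], and samples the Markov chain. All-zero recovered blocks fall
back to uniform distributions with a warning. Mixed precision is not
implemented: R's numeric vectors are double precision throughout, and at
these model sizes there is nothing to gain.

## Screening

The novelty scan runs an affine-gap Smith–Waterman (Gotoh recurrences,
BLOSUM62, gap open 11 / extend 1, a gap of length L costing
`open + L·extend`) of every candidate against a reference set. Traceback
ties break deterministically (diagonal over up over left; the best cell
closest to the origin). Identity/positive/gap percentages are computed
over aligned columns including gaps. A candidate is flagged as a
near-duplicate when a gapless full-length alignment reaches 90% identity
(boundary inclusive). E-values are deliberately not computed — they
belong to database-search statistics out of scope here.

Motif summaries count K/R and W/F/Y residues and grade aromatic–basic
proximity (window of 3 positions; "present" at one pair, "strong" at two
or more — a calibration that reproduces the qualitative labels of the
published example peptides). The helical wheel places residue *k* at
`(100·k) mod 360` degrees with residue-class annotations, and the
amphipathic moment reported with motifs is the best hydrophobic moment
over 11-residue windows.

## Synthetic data: what it emulates, and what it does not

`syntheticSpec()` mirrors the nine-class structure of the reference
dataset: the default per-class counts are the published class sizes
scaled by one half (55, 184, 116, 114, 53, 56, 144, 64, 86), preserving
the >3:1 majority-to-minority imbalance; lengths are uniform on [8, 50];
each class draws residues i.i.d. from a composition bias putting 55% of
the mass on a class-specific residue pair, with a `separability` knob
that mixes the bias toward uniform. Classes are therefore learnably
separable by construction — the nearest-centroid oracle on standardized
features exceeds 0.95 on held-out splits — and the classifier acceptance
threshold (macro-F1 ≥ 0.90) is calibrated against that oracle.

Passing these tests demonstrates that the pipeline machinery — fusion,
attention, rebalancing, conditioning, training, sampling, decoding — is
correct and internally consistent. It does **not** demonstrate
state-of-the-art accuracy on real ACP data: real peptides carry
positional motifs, phylogenetic correlations and label noise that i.i.d.
composition biases cannot imitate, and the k-mer hash embedding is not a
pretrained language model. Conclusions about real-data performance
require the real dataset and, ideally, the pretrained embedding backend.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the classifier on 540
synthetic peptides (60 per class, 3 folds, 60 epochs) and the generator
at 120–1500 optimizer steps depending on feature dimensionality; these
sizes were chosen so the whole suite completes comfortably on a single
CPU while leaving every statistical margin (CLT bounds, Monte-Carlo
tolerances) intact. Degenerate inputs are handled explicitly: length-1
sequences have an all-zero dipeptide block and zero instability index;
zero-variance feature columns standardize with unit scale; empty
alignment inputs score 0; single-class or single-sample training sets are
rejected with explicit errors rather than silently clamped.

## Known limitations

* The fallback embedding is a random-projection hash, not a semantic
  model; swap in the pretrained adapter for real studies.
* The Markov decoder captures first-order composition statistics only;
  generated peptides inherit no long-range structure.
* Diffusion operates on descriptor statistics, so two sequences with
  identical composition and dipeptide profiles are indistinguishable to
  the generator.
* The classifier's condition-dropout calibration (0.2) follows the
  framework design; it has not been re-tuned here.
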