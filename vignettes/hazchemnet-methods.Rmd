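---
title: "Methods: feature construction, model architecture and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature construction, model architecture and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hazchemnet` classifies chemical compounds as hazardous or non-hazardous
from their SMILES structure. This vignette documents the science and the
engineering decisions: how molecules become feature vectors, what the
network computes, how training and evaluation are organized, and what the
synthetic fixtures do and do not demonstrate.

## Molecular representation

Each molecule is encoded as a 516-dimensional vector: a 512-bit circular
(Morgan-style) fingerprint followed by four physicochemical descriptors,
in fixed order — molecular weight (g/mol), computed octanol–water logP
(unitless), hydrogen-bond donor count, hydrogen-bond acceptor count. The
fingerprint captures local topology (every atom's bonded neighborhood up
to radius 2 bonds); the descriptors summarize global properties associated
with bioavailability and bioaccumulation.

SMILES handling and descriptor computation go through OpenBabel (via
**ChemmineOB**/**ChemmineR**). Every input is canonicalized before
featurization, so different spellings of the same molecule yield identical
features. Invalid SMILES are never imputed or silently dropped: they
become typed rejection records carrying the reason, and dataset-level
featurization continues past them. Multi-fragment inputs (salts,
counter-ions) are featurized as given and flagged; no fragment stripping
is attempted, since the correct convention depends on the upstream data
source.

The circular fingerprint is implemented in the package by iterative
neighborhood hashing. Atom identifiers are initialized from
order-invariant properties (atomic number, heavy-atom degree, attached
hydrogens, formal charge, ring membership — ring perception by
biconnected components via **igraph**); at each radius an atom's
identifier is rehashed together with the sorted (bond order, identifier)
pairs of its neighbors; every identifier produced at any radius sets bit
`id mod 512`. Two consequences worth knowing:

* the fingerprint is deterministic and atom-order invariant, which the
  test suite checks with equivalent SMILES spellings;
* bit positions are internal to this implementation. Hashed fingerprints
  are never comparable bit-for-bit across toolkits, so no cross-toolkit
  bit equality is claimed anywhere; regression tests freeze popcounts of
  this implementation.

OpenBabel's logP is a Wildman–Crippen-type model; for some chemotypes
(notably amines) it differs from other toolkits' implementations by a few
tenths. Donor/acceptor counts use OpenBabel's HBD/HBA1 definitions.

## Standardization

All 516 features — binary bits included — are z-scored. The parameters
(per-column mean and **population** standard deviation, denominator
`n`) are fitted on the training split only and applied unchanged to
validation, test and external data; fitting on anything wider would leak
test-set statistics into the model. Zero-variance columns, which are
common because many fingerprint bits are never set in a modest training
set, get `sd = 1` so they standardize to a constant 0 instead of NaN;
their positions are recorded in the standardizer object.

## Architecture

**Attention autoencoder.** For an input `x` (516 standardized values):

* encoder: `h1 = ReLU(W1 x + b1)`, `z = ReLU(W2 h1 + b2)`;
* attention: `u = tanh(Wa z + ba)`, `alpha = softmax(u)` over the latent
  dimensions, `z' = alpha * z` element-wise;
* decoder: `x_hat = W4 ReLU(W3 z' + b3) + b4`.

The decoder consumes the attention-weighted code `z'`, not the raw `z`,
so reconstruction pressure flows through the attention head. The decoder
output layer is linear because standardized inputs are signed. The
autoencoder loss is the mean squared error over all samples and feature
dimensions.

**Mixture of experts.** `M` independent feed-forward experts process
`z'`; each ends in a sigmoid, so every expert emits a probability
`y_m`. A linear gating network produces `M` scores whose softmax gives
weights `g_m`, and the model output is the convex combination
`y = sum_m g_m y_m` — always inside `[min_m y_m, max_m y_m]`, hence a
valid probability. The classification loss is binary cross-entropy on
`y`.

Both softmaxes are computed with max subtraction and are overflow-free
for any finite input; attention weights and gating weights each sum to 1
to within 1e-12, which the suite asserts on randomized inputs.

## Training schedule

Training is two-stage, mirroring the two separate loss curves the model
produces:

1. the autoencoder is trained on reconstruction MSE (default 120 epochs,
   by which point its loss curve has stabilized);
2. the encoder and attention are frozen, and the mixture of experts is
   trained on the resulting `z'` codes (default 100 epochs).

An optional third stage (`fine_tune = TRUE`) propagates the
classification gradient jointly through encoder, attention, gating and
experts; it is off by default so the reported behavior is that of the
staged protocol.

The optimizer is Adam (learning rate 1e-3, batch size 64). Weights are
initialized Glorot-uniform; biases start at zero. Layer sizes default to
hidden 256, latent 64, expert hidden 32, `M = 4` experts — modest
capacity for 516 inputs and a few thousand samples; all of these are
config-exposed and validated, and unknown config-file keys are an error
rather than a silently ignored typo.

Every source of randomness (initialization, shuffling, fold assignment,
synthetic data) derives from one master seed through named sub-streams
(`derive_seed`), so any component can be reproduced in isolation and two
runs with the same master seed produce byte-identical reports. Epoch 0 of
every loss trace is the untrained network's loss, so convergence can be
measured against a genuine pre-training baseline. A non-finite loss
aborts training with a diagnostic rather than propagating NaNs.

### Numerical corner cases

* Binary cross-entropy clamps probabilities to `[1e-12, 1 - 1e-12]`.
* ReLU subgradient at exactly 0 is taken as 0. The gradient-check tests
  randomize biases away from zero because at an exact kink a finite
  difference and a subgradient legitimately disagree.
* Probability exactly at the decision threshold (default 0.5) is
  classified hazardous (`>=`), the recall-favoring convention appropriate
  for a screening tool.
* A single-class training set is an error, not a degenerate fit.

## Evaluation protocol

**Splitting.** The canonical split is 7:2:1 train/validation/test with
largest-remainder rounding, so 5140 records give exactly 3598/1028/514.
Splitting is stratified by label (the hazard datasets of interest have a
positive:negative ratio near 0.9, i.e. mild imbalance); stratification
allocates per class by largest remainder under the constraint that the
global set sizes hold exactly.

**Cross-validation.** The package also implements stratified 5-fold
cross-validation in which each fold is trained independently 5 times with
fresh derived seeds. Reported are per-fold mean ± SD over the repeats and
the overall mean ± SD over all 25 runs; the overall mean is exactly the
arithmetic mean of the run-level metrics, and the SD of a single repeat
is reported as 0. The two protocols (7:2:1 and k-fold) are independently
invokable and are not mixed: cross-validation operates on whatever rows
it is handed, and a held-out test portion can be carved out first with
`split_dataset` when both are wanted.

**Metrics.** Accuracy, precision, recall and F1 come from the confusion
counts at the decision threshold; F1 is the harmonic mean of the reported
precision and recall (asserted to 1e-9 on every emitted report). AUC is
computed by the Mann–Whitney rank statistic with midranks, so a constant
score gives exactly 0.5. Quantities with empty denominators (no actual
positives, no predicted positives, one-class AUC) are reported as `NA`
with an explicit `undefined` flag, never silently zeroed. Percent tables
are formatted as "mean ± SD" with one decimal.

**Ablation.** Six variants — full, minus each descriptor, minus the
whole fingerprint block — are retrained with identical seeds and
evaluated on the same held-out test rows, so metric deltas isolate the
contribution of the removed block.

**External validation.** A trained model is applied to two lists of
never-seen compounds with known class; the runner reports per-class
accuracy, the false-negative rate on the hazardous list and a
per-compound verdict table, featurizing with the model's training-set
standardizer (the only leakage-free choice). Unfeaturizable compounds
are excluded from denominators with a warning.

## Synthetic fixtures: what they emulate and what they do not

The package ships two generators so the entire pipeline and test suite
run with no external data.

`generate_synthetic_features` emits two Gaussian classes separated by a
configurable shift on a configurable set of dimensions, with the first
512 columns binarized by thresholding to mimic fingerprint bits. The
defaults — 250 samples per class, separation 3 (in noise-SD units) on 20
random dimensions, unit noise, binarization threshold 1 — were chosen
once as a clearly separable but non-trivial problem that trains in
seconds; separation 0 is an exact no-signal control. The generator's
calibration (empirical class-mean difference equal to the requested
separation within 3 standard errors on the pre-binarization scale) is
itself under test. For the planted-signal ablation analysis the signal is
placed on a single named descriptor column (NumHDonors) with the
fingerprint block thresholded into near-constant bits, so removing that
descriptor is the only way to destroy the signal.

`generate_synthetic_smiles_table` samples, with replacement, from a
curated pool of 48 real molecules (industrial solvents, reactive
intermediates and recognized toxics versus sugars, polyols, amino acids
and mild metabolites) at a default positive:negative ratio of 0.9,
mirroring a mildly imbalanced screening inventory. Every pool molecule
parses, so featurization of a generated table yields zero rejects.

What passing on these fixtures shows: the featurization geometry, the
optimization machinery, the metric arithmetic and the evaluation harness
all behave as specified, and the model reliably learns genuinely
separable structure while staying at chance on shuffled labels. What it
does not show: performance on real hazard inventories. Real chemical
classes are not Gaussian, fingerprint bits are correlated in
structure-specific ways, and hazard labels encode regulatory judgment as
well as chemistry. Accuracy bands obtained on real data depend on
hyperparameters this package exposes but cannot infer; with a real
compound table supplied in the documented CSV schema, the
cross-validation report reproduces the structure (five metrics, mean ±
SD per fold and overall) at whatever level the data supports.

## Problem sizes used by the shipped analyses

The test suite and the acceptance script train at deliberately reduced
scale — hidden 64, latent 16, expert hidden 16, 4 experts, 40 + 60
epochs, 600 synthetic samples for cross-validation and 400 for the
ablation study — sizes chosen so the complete battery of property,
learning and reproducibility checks runs in a few minutes on one CPU
while still exercising every code path at full feature dimension (516).
The package defaults remain at full capacity.

## Known limitations

* Fingerprint bit positions are implementation-internal; models and
  feature matrices are not interchangeable with those of other
  fingerprint implementations.
* OpenBabel descriptor values (logP especially) differ from other
  toolkits for some chemotypes; a model should be applied to features
  produced by this package's own featurizer.
* No salt/counter-ion normalization; multi-fragment inputs are flagged
  but featurized as-is.
* Class imbalance handling is limited to stratified splitting; no
  reweighting or resampling is implemented.
* The attention mechanism weights latent dimensions, not input features,
  so per-feature attributions require the ablation harness rather than a
  direct read-out of `alpha`.
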