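---
title: "Methods: outer-product fusion networks for imbalanced bimodal drug data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outer-product fusion networks for imbalanced bimodal drug data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its synthetic
data generator, and the design decisions taken where the problem left the
design open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem and the data model

Predicting whether a drug candidate will pass clinical trials is treated
as binary classification on a bimodal feature vector: a chemical modality
$x^{(1)} \in \mathbb{R}^{13}$ (10 molecular properties such as molecular
weight, XLogP, polar surface area, plus the Lipinski, Veber, and Ghose
rule outcomes encoded as three binary features) and a target-based
modality $x^{(2)} \in \mathbb{R}^{34}$ (median expression of the drug's
gene targets in 30 tissues, network degree and betweenness of the target,
its loss-of-function mutation frequency, and a target count). The label is
1 for approved and 0 for failed drugs. The reference table has $n = 828$
drugs split 757:71, an imbalance ratio of 10.662, and a handful of missing
values confined to six features; the package consumes such tables through
`read_feature_table()` + a JSON schema and never computes the features
itself.

## OPCNN

The outer-product CNN embeds each modality with one fully connected ReLU
layer into $\mathbb{R}^{50}$ and fuses the embeddings with the augmented
outer product

$$x_f \;=\; \begin{bmatrix} f^{(1)} \\ 1 \end{bmatrix} \otimes
\begin{bmatrix} f^{(2)} \\ 1 \end{bmatrix}
\;=\; \begin{bmatrix} f^{(1)} \otimes f^{(2)} & f^{(1)} \\
{f^{(2)}}^{\mathsf T} & 1 \end{bmatrix} \in \mathbb{R}^{51 \times 51},$$

which carries all pairwise cross-modality products *and* both raw
embeddings in one matrix. The matrix is treated as a one-channel image and
passed through three residual blocks (three 3×3 convolutions each, 32
kernels, stride 1), then flattened into an FC(100)–FC(50)–FC(1) head with
a sigmoid output — 5 FC and 9 convolutional layers, verified structurally
by `model_audit()`.

Residual-block internals are not fully determined by a block diagram, so
the package fixes the minimal standard pattern consistent with the stated
counts: 'same' padding throughout (the map stays 51×51), ReLU after each
of the first two convolutions, an identity skip — replaced by a 1×1
convolution exactly where the channel count changes (1 → 32 in the first
block) — and ReLU after the addition. No pooling layers are used; the
flattened 51·51·32 tensor feeds FC(100) directly. The split of the three
head widths (100, 50, 1) is a logged, configurable choice
(`opcnn_config(head = ...)`).

## The DMNN comparison family

`build_dmnn()` covers fusion at three levels with five operators:

* **early**: each modality through FC(50)+ReLU, fuse, then
  FC(100)–FC(100)–FC(50)–FC(1);
* **intermediate**: per-modality FC(100)–FC(100)–FC(50), fuse, then an
  FC(100)–FC(50)–FC(1) head (the post-fusion widths are a logged choice —
  only the per-modality stacks are fixed). For the high-dimensional TFL
  and MCF operators the branches shorten to FC(100)–FC(50);
* **late**: full per-modality stacks whose penultimate representations are
  concatenated into FC(1). Only concatenation is supported at this level;
  joining at the probability level (averaging the two branch sigmoids) is
  available as `late_join = "average_proba"`, but the penultimate
  concatenation is the default because the decision-level graph is
  ambiguous about the join point.

The operators are `addition`, `product`, `concat`, `tfl` (the augmented
outer product flattened row-major — the order is immaterial to the
following dense layer but pinned for reproducibility), and `mcf`.
Multimodal circulant fusion projects both embeddings to dimension
$d \le 50$ ($v = W_1 f^{(1)}, c = W_2 f^{(2)}$), builds circulant matrices
$A = \mathrm{circ}(v), B = \mathrm{circ}(c)$, and lets the vectors
interact either by matrix product ($f = Ac, g = Bv$) or by the averaged
elementwise product of circulant columns; the output is
$m = W_3(f + g)$. Both interaction variants are implemented and are *not*
numerically equivalent; `matmul` is the default and $d = k = 50$ (no
information loss within the stated $d \le 50$ constraint). The circulant
convention is $A_{ij} = b_{(i-j) \bmod d}$ — first column equal to the
generating vector, the standard definition; the transposed convention is a
flag of `circulant()`. A useful identity the tests pin: the column average
of $\mathrm{circ}(v)$ columns elementwise-multiplied with $c$ collapses to
$\bar v \cdot c$, because every row of a circulant matrix contains each
entry of $v$ exactly once.

## Training

All networks minimise the class-weighted binary cross-entropy (computed
from logits in the numerically stable softplus form) with Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e−8). Defaults: learning rate 1e−3, batch
size 32, up to 200 epochs with early stopping once the epoch training
loss has not improved by 1e−6 for 20 epochs. These optimisation
hyperparameters are package choices — the protocol tunes the learning
rate per model, and the cross-validation harness records the values used
in its report metadata. Initialisation is He-scaled Gaussian under an
explicit seed; two builds with the same config are bit-identical, and
training is deterministic given the seeds and a fixed BLAS thread policy.

Feature scaling: per-feature z-scoring fit on the training fold, applied
to both modalities before the embeddings (`scale = TRUE` in
`cross_validate()`). Raw heterogeneous units (molecular weight vs binary
rule outcomes) train poorly through shared dense layers; a `scale = FALSE`
switch disables it and the policy is logged in every CV report.

## Class imbalance

Three strategies, named as in benchmark reports: `base` (nothing), `cw`
(cost-sensitive weights $w_+ = n/2n_+$, $w_- = n/2n_-$, which equalise the
loss mass of the two classes), and `smote_cw` (SMOTE to a target
minority/majority ratio of 1, then weights re-derived on the augmented
counts — whether to re-derive or reuse was unstated, re-deriving is the
logged default). SMOTE uses $k = 5$ neighbours (the canonical choice),
interpolates both modalities jointly in the z-scored concatenated
47-dimensional space to preserve cross-modality correlation of synthetic
rows, and does not re-round the binary rule columns (the models consume
them as reals; a rounding post-step would distort the interpolation
geometry). SMOTE runs strictly inside each training fold, after
imputation and scaling were fit on the fold's real rows.

## Evaluation protocol

Stratified k-fold cross-validation (default k = 10) repeated 20 times.
Folds are stratified by label with per-class and global fold sizes
differing by at most one. Within each fold, imputation medians, scaling
statistics, and SMOTE neighbours come from training rows only — the
harness asserts at every fit that training and test indices are disjoint.
Held-out predictions of the 10 folds are pooled before computing one
metric set per repeat: fold-level confusion counts on ~7 negatives are
too unstable to average (a `pool = "per_fold"` option exists). Metrics
undefined in a repeat (a degenerate fold composition) are dropped with a
logged count, never imputed as zero. Model comparison uses two-sided
Welch t-tests on the 20 repeat-level values against the best model per
metric (`*`, `**`, `***` for p < 0.05, 0.01, 0.001, strict inequalities);
the flavour of the t-test was unspecified, Welch is the logged default.
Imputation defaults to the training fold (`impute = "fold"`); a
whole-table `impute = "global"` switch reproduces single-pass behaviour
at the cost of mild leakage.

Degenerate-input conventions, all oracle-pinned in the tests: precision or
recall with an empty denominator is 0; MCC with a zero factor under the
root is 0 (this makes a constant-majority classifier score exactly MCC 0
and accuracy equal to prevalence, 757/828 ≈ 0.914); AUC uses midranks for
ties; AUPRC uses step integration, not trapezoids, which would
systematically overestimate precision–recall areas; hard labels come from
thresholding the sigmoid at 0.5.

## The synthetic generator

`generate_bimodal()` emulates the statistical structure of the drug table
without reproducing its marginal distributions. Per sample, latent factors
$u, v \sim \mathcal N(0, I_4)$ generate the modalities through fixed
random loadings ($x^{(1)} = A_1 u + \varepsilon$,
$x^{(2)} = A_2 v + \varepsilon$, noise sd 0.5), and the label follows

$$\mathrm{logit}\; p \;=\; \alpha + \beta_u (w_1^{\mathsf T} u +
w_2^{\mathsf T} v) + \beta_{uv}\, u^{\mathsf T} v .$$

The interaction term $u^{\mathsf T} v$ is the designed cross-modality
signal: it is exactly the kind of pairwise product the augmented outer
product represents, so the generator is a fair but non-trivial probe of
the fusion mechanism — a unimodal model sees almost none of it (only the
weak $\|u\|$ dependence that survives marginalisation). The intercept
$\alpha$ is calibrated by bisection against one fixed uniform vector so
the realised class split matches the requested imbalance ratio exactly
(the count is a monotone step function of $\alpha$); calibration was
preferred over post-hoc subsampling because it preserves the feature
distribution conditional on class. Defaults: latent dimension 4, noise sd
0.5, 2% missingness in six designated columns (three per modality),
mirroring the real table's sparse missingness. `oracle_bayes_auc()`
Monte-Carlo-estimates the AUC of the true posterior score, an upper bound
for any learner on this generator, with a Hanley–McNeil standard error.

What passing on this generator does *not* show: the synthetic features
have Gaussian marginals and a linear factor structure, unlike the real
table's heavy-tailed expression medians and binary rules, so test results
demonstrate mechanism recovery, not real-data performance.

## The packaged interaction benchmark

`interaction_benchmark()` encodes the package's headline experiment:
n = 2000 samples at imbalance ratio 10, interaction strength 3, no
unimodal signal, 2-fold CV repeated 20 times, plain BCE. Because a
full-width OPCNN forward/backward pass over 51×51×32 maps is far too
expensive for a repeated-CV protocol on one CPU, the benchmark runs every
architecture at a common reduced width — OPCNN with embedding 16, 8
kernels, FC(64)–FC(32)–FC(1) head; the concatenation DMNN and the
unimodal networks with the same embedding and head widths — while keeping
all structure (3 residual blocks × 3 convolutions, fusion operators,
branch depths) intact. Width-matching matters: scaling only one model
down turns the comparison into a capacity contest rather than a fusion
contest. Epoch budgets and learning rates are set per model (OPCNN 6
epochs at 1e−3, the dense networks 20 epochs at 2e−3), in the same spirit
in which the protocol tunes learning rates per model. The acceptance
script reports the resulting repeated-CV AUC/MCC of all four models, the
OPCNN's AUC gain over the best unimodal network, and the fraction of
repeats in which the OPCNN's MCC beats the concatenation DMNN's.

## Known limitations

* The compute core is CPU-only, double precision, and single-threaded
  apart from BLAS; full-width OPCNN training is possible but slow, so
  benchmark-scale experiments use the reduced widths above.
* Early stopping monitors the *training* loss (no validation split is
  carved out of the small folds), which bounds runtime but does not guard
  against overfitting; epoch budgets are the effective regulariser.
* SMOTE is the classic variant only (no borderline-SMOTE/ADASYN), and
  undersampling is not implemented.
* The SVM baseline's probability outputs come from Platt scaling inside
  e1071 and carry its usual seed sensitivity; the harness seeds every fit.
* `sim_config(p1, p2)` can generate other modality widths, but the
  drug-table schema is fixed at 13 + 34 features.
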