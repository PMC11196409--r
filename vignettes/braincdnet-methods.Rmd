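---
title: "BrainCDNet: model, preprocessing and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BrainCDNet: model, preprocessing and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincdnet)
```

## Scope

`braincdnet` implements an end-to-end workflow for classifying 2-D brain-MRI
slices into healthy vs. pathological (binary) or glioma vs. meningioma vs.
pituitary (three-class) categories: an edge-sharpening preprocessing filter,
the BrainCDNet concatenated convolutional architecture with an exact
parameter audit, a self-contained training engine, stratified validation
schemes, the usual confusion-matrix / ROC metric battery, and a synthetic
phantom generator that makes the whole pipeline testable without patient
data. This vignette records the model, the tunable parameters, and the
design decisions a maintainer would want to know about.

## The Nimble sharpening filter

The preprocessing filter replaces every pixel by

$$S(m,n) = \alpha\, I(m,n) + (1-\alpha)\,
  \frac{I(m,n+1)+I(m,n-1)+I(m+1,n)+I(m-1,n)}{4},$$

i.e. it amplifies the difference between a pixel and its 4-neighbour mean.
Since the coefficients sum to $\alpha + (1-\alpha) = 1$, the operator is
affine-equivariant (`filter(aI + b) = a filter(I) + b` before clipping),
constant images are fixed points, and $\alpha = 1$ is the identity. With the
default $\alpha = 2$ the filter adds the negative discrete Laplacian
response to the image, which is what sharpens edges. $\alpha$ must be at
least 1; values around 2 are a sensible operating point, larger values
amplify noise.

Decisions the recurrence itself does not determine:

* **Borders.** The recurrence is undefined at the image border. The default
  policy replicates the nearest edge pixel, which avoids the dark halo that
  zero padding would inject; `reflect` and `zero` are available for
  comparison.
* **Colour.** Multi-channel images are filtered per channel independently.
* **Clipping.** The response can leave `[0, 255]` (e.g. $2I - \bar{I} < 0$
  at dark edges); output is clipped back after filtering, before the final
  rescaling, so the network-input contract stays simple. Tests that verify
  the filter algebra disable clipping.
* **Order.** Images are resized to the network resolution first and
  sharpened second, so the filter's effect does not depend on the source
  resolution. Resizing is bilinear (via EBImage); the full preparation path
  is resize → sharpen (optional) → divide by 255, and always yields a
  `224 × 224 × 3` array in `[0, 1]`. Disabling the sharpening step is the
  ablation arm of the pipeline.

## The BrainCDNet architecture

The network is a three-block concatenated CNN on `224 × 224 × 3` inputs:

* **Block 1** — four parallel *ConvNetA* units applied to the same input:
  3×3 convolution, 64 filters, stride 2, bias; SELU; batch normalization;
  2×2 max-pool, stride 2. The top pair and bottom pair (by declaration
  order) are concatenated channel-wise, so channels add ($c_m + c_n$).
* **Block 2** — one *ConvNetB* unit per pair: 3×3 convolution (128 filters,
  stride 1) + SELU + batch norm, then 1×1 convolution (128 filters) + SELU
  + batch norm + 2×2 max-pool; the two outputs are concatenated.
* **Block 3** — a single *ConvNetC*: 3×3 convolution (256 filters) + GELU +
  batch norm, then 1×1 convolution (256 filters) + GELU + batch norm.
* Global average pooling reduces the final `28 × 28 × 256` map to a
  256-vector feeding a softmax head.

The spatial trace under same-padding convolutions is
224 → 112 (stride-2 conv) → 56 (pool) → 56 (block-2 convs) → 28 (pool) →
28 (block 3) → GAP.

### Parameter audit

`count_parameters()` walks the declarative layer graph with the standard
counting conventions: a biased convolution contributes
$k_h k_w c_{in} c_{out} + c_{out}$; batch normalization over $C$ channels
contributes $2C$ trainable (scale, shift) and $2C$ non-trainable (running
mean and variance) parameters; activations, pooling, concatenation and GAP
contribute nothing; the dense head contributes $256\,C_{cls} + C_{cls}$.
For the three-class build this reconciles **exactly** with the published
totals — 994,563 trainable plus 2,560 non-trainable = 997,123 — which is
the package's strongest desk-scale check of architectural fidelity. Three
conventions are forced by that reconciliation and are therefore treated as
definitional:

* convolutions carry biases (without them the audit falls short by 1,280,
  the summed conv-bias count);
* batch norm is 2 trainable + 2 non-trainable parameters per channel
  (the only convention consistent with 2,560 non-trainable);
* the printed totals correspond to the **three-class** head — each extra
  class costs exactly 257 parameters (256 weights + 1 bias), and the
  binary build totals 994,306.

Other declarative choices: same-padding everywhere (valid padding would not
change any count, only the spatial trace); activation placed before batch
norm, matching the block descriptions; the four block-1 branches have
independent weights (sharing would break the reconciliation); weights are
He-Normal initialized (zero-mean normal, variance $2/\text{fan-in}$).

## The training engine

No deep-learning framework is involved: the package ships its own
convolutional engine (Rcpp/RcppArmadillo) implementing im2col + GEMM
convolutions, SELU/GELU, batch normalization, max-pooling, channel
concatenation, GAP, a softmax cross-entropy head, full backpropagation and
Adam. Numerical specifics:

* Training runs in single precision for speed; the same templated code is
  instantiated in double precision, and analytic gradients of every tensor
  family are verified against central finite differences (tolerance 1e-4)
  in the test suite.
* Batch norm uses $\varepsilon = 10^{-3}$ and momentum 0.9 for the running
  statistics — chosen so the statistics converge within short training
  schedules. After the final epoch the running statistics are re-estimated
  by averaging training-mode batch statistics over the training set under
  the final weights; without this, inference-mode normalization lags the
  weights badly on schedules of a few dozen updates.
* Adam uses the conventional $\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\varepsilon = 10^{-7}$, with bias correction.
* The loss is categorical cross-entropy, the standard companion of a
  softmax head.
* Argmax prediction breaks ties toward the lowest class index.
* All randomness (weight draws, batch shuffling) comes from R's RNG under
  the config seed, so runs are bit-reproducible.

The published training protocol is the default configuration: Adam,
learning rate 0.001, batch size 64, 50 epochs. Desk-scale runs reduce
`epochs`; nothing else is tuned. No learning-rate schedule, early stopping,
augmentation or class reweighting is applied — none are part of the
protocol (a fresh He-Normal initialization per cross-validation fold is,
since reusing weights across folds would leak).

## Validation schemes

Two schemes are provided, matching the reported experiments: stratified
5-fold cross-validation and stratified holdouts at 75/25 and 85/15.
"Approximately equal" folds are implemented as stratified sampling — the
only scheme that guarantees every class appears in every fold/partition —
with per-class fold sizes differing by at most one and each class's
remainder going to the currently smallest folds so total fold sizes stay
balanced. Holdout training counts are per-class
`round-half-up(class size × fraction)`, remainder to test, making split
counts exactly reproducible. Split plans carry their seed and are
exportable as CSV.

Cross-fold aggregation is the unweighted arithmetic mean per metric, which
is also how the per-class "average" rows of the multiclass reports are
formed (the published average sensitivity 93.55 is the plain mean of 93.20,
99.32, 88.12). Metrics with empty denominators (e.g. TPR with no positive
truths) are reported as `NA`, never as 0, so they cannot silently deflate
or inflate macro averages. AUC follows the Mann–Whitney convention (ties
get half credit); the ROC curve is threshold-swept over the observed scores
and its trapezoidal area equals the rank-based AUC identically. A scalar
"AUC" column alongside TPR/TNR in published binary tables is numerically
consistent with the balanced accuracy (TPR+TNR)/2 reading; the package
exposes the threshold-free AUC, and balanced accuracy can be formed from
the reported TPR and TNR if desired.

## Synthetic phantoms

Phantoms are statistical stand-ins for MRI slices, not anatomical
simulations: a dark background (intensity 10), a bright ellipse for the
brain (intensity 120, semi-axes ~0.36–0.40 and 0.28–0.32 of the image side
with mild random jitter), and for pathological classes a uniform disc
lesion at a random position inside the ellipse, plus additive Gaussian
noise (sd 5 by default), clipped to `[0, 255]`. The lesion is a flat-top
disc rather than a soft blob so its mean added contrast is exactly the
class intensity — which gives the generator a sharp statistical oracle
(disc mean = baseline + intensity ± $3\sigma/\sqrt{A}$).

Class identity is carried by the lesion contrast: `c(0, 80)` for the binary
scenario (class 0 has no lesion) and `c(40, 80, 120)` for three classes,
with a validated guarantee that class intensities differ by at least
`3 × noise_sd`. These defaults make the classes learnably separated — a
nearest-centroid baseline on a brightest-pixels summary exceeds 95%
accuracy — so a failure of the full network to learn indicates a pipeline
bug, not a data problem. Each `(seed, class, draw)` triple maps to its own
RNG substream, so generation is deterministic and order-independent.

What phantoms do **not** emulate: T1/T2 contrast physics, bias fields,
skull/anatomy, tumor morphology, inter-scanner variability. Passing the
phantom-based pipeline tests demonstrates that the machinery (filter,
splits, training, metrics) is correct — it says nothing about accuracy on
real MRI data, which requires the external image collections and the full
50-epoch protocol.

## Problem sizes used in the automated checks

The parameter audit always runs at the full 224-pixel input (it is
input-size independent). Engine gradient checks run on an 8-pixel input in
double precision. Pipeline behaviour tests run on 32-pixel phantoms with a
proportionally shrunken network input, where a training run takes seconds.
The end-to-end check trains the full 224-pixel network on 200 default
phantoms (85/15 holdout, 10 epochs, batch 64) and requires at least 95%
test accuracy — a desk-scale stand-in for the published headline accuracies,
which are out of scope here because they require the external datasets and
the full training budget.

## Known limitations

* The engine materializes exactly the BrainCDNet topology (any input side
  whose trace stays positive, any class count); it is not a general graph
  executor. The declarative graph exists so the audit and shape trace run
  without the engine.
* Single-precision training is not bit-identical across BLAS
  implementations; reproducibility is guaranteed for a fixed installation.
* One-channel-at-a-time bilinear resizing and PNG I/O are delegated to
  EBImage/png; DICOM/NIfTI ingestion, skull stripping and registration are
  out of scope.
* `kfold_split` requires every class to have at least `k` members, and
  holdout fractions must leave every class non-empty on both sides.
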