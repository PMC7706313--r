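---
title: "Interpreting CNN classifiers of leaf-disease imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting CNN classifiers of leaf-disease imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(lesionviz)
```

## The problem

Convolutional neural networks diagnose leaf diseases from photographs with
high accuracy, but a bare class probability gives a plant scientist no way
to check *what* the network looked at.  If the decisive evidence is the
lesion -- its color, texture and extent -- the model has learned something
a pathologist would recognize; if it is the background or the leaf contour,
the model has learned a dataset artifact.  `lesionviz` packages the four
families of visualization that make this distinction testable, together
with everything needed to exercise them end to end on one CPU: a small
layer-graph network engine, a synthetic leaf-lesion image generator with
ground-truth masks, and quantitative lesion-overlap metrics.

The package treats interpretability itself as the experiment.  Its central
claims are not "the model is accurate" but "the attention maps land on the
lesions", "the class score decomposes into per-neuron contributions", and
"layers that visualization shows to be uninformative can be removed
without losing accuracy".

## The network engine

Everything operates on an explicit directed acyclic graph of typed layers
(`conv2d`, `batchnorm`, `relu`, max/average pooling, global average
pooling, `dense`, `concat`, `softmax`).  Images are channels-last
`H x W x 3` arrays with values in `[0, 1]` (8-bit images are divided
by 255), origin top-left, and all spatial sizes are reported `H x W`.
This single stated convention is what keeps attention maps aligned
pixel-for-pixel with inputs across eight different algorithms.

`forward()` evaluates in topological order, can capture any layer's
post-activation output, and always runs batchnorm in inference mode from
its moving statistics -- visualization is defined on a fixed trained
function, so nothing about the function may depend on the batch being
visualized.  `backward()` propagates a scalar target (a class logit, a
channel mean, or any weighted sum of a layer) under one of three unit
rules:

* **vanilla** -- the exact analytic gradient; verified against central
  finite differences in the test suite.
* **guided** -- a ReLU passes the backward signal only where both its
  forward pre-activation and the incoming signal are positive.
* **rescale** -- DeepLIFT-style contribution multipliers relative to a
  reference forward pass: at a ReLU the multiplier is the ratio of output
  difference to input difference, with the gradient as fallback when the
  input difference is below `1e-7`; affine layers (convolution, dense,
  batchnorm, average pooling) use their exact linear rule.  On
  affine-plus-ReLU graphs the resulting input contributions sum to
  `F(x) - F(reference)` (summation-to-delta), which the suite checks to
  `1e-4`.

### The InceptionV3-like builder and parameter accounting

`build_inception_v3_like()` reproduces the canonical InceptionV3 feature
extractor -- stem `Conv1..Conv5`, inception modules `Mixed0..Mixed10`
with a final depth of 2048 -- topped by global average pooling (`GAP`)
and a dense head.  Layer shaving (`truncate_at()`) keeps the subgraph up
to a named layer, with its weights, and attaches a fresh GAP + head sized
to that layer's channel depth.

Parameter accounting counts every stored array element.  Batchnorm
follows the inception convention of a per-channel shift with no scale, so
each batchnorm contributes 3 values per channel: the shift plus the two
moving statistics, the latter reported as non-trainable but included in
the total, as deep-learning frameworks do.  Under this convention the
38-class model totals exactly 21,880,646 parameters and the Mixed5
truncation 5,167,878 -- a 76.4% reduction -- and the totals are invariant
to the padding dialect and the input resolution.

The `all_same` padding dialect (every layer padded `same`) is
the default because it yields the convenient 7x7 grid at `Mixed10` for a
224x224 input; the canonical valid-padded stem is available as
`standard_stem` and changes only spatial sizes, never counts.

### Training

`train()` is a plain stochastic-minibatch loop: categorical cross-entropy,
Adam with bias-corrected moments (`beta = 0.9/0.999`, `eps = 1e-7`), an
optional step decay of the learning rate, and selection of the weight
snapshot with the lowest validation loss.  Batchnorm trains in
frozen-statistics mode -- the learnable shift/scale receive gradients
through the inference-mode affine transform while the moving statistics
are updated as an exponential moving average of per-batch input
statistics.  This is the standard fine-tuning treatment of batchnorm; it
avoids making any activation depend on its minibatch, at the cost of a
brief warm-up while the moving statistics adapt (momentum 0.9 for the
desk-scale fixtures).

Two choices matter for small-batch training of tiny networks on
all-positive image inputs, and both are baked into the fixture builders:
batchnorm after every convolution, and a zero-initialized classification
head.  Without them, Adam's aggressive early steps reliably collapse the
feature stack into a dead-ReLU plateau where the network predicts the
uniform distribution forever; with them, training starts *at* the uniform
prediction and grows class-correlated features instead of destroying
them.

## The synthetic leaf-lesion task

`make_dataset()` emulates the structure of curated leaf-disease photo
collections at desk scale: one ellipse-shaped leaf (with mild radial
shading and a small random rotation) on a uniform background, Gaussian
pixel noise (sd 0.02), and disease classes that differ **only** in their
lesions.  The default task has four classes -- healthy; a few large solid
brown spots; ringed lesions with a yellow halo and dark center; many
small near-black specks -- chosen to span the number/size/color axes
along which real foliar symptoms vary.  Images are 64x64 by default,
which trains in about a minute on one CPU.  The split is 6:2:2
train/validation/test, computed as floor for train, then validation, with
the remainder to test, so the counts are reproducible.

Each sample carries the binary lesion mask recorded *before* noise, plus
the leaf-region mask.  Because the lesion is the only class-separating
feature, the masks are a defensible ground truth for where a sound
classifier should look, and every "does the map land on the lesion?"
claim becomes a computable number (`overlap_metrics()`).

What the generator does **not** emulate: photographic texture, specular
highlights, venation, leaf-shape variation between classes, occlusion and
scale variation.  A method that localizes lesions here has passed a
necessary sanity check, not a field trial; conclusions about real imagery
require real imagery.

## Visualization I: hidden-layer outputs

`extract_intermediate()` halts the forward pass at a layer;
`render_grid()` tiles its channels (each min-max normalized
independently, constant channels rendered black) into a near-square grid.
Image complexity is scored by `shannon_entropy()`: ITU-R 709 luminance
conversion, 8-bit quantization, then `-sum(p log2 p)` over gray-level
frequencies, bounded by 8 bits.

## Visualization II: feature visualization

`visualize_neuron()` synthesizes the image that maximizes a channel's
mean activation by gradient ascent in a color-decorrelated Fourier
parameterization: independent complex coefficients per color component
are scaled by `1/frequency` (an energy-balanced, natural-image-like
prior), inverse-transformed with a unitary-style FFT, mixed across color
by the widely used natural-image sqrt-covariance triple (or a matrix
estimated from data via `estimate_decorrelation()`), and squashed to
`[0, 1]` by a sigmoid.  Optimization is Adam at learning rate 0.05 with
no explicit regularization; the parameterization is the only prior.

Numerical choices worth knowing:

* The adjoint of the render (needed for ascent) is an FFT followed by the
  transposed color mixing and the sigmoid derivative; it is verified
  against finite differences in the suite.
* The initial noise has coefficient sd 0.1, which renders as clearly
  visible low-frequency noise.  Deep channels of a trained network are
  often completely inactive on a flat gray start, leaving a zero gradient
  and no ascent direction; if that happens the noise is doubled and the
  ascent restarted (twice at most) before the neuron is declared constant
  and the initial render returned with a warning.
* Adam normalizes each coefficient's step to the learning rate, so
  late-stage ascent injects learning-rate-sized noise into coefficients
  whose true gradient is negligible.  For saturating objectives this
  leaves a small fraction of pixels pinned at the sigmoid's far ends: a
  linear objective such as "mean red value" plateaus around 0.92--0.96
  rather than at the idealized 1.0.  This is a property of
  coordinate-normalized ascent on a spectral parameterization, not of the
  objective.

On the fixture model, renders of deeper layers have higher Shannon
entropy than shallow ones (rank correlation of entropy with depth is
strongly positive), matching the qualitative picture that depth
accumulates feature complexity -- with the caveat that on a color-defined
task the "complexity" gained is largely chromatic, not textural.

## Visualization III: the semantic dictionary

At the GAP layer the pre-softmax score of class *j* is exactly
`logit_j = sum_k a_k W[k, j] + b_j`, so each GAP neuron's summand
`a_k W[k, j]` is its **contribution score** -- no approximation is
involved, and the suite enforces conservation (scores plus bias equal the
logit to `1e-5`) on every image.  `mean_contributions()` averages scores
over a set of same-class images (equivalently, scores the mean GAP
vector, since the decomposition is linear) and ranks neurons with ties
broken by index.  `build_dictionary()` pairs the top contributors
(default 6, configurable -- comparable analyses use 5) with their feature
visualization on the layer feeding the GAP, plus a cross-class score
table.  On the fixture, the top neuron for the brown-spot class renders
in lesion-like colors and contributes negatively to the healthy class.

## Visualization IV: attention maps

Eight algorithms produce `H x W` maps aligned to the input, min-max
normalized to `[0, 1]` with constant maps sent to zero and raw
(pre-normalization, signed where meaningful) values retained for
quantitative work:

| method | family | cost profile |
|---|---|---|
| `occlusion_map` | perturbation | one forward per mask position |
| `superpixel_surrogate_map` | perturbation | one forward per sampled pattern |
| `vanilla_saliency` | gradient | one backward |
| `integrated_gradients_map` | gradient | one backward per interpolation step |
| `guided_backprop_map` | gradient | one backward |
| `grad_cam_map` | gradient, layer-targeted | one backward (to the layer) |
| `deeplift_map` | reference | two forwards + one backward |
| `explanation_map` | reference, layer-targeted | forward only |

The engine counts forward and backward passes (`viz_counters()`), so the
cost contracts are assertions, not documentation: occlusion performs
exactly one forward per mask position plus the baseline, the surrogate
exactly one per design row, and the explanation map performs zero
backward passes.

Choices the underlying methods leave open, fixed here and exposed as
arguments:

* Occlusion: 32x32 mask, stride 16, mask value = image mean color by
  default; overlapping drops are averaged, not maximized.  Scores are
  pre-softmax logits by default (`score = "prob"` available) so the
  linear-scorer oracle is exact.
* Surrogate regression: superpixels from SLIC-style k-means on
  `(y, x, R, G, B)` with grid-seeded centers; binary on/off designs are
  enumerated exhaustively whenever `2^k <= n_samples` (making the least
  squares exact) and sampled otherwise, with a ridge fallback
  (`lambda = 1e-3`) for singular designs.
* Gradient maps aggregate channels by the maximum absolute value.
* Grad-CAM can target any spatial layer; channel weights are spatial
  means of the logit gradient, the weighted sum is rectified and
  bilinearly upsampled.  At the last feature layer of a GAP-head network
  it coincides with class activation mapping (cosine > 0.999 in the
  suite).  A guided-gradient variant is available
  (`relu_rule = "guided"`); which composite the term "guided Grad-CAM"
  denotes is ambiguous in the literature, so neither reading is asserted.
* The explanation map rectifies each channel against its
  reference-derived threshold, `max(0, a_k - t_k)`, where `t_k` is the
  mean activation over a healthy-reference batch and all spatial
  positions; channels are ranked by the spatial sum of the excess and the
  top 3 summed.  Rectified difference was chosen over division because it
  is exact under the "no activation above the healthy level" null and has
  no divide-by-small-threshold pathology.

`layer_scan()` runs a layer-targetable method across layers and, given a
mask, tabulates lesion overlap per layer.  On the fixture, Grad-CAM's
best layer is an intermediate one, not the deepest -- the toy-scale
echo of shallow layers localizing lesions better.  The explanation map's
best layer concentrates roughly 40-55% of its heat mass (across seeds) on
lesions that cover only ~7% of the image: a five-to-seven-fold
enrichment, though the map retains a diffuse leaf-level component (the
16-channel fixture cannot afford purely lesion-specific channels, and the
leaf's radial shading legitimately exceeds the spatially uniform
reference threshold).

## Evaluation and layer shaving

`overlap_metrics()` scores a map against a mask: sensitivity as the
fraction of heat mass on the lesion (mass-based, to avoid an arbitrary
binarization), specificity as one minus the mean off-lesion heat, IoU at
a threshold (default 0.5), and the pointing game.
`misclassification_report()` lists each misclassified image with its top
predictions and attention maps, plus the fraction of heat mass falling
outside the leaf -- the quantitative form of "errors look at the
background".  The suite constructs a deliberately background-confounded
task and verifies that misclassified images show higher background
attention than correctly classified ones.

`shave_series()` runs the truncation experiment: for each cut layer,
truncate, transfer-learn a fresh head (copied feature layers frozen by
default -- the cheaper and more reproducible reading of "transfer
learning"; `fine_tune = TRUE` unfreezes everything), evaluate, count
parameters.  On the fixture the deepest cut matches the full model's test
accuracy within 0.05 and accuracy degrades only gradually toward
shallower cuts, the desk-scale analog of removing half an InceptionV3
without losing accuracy.  The exact canonical counts (21,880,646 vs
5,167,878) are reproduced without any training.

## Problem sizes and reproducibility

The default experimental scale -- 4 classes x 40 images at 64x64, a
three-block CNN, 25 training epochs, 20-image evaluation sets, 128
ascent steps -- was chosen so that the full suite and the acceptance
script each run in minutes on a single CPU while every claim above is
still exercised end to end.  All stochastic steps (data generation,
weight init, shuffling, sampling designs, spectral noise) take explicit
integer seeds, and `scripts/acceptance.R` derives every sub-seed from its
single `--seed` argument, so reruns are bit-reproducible up to BLAS
rounding.

## Known limitations

* The engine is CPU-only, single-image (no batched tensors), and meant
  for desk-scale models; full-scale InceptionV3 training is out of scope
  (construction, forward evaluation, truncation and counting work at
  full scale).
* Weight serialization uses an RDS blob plus a JSON architecture
  manifest rather than a cross-language container.
* The rescale rule implements DeepLIFT's rescale variant only (no
  RevealCancel), and maxpool routes by argmax under all rules.
* Superpixels come from spatially weighted k-means; contiguity is
  encouraged, not enforced.
* Synthetic imagery supports method validation, not agronomic
  conclusions; see the generator section for what it omits.
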