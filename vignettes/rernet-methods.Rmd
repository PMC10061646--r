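---
title: "Randomized-network ensembles over convolutional features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized-network ensembles over convolutional features: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`rernet` classifies white blood cell images — eosinophils, lymphocytes and
monocytes — with a two-stage architecture. A convolutional backbone with
residual (identity-shortcut) blocks is briefly fine-tuned on the labeled
images and then used *only* as a feature extractor: its classifier head is
replaced by `FC128 -> ReLU -> BatchNorm -> FC(m) -> softmax`, and after
fine-tuning the 128-unit fully-connected layer's linear output is tapped as
the feature vector for each image. Everything after that layer is discarded
at inference time.

The features feed three *randomized neural networks* (RNNs), trained in
closed form rather than by gradient descent:

- **ELM** (extreme learning machine): a single hidden layer of $v$ sigmoid
  nodes whose input weights $b_j$ and biases $c_j$ are drawn uniformly on
  $[-1, 1]$, frozen, and never updated. With hidden activation matrix
  $M_{ij} = g(b_j^\top x_i + c_j)$ and one-hot target matrix $H$, the output
  weights are the minimum-norm least-squares solution $d = M^{+} H$, where
  $M^{+}$ is the Moore–Penrose pseudoinverse. A network with $v$ hidden
  nodes can exactly interpolate $v$ distinct observations.
- **SNN** (Schmidt neural network): identical to the ELM except for a
  learned output bias $e$; $(d, e)$ are solved jointly by augmenting $M$
  with a constant-1 column, so the SNN's training residual can never exceed
  the ELM's on the same hidden draw (its column space strictly contains the
  ELM's).
- **dRVFL** (deep random vector functional link): $l$ stacked random
  hidden layers, each consuming the previous layer's activations, with the
  output layer reading the concatenation $T = [X \mid M^1 \mid \dots \mid
  M^l]$ — the raw input enters through *direct links*. Output weights are
  again $d = T^{+} H$.

Each member predicts by argmax over its $m$ score columns (ties to the
lowest class index, for determinism). The ensemble prediction is a hard
majority vote: if at least two members agree, that class wins; if all three
disagree, a fixed fallback class is returned — class 0, which under the
alphabetical class-directory convention is the eosinophil. Because votes
are over hard labels, whenever at least two members are correct on a sample
the ensemble is correct on it; that deterministic consequence is tested
directly.

Evaluation uses repeated stratified k-fold cross-validation (default
5 runs × 5 folds). The m-class problem is scored one-vs-rest: for class
$\partial$, TP is the diagonal confusion-matrix cell, FN the rest of its
row, FP the rest of its column, TN everything else, and

$$\mathrm{accuracy}(\partial) = \frac{TP+TN}{TP+TN+FP+FN}, \quad
  \mathrm{sensitivity}(\partial) = \frac{TP}{TP+FN}, \quad
  \mathrm{precision}(\partial) = \frac{TP}{TP+FP},$$

with F1 the harmonic mean of precision and sensitivity, all reported as
percentages. Macro averages are unweighted means over classes. The
aggregation ladder is fixed: within a class over folds, then over classes,
then over runs; Student-t intervals (appropriate at n = 5 runs) summarize
run-level spread, and model comparisons are reported as plain
difference-of-means intervals with no named hypothesis test attached.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `v` | 400 | Hidden nodes per member; the one pre-defined RNN hyperparameter. Large relative to fold size puts members in the interpolation regime. |
| `drvfl_layers` (`l`) | 3 | dRVFL depth. The depth is a free design choice; 3 balances feature diversity against solve width $n + lv$. |
| `ridge` | 0 | Tikhonov penalty in the output solve; 0 means the plain pseudoinverse with singular values below $10^{-10}\,\sigma_{\max}$ truncated. |
| `mini_batch` | 10 | Fine-tune batch size. |
| `max_epoch` | 2 | Deliberately short fine-tune: the backbone only has to shape features, not classify; more epochs invite overfitting on small data. |
| `learning_rate` | 1e-4 | SGD step size; the optimizer is SGD with momentum 0.9 (a conventional default — the optimizer itself is a free choice). |
| `k`, `runs` | 5, 5 | Cross-validation shape. |
| `fallback_class` | 0 | Vote fallback, generalized from "eosinophil" to "first class in sorted label order" so any m works. |

Weight distribution for the random hidden layers is uniform on $[-1,1]$
for both weights and biases — standard randomized-network practice, keeping
sigmoid inputs in a useful range. One-hot targets are coded $\{0,1\}$ (not
$\pm 1$). The dRVFL uses an independent seeded draw per layer; the recursion
written with shared first-layer weights is dimensionally inconsistent when
$n \ne v$ (layer 1 maps $n \to v$, deeper layers $v \to v$), so per-layer
weights are the default and a `share_deep_weights` flag offers the closest
dimensionally valid shared-draw variant (layers 2..l share one $v \times v$
draw).

## The backbone

The bundled backbone, `tiny_resnet`, exists so the full pipeline — residual
blocks, fine-tuning, feature tapping, Grad-CAM — runs in seconds on a CPU
with no pretrained weights: a stride-2 3×3 stem (16 channels), an
identity-shortcut residual block, a stride-2 transition to 32 channels, a
second residual block, global average pooling, then the FC128 head. A
residual block computes `inner(X) + X`; with a zero inner transform it is
exactly the identity, which is asserted in the tests. The
`resnet50_pretrained` tag is reserved for an ImageNet-pretrained backbone
and raises an informative error when no weight source is available.

Numerical choices that matter:

- **Input centering.** Images are centered by per-channel means estimated
  from the fine-tune data (default 0.5). Without this, zero padding abuts a
  bright smear background and manufactures strong fake edges at the canvas
  border that dominate both the pooled features and Grad-CAM maps.
- **BatchNorm recalibration.** Training uses batch statistics; inference
  uses fixed statistics so features are batch-size independent. After a
  2-epoch fine-tune the exponential running average still lags the
  fast-moving feature means, whose within-batch variance is tiny, so
  `fine_tune` ends by re-estimating the head BatchNorm mean and variance
  exactly over its training set. Features themselves are tapped *before*
  the BatchNorm, so only the softmax head and Grad-CAM depend on it.
- **Update count.** `fine_tune` performs exactly
  `max_epoch * ceiling(N / mini_batch)` SGD-momentum updates with a seeded
  shuffle per epoch; identical data, config and seed give bit-identical
  weights. Learning rates around 5e-3 and above can diverge on this small
  network — the published 1e-4 recipe is stable.
- **Gradients.** The backward pass is verified against central finite
  differences at `eps = 1e-6`; larger probe steps cross ReLU kinks and show
  spurious disagreement.

## Grad-CAM

For a class logit and a convolutional stage, the gradient of the logit with
respect to the feature maps is averaged spatially per channel; the heatmap
is the rectified, channel-weighted sum of the maps, bilinearly upsampled to
input size and scaled to maximum 1. In inference mode the head is piecewise
linear, so the gradient has a closed form that the tests recompute
independently.

One honest limitation: with a small softmax head, one class can be encoded
mostly by the *absence* of the other classes' evidence (all of its channel
weights negative). Its rectified map is then empty or background-focused —
observed for the eosinophil class on the synthetic data — so the
attention-localization checks are asserted for classes with positive,
object-bound evidence (the monocyte's large dark nucleus is the robust
case). A large pretrained backbone does not exhibit this failure on the
real benchmark.

## Synthetic data: what it does and does not emulate

`generate_cell_images` draws caricature blood cells keyed to the gross
morphology that separates the classes: the eosinophil is granular with a
bi-lobed nucleus, the lymphocyte is a small cell filled by a large round
nucleus, the monocyte is the largest cell with a kidney-shaped nucleus.
Each image holds one cell with jittered position and size on a pale smear
background with faint out-of-focus blobs, plus Gaussian pixel noise
(sd 0.05 by default); the cell's bounding box is recorded so attention maps
can be scored against the true object position. A nearest-centroid baseline
on four crude color/darkness features separates the classes at ≥ 90%,
which calibrates that the classes are learnable without being trivial at
the pixel level.

`generate_feature_table` emulates well-separated backbone features
directly: class c is an isotropic Gaussian with mean `separation · e_c`
(defaults: dimension 128, separation 6, unit noise), giving a fast path
that exercises everything downstream of feature extraction.

What passing on these fixtures does **not** show: robustness to staining
variation, occlusion, touching cells, class imbalance, or scanner drift —
none of which the generator emulates. The generator's class cues are also
more color-dominated than real smears, which is precisely why a tiny
backbone suffices here and why accuracy on synthetic data says nothing
quantitative about the published benchmark.

## Degenerate inputs and edge rules

Undefined one-vs-rest ratios (a class with no true samples in a fold, or
never predicted) are flagged `NA` with a warning and excluded from means on
request — never silently coerced to 0. Argmax ties break to the lowest
class index. Stratified folding requires `k` at most the smallest class
count and deals each class round-robin after a seeded shuffle, so per-class
fold sizes differ by at most one. Report tables render percentages rounded
half *up* at two decimals (base R's `round` is half-to-even), with full
precision retained internally.

## Problem sizes used by the test suite

The packaged checks run the image pipeline at 64×64 pixels with 12–60
images per class and 2 runs × 5 folds; the feature-table pipeline runs at
up to 128 dimensions and 400 hidden nodes, identical to the published
hyperparameter `v`. These sizes were chosen so the whole suite exercises
every stage, including two full cross-validation protocols, in a few
minutes on one CPU core while keeping the members in the same
interpolation regime (`v` at least the fold training size) that the
published configuration occupies.

## Known limitations

- The bundled backbone is a deliberately small stand-in; it shares the
  structure (residual blocks, FC128 feature tap, 2-epoch fine-tune recipe)
  but not the capacity of a 50-layer pretrained network, so absolute
  accuracies on real microscopy data will differ.
- Closed-form solves materialize an N × (n + lv) design matrix; at very
  large N a ridge solve (`ridge > 0`) via the normal equations is the
  memory-friendly path.
- Majority voting is hard-label by design; probability averaging or
  stacking are out of scope.
- The model archive uses R native serialization with a format/version
  header; it is not portable to other languages.
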