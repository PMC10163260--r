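---
title: "Weakly supervised single-cell protein localisation: models and methods"
author: "SubCellLoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised single-cell protein localisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Immunofluorescence screens such as the Human Protein Atlas image a protein
of interest (green) together with reference stains for the nucleus (blue),
microtubules (red) and the endoplasmic reticulum (yellow). Annotation is
collected per *image*, but each image contains many cells, and the
image-level label is the union of the labels of its cells. Propagating the
image label to every cell therefore produces *weak* cell labels: every
class the image carries is marked positive on every cell, even on the
cells that do not express it. A cell-level classifier must be trained
through this label noise, under severe class imbalance, a multi-label
regime (a protein may live in several compartments at once), and highly
variable cell appearance and capture quality.

SubCellLoc implements a desk-scale version of a full pipeline for this
problem: cell extraction, three trainable model families, iterative
refinement of the weak labels, per-cell visual-integrity weighting,
correlation-gated fusion of image- and cell-level evidence, diversity
ensembling, and a mask-matched mean-average-precision metric. Every stage
is exercised end to end on a synthetic data generator with known per-cell
ground truth, so the behaviour of each component is testable without any
external download.

# Weibull activation pooling

The aggregation head shared by the dual-stream and cell-level "actnet"
models transforms the final convolutional feature tensor
$R \in \mathbb{R}^{W \times H \times D}$ elementwise by a Weibull-shaped
learnable activation

$$T_i = \left(\frac{R_i}{\lambda}\right)^{\zeta - 1}
        \exp\!\left(-\left(\frac{R_i}{\gamma}\right)^{\eta}\right),$$

followed by global average pooling
$S_k = \tfrac{1}{WH}\sum_i \sum_j T_{ijk}$ and a learnable power
normalisation $\delta(s) = \alpha s^\beta$. The activation dampens weak,
uninformative feature responses and equalises a learnable proportion of
strong ones; the power normalisation compensates the nonlinear scaling
before the classifier head.

Numerical choices:

* All six parameters are learnable scalars shared across the $D$
  channels. The reference description leaves the sharing unspecified;
  shared scalars are the fewest-assumption default and a per-channel
  variant would slot into the same interface.
* Positivity of $\lambda, \zeta, \gamma, \eta, \alpha, \beta$ is enforced
  by learning their logarithms, keeping the optimisation unconstrained.
* Initialisation is $\lambda = \gamma = 1$, $\zeta = 2$, $\eta = 1$,
  $\alpha = 1$, $\beta = 0.5$ — a smooth start close to identity-scale
  behaviour.
* Inside the training layers, inputs to fractional powers are clamped at
  $\varepsilon = 10^{-8}$ so gradients stay finite at zero. The public
  `weibullActivation()` evaluates the formula exactly (no clamp) so that
  the analytic values, e.g. $T(0) = 0$ for $\zeta > 1$, hold to machine
  precision.
* The formula uses $\lambda$ in the power term but $\gamma$ in the
  exponential; the two are kept independent, exactly as specified.

Analytic gradients of the activation with respect to the input and all
four parameters are implemented in `weibullGradients()` and verified
against central finite differences in the test suite.

# The three model families

All models share a small convolutional trunk: blocks of 3×3 same-padded
convolution, ReLU and 2×2 average pooling, implemented with explicit
im2col matrix algebra and hand-written backpropagation. The engine is
deliberately self-contained: the novel layers (Weibull pooling, bag
max-pooling with gradient routing, hybrid scattering fusion) are the
package's subject matter, and a from-scratch implementation keeps every
gradient inspectable and exactly testable.

**DSA (dual-stream actnet).** Each cell of an image is embedded into a
descriptor by trunk → Weibull activation → GAP → power normalisation. The
*image stream* takes the elementwise maximum over the bag of $N$
descriptors from one image (gradient routed to the argmax cell) and
classifies it against the image label; the *cell stream* classifies each
descriptor against the (weak or refined) cell labels. The training loss is
$L_f = W_1 L_1 + W_2 L_2$ with $(W_1, W_2) = (1, 0.2)$ in round 1 — the
cell labels are weak, so the cell stream is down-weighted — and $(1, 1)$
in round 2, when refined labels are trusted. At inference the two streams
are fused per class by the correlation rule described below. Bags are
drawn per image; images with more than $N$ cells are subsampled without
replacement, images with fewer are resampled with replacement.

**CLA (cell-level actnet).** The same descriptor path with a per-cell
multi-label head; trained with inverse-class-frequency weighted binary
cross-entropy plus a focal term.

**CLH (cell-level hybrid).** The trunk is augmented with two hybrid
fusion blocks that inject wavelet-scattering coefficients of the input
crop after the first and second downsampling stages. The scattering
stack is projected to the trunk width by a learnable 1×1 mixing,
resampled to the trunk's spatial size, concatenated with the deep
features and reduced back to the trunk width by a second 1×1 mixing,
added residually. The residual form makes the block
insertion-transparent: with fusion disabled the trunk is
weight-compatible with its plain counterpart, which gives a clean
ablation path. CLH aggregates by plain GAP (no Weibull pooling),
mirroring the reference configuration of the hybrid family.

The scattering transform itself is implemented with an FFT Morlet filter
bank: order-0 (Gaussian low-pass), order-1
$|x \star \psi_{j_1,\theta_1}| \star \phi_J$ and order-2 coefficients over
increasing scales $j_2 > j_1$, subsampled by $2^J$ (defaults $J = 2$,
$L = 4$ orientations). Convolutions are circular and subsampling is
strided, so a circular shift of the input by $2^J$ pixels shifts the
coefficient maps by exactly one sample — translation equivariance holds to
FFT round-off and is tested at $10^{-6}$. The filter bank is normalised to
a Littlewood–Paley bound of one, which makes the transform provably
energy non-increasing (also tested). Band-pass filters are zero-mean by
construction, so constant inputs produce exactly vanishing higher-order
coefficients.

**Heads.** Multi-label heads use elementwise logistic outputs rather than
a competing-class normaliser: the training losses are binary
cross-entropies over multi-label targets, which require independent
per-class probabilities. A softmax head is provided for single-label uses
(it drives the 4-class capture-ratio classifier) and as an inference-time
option.

**Optimisation.** Adam under a cosine-annealed learning rate,
$lr(e) = floor + \tfrac12 (lr_0 - floor)(1 + \cos(\pi e/(E-1)))$, with
$lr_0 = 2 \times 10^{-4}$ by default, matching the reference recipe for
full-size backbones. The desk-scale benchmarks in the tests and the
acceptance script use $lr_0 \approx 10^{-2}$: networks three orders of
magnitude smaller than EfficientNets tolerate, and need, proportionally
larger steps when trained for a handful of epochs. Augmentation (random
flips, 90° rotations, small shifts, nearest-neighbour rescaling, cutout)
is available with configurable probabilities and is off by default in the
short benchmarks, where it mainly adds variance. Training aborts with a
diagnostic on non-finite losses, and is bit-reproducible for a fixed
seed.

# The synthetic data generator

The generator emulates the *statistical structure* of the weakly
labelled regime, not the photorealism of micrographs:

* Multiple elliptical cells per image (default 12 per 128-px image,
  radius 10–14 px), placed by rejection sampling; mild contact is
  allowed, as in a confluent monolayer, and instance masks stay disjoint
  because later cells claim only unclaimed pixels. Border-touching cells
  are allowed so that partially captured cells occur naturally.
* Four channels per cell: a nuclear disk, angularly textured
  microtubules, a perinuclear ER band, and the protein channel.
* Each class renders a distinct protein pattern relative to the cell
  geometry — nuclear fill, nuclear rim, cytoplasmic fill, plasma-membrane
  rim, punctate cytosolic spots, nucleolar dots, a single aggresome-like
  focus, radial filaments — via an internal pattern registry (recycled
  when C exceeds the registry size). The patterns are designed so that a
  small model *can* learn them; only their statistical structure, not
  their biology, matters.
* **Correlated cell labels.** All cells of an image stain the same
  protein, so the image first draws a label set (size 1–2 by default,
  classes by the configured imbalanced frequencies), and each cell
  expresses each class of that set with probability `expressRate`
  (default 0.65; at least one class per cell). The image label is then
  the union of its cells' labels, and the weak per-cell labels inherited
  from it are wrong exactly for the unexpressed classes — the same
  structure as "only 30–60% of cells in an image show the pattern".
  An earlier design that sampled each cell's labels independently was
  discarded: with 12 cells per image the union saturates for frequent
  classes, their weak labels degenerate to all-positive, and no
  classifier (at any scale) could learn them — an unfaithful rendering of
  the real regime.
* Class imbalance via the default frequency vector
  (0.30, 0.25, 0.18, 0.12, 0.10, 0.05) over C = 6 classes.
* Capture defects: with probability `defectRate` a cell loses a
  contiguous boundary-adjacent cap — everything beyond a chord
  perpendicular to a random direction (keep fraction drawn from
  0.2–0.8) — from its mask and all channels. A chord cut is the shape of
  real border truncation and one-sided occlusion, and, unlike a
  centre-pivoted angular wedge, it can remove the nucleus entirely, so
  severe defects genuinely destroy the information the localisation
  patterns live on. `corruptCell()` applies the same operation with an
  exact pixel-count target.

The generator is deterministic for a fixed seed, and the union property
(image label = OR of cell labels) holds by construction and is verified
exactly in the tests. What passing these tests does *not* show: robustness
to staining chemistry, cell-line morphology shifts, focus artefacts, or
any appearance statistics of real micrographs — the synthetic patterns are
geometric archetypes, far easier than real HPA classes.

# Label refinement (AI-trains-AI)

Weak labels are refined by the cell re-labelling procedure: an ensemble
of source models (default three small CLAs with different seeds, standing
in for three large heterogeneous trunks — diversity, not trunk identity,
is what matters) is trained on the current labels; their per-cell
confidences are averaged; the combined confidence $c$ replaces each
originally-positive label as $c^\beta$, and originally-negative labels
remain exactly zero. Two rounds are the default. $\beta$ defaults to 0.5:
the value is not stated in the reference description, but the intended
effect — inflating low-to-mid confidences so that genuinely positive
labels are not crushed toward zero — requires $\beta < 1$. The exponent
is housed separately from the $\beta$ of the power-normalisation layer;
the symbol collision in the source material is resolved by keeping the
two parameters independent.

# Visual integrity (VID)

Two per-cell weights are multiplied into the final probabilities:

* $W_1 = 1 - P_b$, where $P_b$ is the probability of the 'bad' class
  from a gradient-boosted tree classifier (xgboost, boosting rounds
  chosen by fivefold cross-validation) over eight geometric features:
  bounding-box height, width, aspect ratio (width/height), bounding-box
  area, mask area, mask perimeter (4-neighbour boundary-pixel count,
  raster border counting as outside), largest bounding-box dimension, and
  a binary staining flag. The staining flag is operationalised as: 1 when
  the fraction of crop pixels whose nucleus or protein intensity exceeds
  $\tau = 10$ (8-bit scale) falls below $f_{\min} = 0.05$; both
  thresholds are configurable, since the reference wording describes the
  feature only loosely.
* $W_2$ from a small softmax CNN predicting the captured fraction of the
  cell body in four bins — class 1 below 30%, class 2 30–50%, class 3
  50–80%, class 4 80–100% — trained with cross-entropy on synthetically
  corrupted cells; $W_2 = 0.1, 0.5, 1, 1$ for classes 1–4.

The bins are interpreted on the *captured* (remaining) fraction of the
cell body, the reading consistent with "predicts the ratio of the total
cell body being captured" and with monotone weights; the alternative
reading (fraction removed) would invert the weight ordering. Bin
boundaries are half-open below and closed at 1, an exhaustive
non-overlapping cover of [0, 1]. $W_v = W_1 W_2$ lies in [0, 1], so
applying it never increases a probability.

The benchmark that quantifies the effect of $W_v$ follows the
annotation convention of the single-cell challenge this task comes
from: a cell captured below 50% cannot be meaningfully annotated, so
such cells are absent from the ground truth, while the pipeline (which
cannot know this) still predicts every segmented cell. Predictions on
sub-50% cells can therefore only be false positives, and suppressing
them with $W_v$ is what improves the mAP. Scoring hopelessly truncated
cells against their full ground-truth labels instead would reward
keeping their scores high and make integrity weighting look harmful —
an artefact of the protocol, not a property of the method.

# Fusion, ensembling, evaluation

**Correlation-gated stream fusion.** For each class, the Pearson
correlation $r$ between image-stream and cell-stream probabilities is
computed over the cells whose parent image carries that label, on a
held-out split — never on training predictions, to avoid leakage. Classes
with $r > \rho_{th} = 0.32$ multiply the two streams; the rest keep the
cell-stream probability (image-level predictions for low-correlation
classes systematically over-label). Undefined correlations (constant
input, fewer than two eligible cells) conservatively fall back to
cell-only.

**Diversity ensembling.** The best-scoring member of each architecture
family is selected (ties broken lexicographically by model id); the
inter-model correlation matrix of flattened probabilities is reported as
the block-diagonal diversity diagnostic. Member outputs are aggregated
hierarchically — mean within family, then mean across families — before
fusion and VID weighting. "Hierarchical" is not defined operationally in
the source material; the family-mean-then-grand-mean reading matches the
family grouping of the inference diagram, and a flat mean over members is
provided as an option.

**Metric.** Predicted cells are matched to ground-truth cells greedily in
descending confidence at mask IoU > 0.6, each ground truth matched at
most once. Per class, every prediction contributes a detection (true
positive only if its matched ground-truth cell carries the class); the
all-point, non-interpolated area under the precision–recall curve gives
the class AP, and the unweighted mean over classes the mAP. Tied
confidences are grouped into a single operating point. The exact
interpolation convention of the competition's two-stage reference is not
published; the all-point form is used and stated here, and in the common
in-pipeline case (predicted masks are the ground-truth masks) the metric
reduces exactly to classification AP, which is cross-checked in the
tests.

# Desk-scale sizing

The benchmark problem sizes are chosen so that the full pipeline —
generation, three model families, two-round refinement, VID, ensembling,
evaluation — runs end to end on a single CPU core in minutes: a reference
manifest of 200 images × 12 cells over C = 6 classes, 24-px crops, and a
two-block trunk (8, 16 channels; descriptor dimension D = 16). The same
`backboneSpec` interface accepts deeper and wider configurations (e.g.
four blocks, D = 128, 128-px inputs) for users with more patience; none
of the package's logic depends on the trunk size.

# Known limitations

* The trunk is a plain small CNN; no pretrained large backbone family is
  bundled, and headline full-dataset scores of large-scale systems are
  out of reach (and out of scope) at desk scale.
* Training supports the logistic multi-label head only; the softmax head
  is inference-only except in the capture-ratio classifier.
* The synthetic generator's geometric archetypes make class separability
  much easier than in real micrographs; benchmark numbers quantify the
  pipeline's mechanics, not expected real-data accuracy.
* Mask post-processing (`postprocessMasks`) implements the
  down-scale/up-scale efficiency trick around thresholding, opening and
  nuclei-seeded region growing; the exact morphological recipe of the
  original segmentation post-processor is not public, so agreement is
  asserted only on label counts for well-separated inputs.
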