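---
title: "Methods: enhancement, architectures, feature selection and evaluation in leafsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancement, architectures, feature selection and evaluation in leafsight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafsight)
```

leafsight implements a complete recognition pipeline for fruit and
vegetable leaf diseases from RGB images: contrast enhancement, autoencoder
class balancing, two custom convolutional architectures with self-attention
feature taps, deep-feature fusion, binary Human Learning Optimization (HLO)
feature selection, and shallow neural-network classification. This vignette
records the models, the tunable parameters, and the design decisions made
where the design was genuinely open.

## Hybrid contrast enhancement

Disease symptoms on leaves are often low-contrast. The enhancement chain
first treats the image as degraded by the haze model

$$I(X) = J(X)\,t(X) + L\,(1 - t(X)),$$

where $I$ is the observed intensity, $J$ the scene radiance, $L$ the global
atmospheric light and $t$ the per-pixel transmission. The dark channel — a
sliding-window minimum (default window 15 px) of the per-pixel channel
minimum — estimates the airlight contribution: `estimate_atmospheric_light()`
averages the colors of the brightest 0.1 % of dark-channel pixels, and the
transmission is $T = 1 - \omega\,\mathrm{dark}(I/L)$ with retention factor
$\omega = 0.95$, so a residue of haze survives and restored images keep
depth cues. Restoration divides by $\max(T, t_0)$ with floor $t_0 = 0.1$.

Two recovery forms are provided. The default, `recovery = "airlight"`,
restores $J = (I - L)/\max(T, t_0) + L$ per channel. The alternative,
`recovery = "offset"`, replaces $L$ by a static scalar offset $a = 0.2$ in
both roles. The offset form is kept because it is the simplest constant-
offset reading of the recovery equation, but it cannot invert a forward
haze synthesis: substituting the model into it leaves a residual bias of
$(1-a)(1-t)/t$ per pixel, which for $t \le 0.9$ exceeds the error of the
hazy input itself. The package therefore defaults to the airlight form —
the test suite checks that dehazing a forward-hazed fixture with constant
$t \in [0.3, 0.9]$ and $L = (1,1,1)$ strictly reduces mean absolute error
to the clean image — and unit-tests the offset form against direct
evaluations of its formula.

Bi-histogram equalization (BiHE) then raises local contrast in five steps:
the 256-bin luminance histogram is smoothed with a Gaussian of width 3
bins; local maxima of the smoothed histogram are detected
(leftmost-of-plateau, greedy suppression within 8 bins); the maxima
partition the intensity axis, each sub-range keeping its own input span as
output dynamic range; each sub-histogram is equalized independently with
the midpoint-CDF convention (a bin maps to the middle of its allocated
mass, so an already-uniform histogram maps to itself within one bin); and
the output mean luminance is shifted back to the input mean. BiHE operates
on Rec. 601 luminance with chrominance preserved by rescaling RGB with the
luminance ratio, since per-channel equalization would shift hue. Constant
images are returned unchanged. Enhancement is deterministic;
`enhance(enhance(x))` is *not* claimed to equal `enhance(x)`.

## Autoencoder class balancing

Small disease classes are expanded to a fixed per-class target (default
1000) by a convolutional autoencoder trained per class at 64×64: encoder
conv(8)/2 → conv(16)/2 → dense latent (default 64); decoder mirrors with
nearest-neighbour upsampling and a sigmoid output. Training is seeded
minibatch SGD with momentum 0.9 on mean squared reconstruction error.
Generation allocates passes over the source images round-robin — with $n$
sources and target $T$ every source yields $\lfloor T/n \rfloor$ variants
and the first $T \bmod n$ sources one more — and each variant decodes a
latent code perturbed with Gaussian noise (sd 0.1; zero noise reproduces
plain reconstructions). The balanced class therefore contains exactly the
target count of generated images. Augmentation runs after the
train/validation/test split and only on the training partition, so
generated variants of an image can never leak into validation or test.

## The two architectures

`build_brwsa()` and `build_ibrwsa()` construct directed acyclic graphs of
layer specifications supporting shape inference, layer enumeration and
learnable counting without allocating weights.

The bottleneck-residual network (224×224×3 input) stacks four groups of
parallel bottleneck paths (1×1 reduce, 3×3 transform, 1×1 restore; ReLU
and batch normalization after the first two convolutions of each path)
with path counts 5/5/5/3 and widths [32,128,32], [128,256,64],
[256,512,128], [512,512,256]; an identity skip joins each group's paths at
an addition node, and stride-2 transition convolutions of depth 64/128/256
link the groups. The tail is conv-512/2, 3×3/2 max pooling, conv-1024/2,
global average pooling, flatten, self-attention (width 1024),
fully-connected softmax head and a classification output node: 149 nodes
in total under the one-node-one-layer convention, 23.6 M learnables.

The inverted-bottleneck network (227×227×3 input) uses five paths per
group that expand with 1×1 (widths 64/128/256/512), apply a channel-wise
3×3 grouped (depthwise) convolution, and squeeze with 1×1
(32/64/128/256); its tail is conv-512/2 + ReLU + batch norm, global
average pooling, flatten, self-attention (width 512) and a
fully-connected softmax head, which enumerates to 161 nodes and 3.9 M
learnables. The second network ends at its softmax node, which doubles as
the output; the layer totals pin this choice.

Design choices worth recording:

* **Layer counting.** Every node — input, convolution, activation,
  normalization, pooling, addition, flatten, attention, softmax, output —
  counts as one layer. This is the convention under which the totals
  149/161 are exact, and both builders carry regression tests pinning them.
* **Self-attention sizing.** The attention layer is single-head scaled
  dot-product attention over the flattened pooled vector with learnable
  query/key/value projections to a reduced key width and an output
  projection restoring the input width. The form is identical in both
  models; the key width is the one free constant left by the design, and
  it is pinned per model to the architecture's parameter budget: 288 at
  input width 1024 and 256 at input width 512. No single key-width rule
  (shared fraction of the width, shared absolute width, dropped or shared
  projections) reproduces both budgets simultaneously, so the width is a
  per-model constant, documented here and in the builders. With a single
  token the attention weight is identically 1, so queries and keys
  contribute capacity and parameter count but receive zero gradient; the
  value/output path carries the features.
* **Padding.** All convolutions and pools use half padding
  (`floor(k/2)`), so stride-1 stages preserve spatial size (making
  identity skips shape-correct) and stride-2 stages halve it rounding up.
* **Skips.** Block input and output channel counts agree everywhere, so
  skips are identity; no projection convolutions are needed.
* **Reduced variants.** `width_scale` shrinks every channel width (and the
  attention key width) by a common factor and `input_side` shrinks the
  input, preserving the topology and layer count. They exist so the
  training path runs in seconds on a CPU; all printed counts refer to the
  default scale.

The execution engine stores activations channels-last, computes
convolutions by im2col + BLAS multiply, and implements a full backward
pass (including depthwise convolutions, overlapping max-pool windows via
winner-offset bookkeeping, batch normalization with batch statistics at
training time, and the attention value path). Analytic gradients are
tested against central finite differences through both full graphs at
reduced scale.

## Training and features

Training is seeded minibatch SGD with momentum on cross-entropy. Default
hyperparameters are the values a hyperparameter search settled on: learning rate 0.0002,
momentum 0.702, minibatch 64, 100 epochs, with a stratified 60:10:30
train/validation/test split (a two-way 70:30 protocol is a common
alternative; the fractions are configurable). Gradients are clipped to a global norm of 5, which leaves
well-conditioned full-scale runs untouched but prevents the occasional
exploding step in aggressive reduced-scale schedules; training aborts with
the epoch index if the loss or gradient turns non-finite. A fixed seed
reproduces the loss history exactly on a fixed BLAS.

Deep features are read at the self-attention tap: N×1024 for the
bottleneck model, N×512 for the inverted-bottleneck model, and
concatenation fusion yields N×1536 with provenance tags preserved.
By default selection operates on features of the test partition, the
protocol this pipeline reproduces; selecting on training features instead
is a one-line change (pass those features) and is the leakage-safe
recommendation for real studies.

## Improved HLO feature selection

Candidate solutions are length-$m$ bit strings (feature masks). Fitness is
$\mathrm{COST} = \rho\,\mathrm{ERROR} + \varsigma\,(\text{selected}/m)$
with $\rho = 0.82$, $\varsigma = 0.02$, and ERROR = 1 − accuracy of a
$k$-NN classifier ($k = 10$, Euclidean distance on z-scored columns) fit
on a single stratified 70/30 train/holdout split of the feature matrix
drawn once per run, so every mask sees the same landscape. An all-zero
mask leaves the classifier undefined and is assigned the worst error
(cost $\rho$).

Each generation regenerates every individual bit-by-bit: with probability
$p_r = 0.1$ a fresh uniform random bit (random exploration); with
probability $p_i - p_r$ ($p_i = 0.85$) a copy from a uniformly chosen
entry of the individual's knowledge database (IKD, capacity $g = 3$);
otherwise a copy from the social knowledge database (SKD, capacity
$h = 3$). Databases stay sorted by cost and deduplicate identical bit
patterns. An individual whose personal best has not improved for 10
generations relearns: its IKD is cleared and reseeded with a fresh
evaluated random solution, while the SKD is untouched — hence the global
best cost is monotone non-increasing, which the tests assert on every run.
The IKD/SKD capacities and the stagnation window are design constants of
this implementation (the operator description leaves them open);
population 10 and 100 generations are the reference settings.

The final mask applies a Bayesian-inference refinement over the SKD: a
per-bit Beta(1,1) posterior over inclusion is updated with rank weights
($h$ for the best member down to 1 for the worst), bits with posterior
mean above 0.5 form the candidate mask, and the best SKD member is kept
instead if it scores better. This is one concrete, testable reading of an
"inference-refined" final selection; on small problems
($m \le 12$) the whole procedure is validated against exhaustive
enumeration of all $2^m$ masks.

`tune_hyperparameters()` reuses the same loop for discrete grids by
encoding each axis index in binary (decoded modulo the axis length), which
is how the training hyperparameters can be searched when one does not
simply adopt the defaults.

## Shallow classifiers and evaluation

The classifier family on selected features: SWNN (one hidden layer of 10),
MN2 (25), N3 (100), BiN2 (100, 100) and TiN2 (100, 100, 100), all ReLU
with softmax outputs, trained full-batch with momentum on z-scored inputs
(max 1000 epochs or loss delta below 1e-6). Every layout is overridable
for users who prefer a different reading of the family's names.
Evaluation is stratified k-fold cross-validation (default 10-fold):
out-of-fold predictions pool into one confusion matrix, from which
per-class TPR, PPV, F1 and FPR and their unweighted macro means derive;
AUC is one-vs-rest macro-averaged on the pooled softmax scores
(`pROC`); zero-denominator classes contribute 0 with a warning. Wall-clock
time is logged but is hardware-dependent and never asserted.

## Synthetic fixtures

`make_leaf_images()` draws textured backgrounds, a fixed elliptical leaf
shape, and class-specific disease blobs (count, size and hue differ by
class; the leaf shape does not), so the class signal lives exactly where
the enhancement stage claims to help; `disease_contrast` scales symptom
visibility, and an optional forward haze with known constant transmission
gives dehazing a ground truth. `make_feature_matrix()` builds matrices
with known informative columns (equally spaced class means separated by a
configurable number of noise standard deviations, class order permuted per
column), redundant noisy copies, and pure noise columns, all tagged.
Everything is bit-reproducible from the seed. These fixtures exercise the
pipeline's *mechanics*; they are far simpler than field photographs (no
pose, occlusion, lighting or background variation), so passing tests
demonstrate correctness of the computations, not field-level accuracy.

## Problem sizes used by the test suite

The default configurations are full study scale (224/227 px inputs,
full-width models, 1000 images per class, 100 epochs, 100 HLO
generations). The test suite exercises the same code paths at sizes chosen
so every check resolves its tolerance: end-to-end runs use 3 classes × 30
synthetic leaves at 32×32 with 1/16-width models (fused feature width 96),
10 training epochs, 40 HLO generations, and 5-fold evaluation on 27 pooled
test samples — at that size one sample moves pooled accuracy by 3.7 %,
below the 5 % acceptance band, and the end-to-end comparison of
pre-selection versus post-selection accuracy is meaningful. The
augmentation contract and the feature-width checks run at full 64×64 and
224/227 resolution respectively. Structural quantities (layer and
parameter counts) are computed on the full-size graphs.

## Known limitations

* Training full-size models to convergence is out of reach of a desk CPU;
  the reduced variants demonstrate the training path, and the full-size
  models are exercised with random weights for structure and feature-width
  checks.
* The single-token attention receives no gradient through its query/key
  projections (see above); with sequence-valued inputs the same layer
  would train them.
* KNN vote ties are broken at random by the underlying implementation;
  runs remain reproducible under a fixed seed, but a tie-heavy landscape
  can make a mask's cost depend on the draw. The shipped configurations
  use two- and three-class problems with small odd effective
  neighbourhoods where ties are rare.
* The offset-form recovery is a faithful transcription of its printed
  equation and is not a working dehazer; it exists for comparison and is
  excluded from the inversion guarantees.
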