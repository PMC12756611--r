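---
title: "Star-shaped multi-scale attention: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-shaped multi-scale attention: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmanet)
```

## The problem

Medical image classification (CT, ultrasound, histopathology, endoscopy,
X-ray) works with small, imbalanced datasets in which lesions vary widely in
shape, size and contrast. Plain convolutional backbones see only local
context; full self-attention is data-hungry and quadratic in resolution.
Channel–spatial attention modules are the middle ground: a learned,
input-dependent re-weighting of a feature map that costs little and can be
dropped into any CNN. This package implements one such mechanism — a
star-shaped multi-scale attention block (StarMA) — and the classification
backbone built around it (StarMA Net), together with the measurement tools a
study of such a model needs: an evaluation-metrics suite, a parameter/MAC
accountant, Grad-CAM visualization and a synthetic lesion-image generator so
every component is testable without any clinical dataset.

## The attention block

Input is a feature map $X \in \mathbb{R}^{B\times C\times H\times W}$.

**Feature grouping.** Channels are split into $G$ contiguous groups of
$C' = C/G$ channels; the group index is folded into the batch axis, so all
further operations act on $(B\,G, C', H, W)$ with weights shared across
groups. $G$ defaults to 8 and every width in the backbone is kept divisible
by it. Ungrouping is the exact inverse (bit-for-bit, tested).

**Cross-channel information interaction branch (CCIB).** Axial average
pooling compresses the map into a per-height descriptor $x_h$ (mean over
width, shape $C'\times H\times 1$) and a per-width descriptor $x_w$
($C'\times 1\times W$). This keeps 1-D spatial structure in each direction
at linear cost — anatomical structures (vessels, lesion boundaries) tend to
extend along an axis, and pooling the orthogonal axis preserves that
continuity. The two descriptors are concatenated into a strip of length
$H+W$, downsampled by a stride-2 $1\times 1$ convolution, and passed through
the *star operation*: two parallel width-preserving $1\times1$ convolutions
whose outputs are multiplied elementwise, one after a GELU —
$\sigma(f(x)\odot \mathrm{GELU}(g(x)))$. The elementwise product of two
learned linear maps implicitly spans the pairwise products of features, a
high-dimensional nonlinear space, at linear cost. The sigmoid output is
restored to length $H+W$ (nearest-neighbour by default) and split back into
a height gate and a width gate. The branch output is

$$x_1 = x_\mathrm{group}\odot\sigma(x_h)\odot\sigma(x_w)\odot
\mathrm{gate}_h\odot \mathrm{gate}_w,$$

four broadcast factors, each strictly inside $(0,1)$.

**Stacked convolution branch (SCB).** Three same-padding, stride-1,
width-preserving convolutions with kernel sizes 1, 5, 7 (applied in that
order) followed by GELU. The stacked kernels widen the receptive field and
supply the multi-scale spatial context the axial branch cannot.

**Cross-spatial feature aggregation (CSFA).** Each branch is summarized by a
channel distribution: the softmax over $C'$ of the spatial mean of
GroupNorm($x_1$) (one normalization group per channel, $\epsilon=10^{-5}$,
identity affine initialization), and of the raw $x_2$. Each distribution
weights the *other* branch's spatial maps via a $1\times C'$ by
$C'\times HW$ matrix product, the two weighted maps are added, squashed by a
sigmoid and broadcast over channels to gate the grouped input. With constant
branch maps $x_1\equiv c_1$, $x_2\equiv c_2$ the whole stage collapses to
$\mathrm{sigmoid}(c_1+c_2)\cdot x_\mathrm{group}$ — a closed form the test
suite asserts.

Because every fused factor is a sigmoid output, the block satisfies three
analytic invariants used throughout the tests: output shape equals input
shape, zero input maps to zero output, and $|$output$| \le |$input$|$
elementwise with equality only at zeros.

### Design choices where the design was genuinely open

* **Axial orientation.** The pooling-kernel naming for the two descriptors
  is internally inconsistent in the originating description; we follow the
  coordinate-attention/EMA lineage: $x_h$ is per-height (mean over width),
  $x_w$ per-width, so the concatenated strip has length $H+W$.
* **Star-gate resolution.** The stride-2 downsampling halves the strip; the
  gate is restored by interpolation (nearest by default, linear available)
  before splitting, because the gate must multiply the full-resolution map.
  The joint gate is realized as the broadcast product
  $\mathrm{gate}_h\odot\mathrm{gate}_w$ — the only reading that is
  shape-consistent.
* **Which map feeds the cross product.** The fusion pseudo-code can be read
  as re-binding $x_1$ to its normalized version before the second product.
  We keep GroupNorm inside the channel-descriptor path only and multiply the
  *raw* $x_1$; this is the reading consistent with the constant-input closed
  form above. A consequence, found during the gradient audit: the GroupNorm
  scale $\gamma$ is structurally inert (the normalized map has zero spatial
  mean, so the pooled descriptor sees only $\beta$); its gradient is
  numerically zero and the parameter simply stays at its initialization.
* **Star convolutions.** The two $1\times1$ maps are independent and
  width-preserving (sharing and widths were unspecified).
* **Sigmoids in the CCIB product** apply to the raw pooled descriptors, with
  no shared pre-convolution — exactly as the branch formula is written.
* **Single-branch ablations.** With only one branch enabled, that branch's
  own channel-pooled softmax-weighted map forms the gate
  ($\mathrm{sigmoid}(x_{kk}\otimes x_k)$, through GroupNorm for the CCIB
  branch); with both branches but no CSFA, the gate is
  $\mathrm{sigmoid}(x_1+x_2)$. All switches on reproduces the full block
  bit-exactly.

## The backbone

StarMA Net is input stream → trunk → output stream:

* **Input stream**: two 3×3 stem convolutions (the first carries stride 2;
  each followed by BatchNorm + GELU), then three Base Blocks — 3×3
  convolution, BatchNorm, GELU, 2×2 max pooling (stride 2), DropPath —
  giving four spatial reductions (224 → 112 → 56 → 28 → 14).
* **Trunk**: four StarMA Blocks at constant width and resolution. Each
  computes $x_a = \mathrm{Conv}_{3\times3}(\mathrm{GELU}(\mathrm{StarMA}
  (\mathrm{BN}(\mathrm{Conv}_{3\times3}(\mathrm{Conv}_{3\times3}(x))))))$
  (a single BatchNorm after the two stacked convolutions, implemented
  literally), adds it residually through DropPath, applies a two-layer MLP
  (1×1 convolutions expanding by `mlpRatio` with GELU between) with a second
  DropPath residual, and finishes with GELU.
* **Output stream**: a Normal Block (Base Block without pooling or
  DropPath), a stride-2 3×3 convolution (14 → 7), a 1×1 convolution,
  BatchNorm, GELU, global average pooling and the linear classifier head.

DropPath (stochastic depth) is whole-feature-map Bernoulli dropping with
survivor rescaling; the experimental rate is 0, under which all forward
passes are deterministic (asserted bit-for-bit in the tests).

**Width calibration.** Channel widths are not published for this
architecture; only the aggregate budget is (≈47.5M parameters, 18.11G MACs
at 224²). The defaults — stem (64, 128), stages (264, 320, 512), trunk 512,
`mlpRatio` 4, output (800, 1024), binary head — were tuned once against that
budget under the MAC convention below and then frozen:

```{r budget}
a <- starmaNetArch(backboneConfig())
c(params_M = countParams(a) / 1e6, macs_G = countMacs(a) / 1e9)
```

`widthMultiplier` scales every width (rounded to a multiple of $G$); 0.5
reproduces the channel-halved variant and cuts parameters by ≈4× (quadratic
width scaling; affine layers deviate slightly).

## Complexity accounting

"FLOPs" columns of model-complexity tables conventionally report fused
multiply-accumulates. The accountant counts, per layer,
$C_\mathrm{out} C_\mathrm{in} k_h k_w H_\mathrm{out} W_\mathrm{out}$ for
convolutions (times the group count for the attention convolutions, which
run once per group with shared weights) and $C_\mathrm{in} C_\mathrm{out}$
for linear layers; normalization, activations, pooling, softmax and the
fusion stage's data–data matrix products are excluded. This convention is
pinned by two independent anchors whose published budgets it must reproduce
— VGG19 (143.67M parameters, 19.63G MACs) and ResNet34 (21.8M, ≈3.7G) at
224², both enumerated layer-by-layer in the test suite by hand.

The channel-coupling index reported alongside such architectures has no
published formula; the package provides a *documented proxy* — the mean
absolute off-diagonal Pearson correlation between channels' attention
weights across samples, plus the mean per-sample variance of those weights —
and tests only its analytic extremes (identical channels → 1, independent
channels → ≈0, constant weights → zero variance). Its numeric values on any
particular dataset are not reproduction targets.

## The neural-network engine

No deep-learning framework is assumed: layers are reference-semantics
environments over base-R arrays, convolutions run as one BLAS GEMM per layer
over an im2col patch matrix built in C++ (with the matching col2im adjoint),
and every backward pass is a hand-derived adjoint. Correctness rests on two
independent lines of evidence in the test suite: forward passes against
straight-line loop/matrix oracles (tolerance $10^{-5}$), and analytic
gradients against central finite differences at $\varepsilon=10^{-5}$
(relative tolerance $10^{-3}$) across randomly sampled parameters of the
full network in both BatchNorm modes. GELU is exact
($x\,\Phi(x)$), with its derivative computed at forward time. AdamW applies
decoupled weight decay to convolution/linear weight matrices only. BatchNorm
keeps running statistics (momentum 0.1, $\epsilon=10^{-5}$); evaluation mode
is deterministic. Truncated-normal initialization (sd 0.02, resampled beyond
2 sd) with zero biases is pinned by the configuration seed.

## Training protocol

Defaults follow the reference protocol: learning rate $10^{-5}$, batch size
16, 100 epochs, AdamW (the settings table's plain Adam is available as an
option), cross-entropy loss, bilinear resize to 224×224, pixel scaling to
$[0,1]$ with no further standardization and no augmentation, per-epoch
validation and best-validation checkpointing, all randomness under one seed.
"Iterations" in the protocol are read as epochs, consistent with per-epoch
validation checkpointing.

Three optional pipeline elements extend the defaults for short schedules,
all off unless requested: a cosine learning-rate decay (`lrSchedule`),
random horizontal/vertical flips of training batches (`augment = "flip"`, a
label-preserving augmentation for lesion geometry), and an exponential
moving average of the weights adopted as the final model (`emaDecay`).
Independent of these, training always ends with *precise BatchNorm
re-estimation*: one pass over the training split with frozen weights
replaces the momentum-based running statistics with the exact mean of
per-batch statistics. Momentum averages lag the weights whenever the
schedule is short relative to the learning rate; without the
re-estimation, evaluation-mode accuracy can sit far below training-mode
accuracy on freshly trained models.

## The synthetic generator, and what passing its tests shows

`syntheticImageSpec()` describes grayscale images with one elliptical lesion
each (class-specific radius band, eccentricity, contrast, texture frequency)
on a textured background, degraded by multiplicative speckle (variance 0.05)
and additive Gaussian noise (sd 0.02) — an ultrasound-like corruption model.
The radius parameter is the *equivalent radius*: semi-axes are
$r/\sqrt{e}$ and $r\sqrt{e}$, so the lesion area is exactly $\pi r^2$
for any eccentricity $e$ and disjoint radius bands give size-separable
classes by construction (with axis-aligned semi-axes $r$ and $re$ the area
would span $\pi r^2 e$ and adjacent classes could overlap). Every image
stores its lesion mask, generation is bit-reproducible under the spec
seed, and splits
are stratified 7:1.5:1.5 with round-to-nearest sizing and the remainder to
train (780 samples → 546/117/117). Class-count presets can mirror imbalanced
public corpora (e.g. 133/437/210 for a three-class breast-ultrasound
layout).

The generator emulates *geometry, contrast and speckle*, not pathology: real
lesions have irregular boundaries, heterogeneous texture, acquisition
artifacts and inter-patient variation that the ellipse model lacks. Passing
the learnability test therefore shows the network, optimizer and gradients
work end-to-end on a lesion-like task — it says nothing about clinical
accuracy, which is why the published benchmark accuracies on external
datasets are explicitly out of scope here.

**Learnability smoke protocol.** A slim model (`widthMultiplier` 0.25) on
64×64 inputs, 3 classes × 100 images split 240 train / 60 test, 15 epochs.
The short-schedule optimizer settings are learning rate $10^{-4}$ with
batch size 8 and flip augmentation: the reference $10^{-5}$ belongs to the
100-epoch protocol and would barely move a freshly initialized network in
15 epochs, and within the fixed epoch cap the number of optimizer updates
(450 at batch 8) — not the step size — proved the binding constraint, with
larger rates fitting the training set while generalizing worse. The check
asks for held-out accuracy ≥ 0.9, plus the Grad-CAM localization property
below on ≥ 80% of test images. These problem sizes are the package's
chosen validation scale: large enough for the separable task to be
learned, small enough to run routinely on one CPU.

## Grad-CAM

Standard gradient-weighted class-activation mapping at the output of the
last StarMA Block: the class score's gradient is global-average-pooled per
channel, the pooled gradients weight the activation channels, the weighted
sum is rectified, max-normalized to $[0,1]$ and bilinearly upsampled to the
input size. BatchNorm uses running statistics during the Grad-CAM pass
(gradients flow through the frozen affine map), so the heat map is
deterministic and the model is not perturbed. The localization check asks,
per image, whether mean heat inside the stored lesion mask exceeds the mean
outside. Its resolution limit should be kept in mind when reading the
score: at 64×64 input the last StarMA Block is a 4×4 map, so each CAM cell
covers 16×16 pixels. Large lesions (several cells) localize essentially
always; the smallest class (equivalent radius 5–8 px, under one cell)
localizes far less reliably — for that class the network's evidence is
partly global (the absence of a large lesion), which gradient-weighted
maps faithfully report as diffuse heat. The aggregate fraction therefore
varies with the generator seed.

## Numerical notes and degenerate inputs

* Grouping requires $C$ divisible by $G$; violations raise configuration
  errors naming both numbers, as do backbone widths not divisible by $G$.
* The gate strip needs $H+W \ge 2$; max pooling needs both spatial sizes
  ≥ 2; degenerate inputs raise errors rather than producing empty maps.
* Zero denominators in metrics (empty classes, single-class predictions)
  yield 0 with a warning; single-class truth makes AUC an error, since no
  ROC exists.
* ROC ties are grouped per unique score; the AUC equals the Mann–Whitney
  pair-count statistic to $10^{-10}$.
* Softmax and row-softmax subtract row maxima before exponentiation.
* Nearest upsampling uses the index map
  $j = \lfloor (i-1)\,L_d/L \rfloor + 1$, exact inverse-scaled flooring, so
  odd $H+W$ strips round-trip consistently.

## Known limitations

* The engine is CPU-only and R-double precision; wall-clock training at the
  published scale (224², 100 epochs, five datasets) is out of reach and out
  of scope — the package validates the mechanism, the accounting and the
  pipeline, not the benchmark numbers.
* The GroupNorm scale parameter is inert under the chosen fusion wiring
  (see above); it is retained for fidelity to the stated layer but carries
  no information.
* Inference latency is hardware-bound and deliberately not measured.
* The channel-coupling index is a proxy with no external numeric target.
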