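---
title: "Methods: small-object bird detection building blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-object bird detection building blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package is

`aviscan` implements, as independently testable components, the network
modifications used to detect small, dense, frequently occluded birds in
fixed-camera wetland surveillance imagery: a receptive-field attention
convolution for the backbone, a four-level multi-scale fusion neck with
dynamic upsampling and Gaussian scale-sequence fusion, a lightweight shared
detail-enhanced detection head, and the Inner-ShapeIoU bounding-box
regression loss. Around these sit a scene generator that emulates the
statistics of such footage, a full anchor-free training loop, a detection
metric kit, and exact parameter/FLOP accounting.

R has no deep-learning framework in this toolchain, so the package carries
its own minimal tape-based reverse-mode autodiff engine over dense `(H, W,
C, N)` arrays, with compiled (Rcpp/Armadillo) kernels for convolution,
pooling and bilinear grid sampling. The engine is infrastructure: every
module above it is ordinary R code that runs identically on plain arrays
(inference) and on taped tensors (training).

## The box-loss family

All losses operate on centre-form boxes $b = (x_c, y_c, w, h)$ with $w, h >
0$. Plain IoU is intersection over union, defined as 0 for disjoint or
degenerate (edge-touching) pairs.

**Shape-IoU.** The ground-truth box's side lengths set direction weights
with a size exponent (`scale`, default 0):

$$ww = \frac{2\,w_{gt}^{scale}}{w_{gt}^{scale}+h_{gt}^{scale}},\qquad
  hh = \frac{2\,h_{gt}^{scale}}{w_{gt}^{scale}+h_{gt}^{scale}},$$

so $ww + hh = 2$ always. The distance term pairs $hh$ with the x-offset and
$ww$ with the y-offset (this pairing follows the loss's original
formulation) and is normalised by $c^2$, the squared diagonal of the
smallest box enclosing both boxes — the standard choice in the DIoU family;
the source formulation leaves $c$ implicit. The shape cost uses absolute
relative side differences,

$$\Omega = \sum_{s \in \{w,h\}} \left(1 -
  e^{-|s - s_{gt}| / \max(s, s_{gt})}\right)^{\theta},$$

with $\theta = 4$ by default; the signed variant would be negative for one
ordering, so the absolute value is the only self-consistent reading. The
total is $1 - IoU + distance + 0.5\,\Omega$.

**Inner-IoU.** Both boxes are scaled by `ratio` $\in [0.5, 1.5]$ about
their own centres and plain IoU is computed on the auxiliary pair. The
printed construction of the anchor's auxiliary box mixes ground-truth
centre terms into its boundaries; the package defines the inner anchor
symmetrically about the anchor's own centre — otherwise `ratio = 1` would
not reduce to plain IoU, which is the defining property of the construction.

**Inner-ShapeIoU** is $L_{shape} + IoU - IoU_{inner}$. At `ratio = 1` the
correction vanishes; the implementation short-circuits that case so the
identity is exact in floating point, not merely close. Defaults are
`scale = 0`, `ratio = 1` (neutral): no tuned values are available for these
two parameters, so the package does not invent any.

All four losses (`ciou`, `shape_iou`, `inner_shape_iou`, `iou`) are written
over generic elementwise operations, so the training loop differentiates
through them directly; the test suite checks tape gradients against central
differences at $10^{-4}$ relative error, and analytic IoU against a
pixel-rasterisation oracle.

## Receptive-field attention convolution

For each input channel, a grouped $k \times k$ convolution (groups = C, so
each channel owns its $k^2$ kernels) expands the map to $C k^2$
receptive-field slots; in parallel, average pooling over each receptive
field followed by a grouped $1 \times 1$ convolution produces slot logits,
and softmax across the $k^2$ slots of each channel yields attention weights
that sum to 1 per channel per site. The weighted slots are laid out
spatially ($k H \times k W$) and re-aggregated by a $k \times k$ convolution
with stride $k$, making the block a drop-in replacement for a standard
convolution of the same kernel and stride. "Norm" on the expanded features
is batch normalisation, per the mechanism's reference implementation. In
the bird variant, the four strided downsampling convolutions of the
backbone are replaced; the stem is not (the replacement set is exposed only
through the `rfaconv` flag, since the source architecture diagram marks the
backbone stages without enumerating them).

## The DyASF-P2 neck

The backbone emits P2–P5 (strides 4/8/16/32; 160/80/40/20 cells at a
640-pixel input). The neck fuses them with:

- **DySample** — upsampling whose sampling positions are the regular
  bilinear grid plus content-dependent offsets predicted by a $1 \times 1$
  convolution, bounded by a 0.25-cell scope factor, with 4 offset groups;
  values are read by bilinear interpolation with border clamping. With all
  offset weights zero it is exactly bilinear upsampling — a
  regression-tested contract.
- **SSFF** — deeper levels are channel-aligned, DySample-upsampled to the
  shallowest input's size, smoothed with a normalised Gaussian
  ($\sigma = 1$ per level by default; no value is stated anywhere upstream,
  and $\sigma$ is configurable), stacked along a scale axis of depth 3, and
  reduced by a 3-D convolution with kernel 3 along scale and $1 \times 1$
  spatially. Since the kernel spans the whole scale axis without padding,
  this 3-D convolution is computed as its exact algebraic equivalent: a
  $1 \times 1$ 2-D convolution on the channel-stacked maps.
- **TFE** — large/medium/small branches are channel-adjusted to a common
  width, the large branch downsampled by the element-wise mean of 2×2 max
  and average pooling (the simplest reading of "combining" the two pools,
  keeping channel width fixed), the small branch upsampled by nearest
  neighbour, and the three concatenated along channels.

Wiring: a TFE over (P2, P3, P4) and an SSFF over (P5, P4, P3) are added at
the P3 level; the result is DySample-upsampled and merged with P2 alongside
a second SSFF over (P4, P3, P2) to form the added P2 output; a second TFE
over (fused-P3, P4, P5) forms the P4 output; a strided convolution plus
merge with P5 forms the P5 output. Four levels feed four heads; Gaussian
smoothing and reflect padding make SSFF exactly mean-preserving on constant
regions.

The neck's output widths (336/384/512/640 before the compound width
multiplier; 84/96/128/160 at nano scale) and the TFE widths (192/256 base)
are free constants — no reference prints them. They were fixed once so that
the complete bird variant meets its published budget of ≈2.2 M parameters
and ≈12.1 GFLOPs at 640 px, and are not revisited. A consequence worth
knowing: the intermediate ablation that pairs this neck with the *standard*
(unshared) head is considerably more FLOP-hungry than the published
intermediate row, because the standard head is expensive at the added
160×160 level; only the direction of the change (more FLOPs than the
baseline) is treated as a contract.

## The LSDECD head

Each neck level passes through a level-specific $1 \times 1$ convolution
with group normalisation to a shared width, then through **two shared**
DEConv+GN blocks — one parameter set used at every level, which is where
the parameter saving comes from — and finally through decoupled per-level
$1 \times 1$ classification (nc channels) and regression
($4 \times reg\_max$ channels) convolutions. A per-level learnable scalar
(initialised to 1) multiplies the regression features before the regression
convolution, compensating for the scale statistics differing across pyramid
levels. The sharing contract covers exactly the two DEConv blocks: an
earlier design iteration that also shared the output convolutions trained
noticeably worse, because one classifier weight set then has to serve
feature distributions from four pyramid scales at once.

Detail-enhanced convolution is the sum of five parallel $3 \times 3$
branches: vanilla plus central/angular/horizontal/vertical difference
convolutions. Each difference branch stores a raw kernel and convolves with
a linear transformation of it (centre-minus-sum for the central difference;
cyclic first differences along rows/columns for horizontal/vertical; kernel
minus its 90°-rotation for angular — exact tap arithmetic is documented in
the source). Every transformation has zero tap sum, so difference branches
annihilate constants; and because all transformations are linear, the five
branches fuse exactly into one kernel for deployment (`deconv_fuse`),
verified to $10^{-5}$ against the branch-sum, including after gradient
updates.

Head defaults: shared width 64 before the width multiplier (16 at nano) —
chosen, like the neck widths, against the published parameter budget of the
head-only ablation (≈2.3 M) — GN groups 16, `reg_max = 16` with
distribution-style box regression retained from the baseline head (the head
modification touches its convolutions, not the box encoding). Group
normalisation uses at most 16 groups but never fewer than four channels per
group where the width allows: at reduced desk-scale widths, one-channel
groups degenerate into per-channel instance normalisation over a handful of
cells, which destroys the information the classifier needs (observed as a
training plateau before the rule was adopted). At the default width of 64
this reproduces plain 16-group GN.

## Assembly, cost accounting and training

The baseline is the standard nano-scale anchor-free detector: C2f/SPPF
backbone (widths 16/32/64/128/256, depths 1/2/2/1), PAN neck, decoupled
three-level head. Flags `rfaconv`, `dyasf_p2`, `lsdecd` and the loss name
switch in each improvement independently, giving the full 8-way ablation
grid.

`count_params()` counts trainable scalars exactly (the fixed DFL expectation
weights and Gaussian kernels are buffers, not parameters).
`count_flops()` runs a real forward pass with counting hooks and sums
2×multiply–accumulates over parameterised convolution and affine layers
only — pooling, activations, normalisation and fixed-kernel convolutions
are excluded. Conventions differ across tools; this one reproduces the
published baseline figure (8.1 GFLOPs at 640 px) and is stated here because
any comparison must use the same rule. Under it, the 5-class baseline
counts 3,011,807 parameters (3.0 M at one decimal — the often-quoted 3.1 M
corresponds to the 80-class head), the full bird variant 2,190,280 (2.2 M)
at 12.1 GFLOPs, and the head-only ablation 2,293,426 (2.3 M).

Training uses task-aligned assignment (top-10 candidates per target,
alignment metric $s^{0.5} u^{6}$, centre-inside gating) and the composite
loss BCE-classification + box loss + distribution-focal, weighted
0.5/7.5/1.5 — all retained baseline infrastructure; the box-loss term is
the only component the loss flag changes, and a test pins that isolation.
The optimiser is plain momentum SGD (momentum 0.9) by default, with a
constant learning rate decayed 10× for the final 20% of steps, global-norm
gradient clipping at 10, and full determinism for a fixed seed in
single-threaded mode; an Adam option exists because on few hundred-image
desk-scale sets it converges in roughly a third of the steps, which is what
keeps the trainability demonstration inside a coffee break. Upstream
training hyper-parameters are not published; these defaults matter only for
the desk-scale demonstrations, not for the correctness of any module.

## The synthetic scene generator

Scenes emulate the *box statistics* of wetland surveillance frames — object
density (1–12 per image), scale variation (2–40% of the image side),
constructive occlusion pairs, cluttered low-frequency backgrounds, five
classes with distinct hue and silhouette (the last class rendered pale and
low-contrast, as pale swans against bright water) — not their photometry.
Objects are harmonically perturbed ellipses; boxes are tight to rendered
pixels, normalised, in YOLO label format; splits follow the 7:2:1
floor-then-carry rule (8077 items split exactly as 5653/1616/808). What
passing tests on this generator show is that the detection machinery —
assignment, losses, decoding, NMS, metrics — is correct and trainable
end-to-end; they say nothing about accuracy on real imagery, which would
require the real footage and full-scale GPU training (out of scope here).

## Desk-scale problem sizes

Everything is verified at sizes a single CPU handles in minutes: unit
oracles run on 4–16 channel maps of 6–16 cells; architecture accounting
builds the real 640-px models (seconds to count parameters, ~15 s of dense
arithmetic to count FLOPs); the learnability demonstration trains a
width-multiplier-0.125 bird variant (head width 32) for 12 epochs of Adam
on 500 easy 64-px synthetic scenes (one or two large, well-separated
objects each) and checks mAP@0.5 ≥ 0.5 on 100 validation scenes — a
self-consistency bar for the pipeline, not a reproduction of any published
accuracy. Input sizes below 64 px are not used for training: at 32 px the
deepest pyramid level is a single cell and its batch statistics become
degenerate.

## Numerical choices and degenerate inputs

- Disjoint and edge-touching boxes give IoU 0, not an error; invalid boxes
  (non-positive sides) raise errors at construction.
- Softmax is computed with max-subtraction; BCE on logits with the
  log1p-of-exp form; DFL bin probabilities are floored at $10^{-9}$ before
  the log.
- Batch normalisation uses batch statistics in training and running
  statistics (momentum 0.1) at inference; group normalisation has no
  running state. Variance estimates are floored at 0 before adding
  $\epsilon = 10^{-5}$.
- Ties in elementwise max/min take the first operand's subgradient;
  `ratio = 1` and all-zero-offset paths are short-circuited to their exact
  algebraic reductions.
- Reflect padding mirrors without repeating the border pixel, which
  combined with a unit-sum kernel preserves constants exactly.

## Known limitations

- The generator's rendered blobs carry no texture detail, motion blur or
  lighting variation; detectors trained on them do not transfer anywhere.
- The tape engine is single-threaded R plus sequential Armadillo GEMMs:
  adequate for the desk-scale sizes above, two orders of magnitude away
  from GPU training.
- The intermediate neck-only ablation row's absolute cost depends on head
  pairing (see above); only the full variant's budget is pinned.
- Rotated boxes, additional IoU variants (GIoU/DIoU/SIoU), FPS
  benchmarking and attention heatmaps are out of scope.
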