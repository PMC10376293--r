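---
title: "Small-target goat face detection: models, losses and statistics"
author: "capriDetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-target goat face detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capriDetect)
```

# The problem

Goat faces filmed in pastures and barns are small targets in the
absolute sense: a face whose bounding-box side exceeds 50 px is not a
small target, and the faces of interest span 8–55 px on a 1920×1080
frame, with most side lengths between 24 and 32 px. At that scale a
face occupies a handful of feature-map cells after the first few
strides, its texture is weak, and background clutter of similar spatial
frequency competes with it. `capriDetect` implements an anchor-based
one-stage detector specialized for this regime, the loss it is trained
with, the data pipeline that produces its training sets, the detection
metrics it is judged by, and the rank statistics used to compare it
against other detectors.

# The detector

The network has the usual three-part layout: a compact CSP-style
backbone tapped at strides 8/16/32, a neck, and three YOLO heads. For a
640-px input and one class the heads emit (80, 80, 18), (40, 40, 18)
and (20, 20, 18): each of 3 anchors per cell carries 4 box parameters,
1 objectness and 1 class score. The backbone is deliberately generic —
the architectural contribution lives in the neck — and only its
stride/channel contract matters: channels grow 1/2/4/8/16× a base width
from stride 2 to stride 32.

**Spatial pyramid pooling (CSP form).** The deepest tap passes through
a split block: one half is max-pooled at kernels 5/9/13 (stride 1, same
padding) and fused, the other bypasses; the halves are concatenated and
reduced. This widens the receptive field at constant resolution.

**Context module.** Each pyramid level is enriched with (i) local
context — four parallel 3×3 dilated convolutions with rates 1–4
(padding = rate), each emitting a quarter of the channels, concatenated
back to full width — and (ii) neighbor context: the adjacent coarser
level is upsampled (bilinear ×2), gated by efficient channel attention
(ECA: global average pool, 1-D cross-channel convolution, sigmoid
gate), and projected; the adjacent finer level is average-pooled ×2 and
treated likewise. The output is the elementwise sum of the branches
present. At the pyramid ends the missing neighbor branch is dropped —
this is the reduced variant of the module, and we take "absent
neighbor" to be the only interpretation that type-checks at the ends of
the pyramid.

**Feature-complementary fusion.** The three context outputs are aligned
to a common width by dilated convolutions with kernels 3/5/7, then
fused pairwise. For a pair (f1 fine, f2 coarse):

- `f12 = Conv(down(f1)) · Conv(f2)` (coarse resolution),
- `f21 = Conv(up(f2)) · Conv(f1)` (fine resolution),
- up path: `Conv(f21) · Conv(up(f12))`,
- down path: `Conv(f12) · Conv(down(f21))`,

with `up` = bilinear ×2 and `down` = 2×2 average pooling. The products
keep only structure both resolutions agree on; the absolute difference
|up path − resampled down path| then cancels what the two paths share —
background — while preserving where they disagree, which is where
resolution actually matters. The (f1,f2) and (f2,f3) difference maps
are resampled to the block's target stride (finest for the "up" block
feeding the stride-8 head, coarsest for the "down" block feeding
stride 32), concatenated, and reduced 1×1. The exact pairing and the
operands of each difference are not fully determined by the source
figures; the wiring above is this package's documented choice, fixed by
the resolution contract (each block must emit one tensor at its target
stride) and kept minimal.

**Heads and decoding.** Each head is a bare 1×1 convolution. Decoding
follows the YOLOv5 convention: cell offset `2σ(t) − 0.5` (range −0.5 to
1.5, matching the neighbor-cell assignment below), size
`(2σ(t))² · anchor`, objectness and class through sigmoids, greedy NMS.

# Anchors and assignment

The nine small-target priors (5,9) (12,16) (19,36) / (42,31) (40,28)
(55,48) / (36,75) (76,55) (72,146) replace the stock COCO-scale priors,
whose smallest template (12,16) already exceeds many of the faces. The
18 printed sizes pair by adjacency; grouping is by ascending area,
three per stride. `kmeansAnchors()` re-derives priors for any box set
by k-means under the 1 − IoU distance (templates compared at a common
origin) with seeded k-means++ initialization; its objective is
non-increasing by construction and is exposed for inspection.

Training-sample assignment is the YOLOv5-style rule: an anchor matches
a ground truth when `max(w/aw, aw/w, h/ah, ah/h) < 4`, and a match
produces positives at the box's cell and its two nearest neighbor
cells. The dynamic label-assignment schemes of newer detectors are out
of scope on purpose: the contribution under study is the neck and the
loss, and a fixed, enumerable assignment keeps every positive
verifiable by brute force (the test suite does exactly that).

# The loss

`Loss = 0.1·L_conf + 0.125·L_cls + 0.05·L_loc`, with binary
cross-entropy (sample weight ω, default 1) for confidence and class,
and `L_loc = 1 − s` for a configurable overlap score s ∈ {IoU, GIoU,
DIoU, CIoU, wh-CIoU}.

wh-CIoU replaces CIoU's aspect-ratio consistency term with separate
width- and height-ratio penalties:
ε = (2/π²)[(arctan(w_pr/w_gt) − π/4)² + (arctan(h_pr/h_gt) − π/4)²],
β = ε/((1 − IoU) + ε), score = IoU − ρ²/d² − βε. Two subtleties are
worth recording:

- **Sign of ε.** The printed form subtracts the height term from the
  width term, which would allow a negative "penalty" and reward height
  mismatch whenever the width matches; the stated motivation (each
  dimension's deviation measured separately, minimized jointly) implies
  a sum. The default is the sum (`epsCombine = "plus"`, penalty ≥ 0 and
  0 exactly at a perfect size match); the subtractive form is retained
  behind `epsCombine = "as_printed_minus"` and both are unit-tested.
  Neither is silently "corrected".
- **Symmetry.** Although the ratios are directional (prediction over
  ground truth), the value is swap-invariant: arctan(x) + arctan(1/x) =
  π/2 makes each squared deviation invariant under reciprocals. The
  tests verify the directional formula and this identity rather than a
  spurious asymmetry.

Degenerate inputs: geometric operations clamp box sides to 1e−7 px;
loss functions raise on nonpositive ground-truth sides; probabilities
are clamped to [1e−7, 1 − 1e−7] before logarithms; β·ε is defined as 0
when ε = 0 (continuity); d² is the squared diagonal of the smallest
enclosing box (standard DIoU convention). Coordinates are continuous
pixels with no +1 convention; VOC's 1-based inclusive integers are
converted on read and restored on write.

# The training engine

No deep-learning framework is used: the package carries a minimal
reverse-mode tensor engine (R, with Rcpp kernels for im2col/col2im,
pooling and bilinear resampling) sized exactly to this architecture.
Convolutions are im2col + BLAS matrix products; batch normalization
(momentum 0.1, eps 1e−5) and SiLU follow every convolution unless an
equation names a bare Conv; initialization is Kaiming for convolutions
under a single model seed. The optimizer is AdamW with decoupled decay
(biases, batch-norm and attention parameters excluded).

Gradients of the confidence/class BCE terms are analytic. The
localization term's gradient is taken by central finite differences on
the four raw box outputs of each positive sample (8 scalar evaluations
of the decode + overlap chain, step 1e−3 on the logit scale): the
overlap scores are piecewise-smooth maps of four variables, so the
stencil is accurate to well below optimizer noise, and the whole
engine's correctness is pinned by a finite-difference check of the full
backward pass in the test suite (relative error ~1e−6 at sampled
parameters).

The default protocol mirrors the study settings: batches of 8, initial
learning rate 1e−4, AdamW, 100 epochs with checkpoints every 10
("iterations" in the protocol are read as epochs — a checkpoint cadence
of 10 only makes sense at epoch granularity for a dataset of thousands
of images). Checkpoints are self-describing (configuration + anchors +
weights + batch-norm statistics). The training input resolution is
never stated by the protocol; the head shapes imply 640 and that is the
default, configurable.

# The synthetic scene generator

The field dataset (8,871 images, 65,894 faces, Albasian velvet goats,
collected 06:00–18:00) is not deposited, so `synthScene()` generates
the study conditions: 1920×1080 frames (640 or smaller for training),
4–11 faces per frame (the field set averages ≈ 7.4), face max-sides
uniform in 8–55 px, optional clustered placement (half of scenes, 1–3
Gaussian clusters), a global illumination factor in [0.5, 1.1]
emulating the dawn-to-midday range, and Gaussian sensor noise
(σ = 0.02). Faces are two-tone ellipses with eye dots and darker
muzzles on a low-frequency cluttered background; boxes are exact by
construction and every scene is bit-reproducible from its seed.

What this does and does not show: passing tests on synthetic scenes
demonstrate that the geometry, assignment, loss, optimization and
evaluation machinery are correct and that the full network can fit
structured small targets; they say nothing about accuracy on real goat
imagery, whose pose variation, occlusion and texture the generator does
not attempt to model. The published real-data accuracies are therefore
never asserted by the test suite; the statistics computed *from* the
published tables are.

# Data pipeline choices

- The small-target filter is image-level, as in the dataset's
  construction: an image is kept iff every face is ≤ 50 px (a 50-px
  face is itself small — "larger than 50" is removed); a box-level mode
  exists for other workflows. The filter is idempotent.
- Mosaic stitches four scaled, cropped sources around a random center;
  clipped boxes below 8 px² are dropped (documented constant, avoids
  degenerate slivers).
- Mixup blends images as λa + (1−λ)b and unites labels at weights λ and
  1−λ; λ ~ Beta(8, 8) when unspecified (the YOLO-family convention; no
  distribution is prescribed by the protocol).
- Video frame extraction is out of scope; the generator emits stills.

# Evaluation

Greedy score-descending one-to-one matching (ties broken by index) at
IoU 0.7, the threshold used throughout the study; precision, recall and
F1 at a confidence cutoff (0.5 by default — the study does not state
its cutoff, so the default is documented rather than asserted as the
authors'); AP as the all-point interpolated area under the PR curve
(modern VOC/COCO practice; the 11-point variant is not used). The AP
implementation is checked against a brute-force enumeration over score
cuts, and its tie handling is permutation-stable.

# Model-comparison statistics

`rankModels()` ranks k detectors per metric (ties averaged),
`friedmanRankTest()` computes the classical statistic
12/(nk(k+1))·ΣR_j² − 3n(k+1) with the standard tie correction (on by
default; tie-free tables are unchanged), and `nemenyiCD()` evaluates
CD = q_α(k)·√(k(k+1)/6n) from the embedded critical-value table
(q₀.₀₅: 1.960, 2.343, 2.569, 2.728, 2.850, … for k = 2…; also α = 0.1).
On the published six-model small-target ranks this gives χ² = 14.429
(p ≈ 0.013) and CD = 3.770; on the four-configuration ablation ranks,
χ² = 12 (p ≈ 0.007) and CD = 2.345. Two defects of the published
normal-size comparison are recorded and not "fixed": its printed χ² =
18.813 is reproducible from neither the classical nor the tie-corrected
statistic on its printed ranks, and its P-rank column transposes the
two weakest models relative to its own metric table. The package
computes the honest statistics; `stats::friedman.test` serves as an
independent oracle in the tests.

# Problem sizes used by the test suite

All checks run on one CPU. Geometry properties use 200 random
integer-cornered box pairs against a subpixel rasterization oracle;
gradient-descent monotonicity runs 500 steps at step size 1 (larger
steps overshoot the plateau where boxes are disjoint and the gradient
is small — the documented demonstration setting). Network contracts are
exercised at 32–64 px inputs with base widths 4–8; the forward pass is
checked finite over 100 random inputs; backpropagation is
finite-difference-checked at 7 sampled parameters. The end-to-end run
overfits eight 64×64 scenes (two 12–28 px faces each) for 300 epochs at
learning rate 5e−3 with anchors clustered from the training boxes,
reaching ≥ 90 % loss reduction and train-split AP@0.5 ≥ 0.9; 5e−3
rather than the full-scale 1e−4 is the standard choice for a full-batch
overfit of a freshly initialized small network, and the run doubles as
the determinism check (it is seed-exact).

# Known limitations

- The backbone is a stand-in honoring the stride/channel contract, not
  a replica of any published backbone; re-parameterized inference
  graphs, auxiliary heads and dynamic label assignment are out of
  scope.
- The fusion block's internal wiring beyond the text's equations is a
  documented package decision, not a claim about the original figures.
- The training engine is single-threaded CPU code built for desk-scale
  experiments; it is not a route to full-scale training.
- Synthetic scenes do not model pose, occlusion, or real goat-face
  texture; conclusions about real-data accuracy cannot be drawn from
  them.
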