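---
title: "Methods: lightweight attention blocks for rice-disease detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight attention blocks for rice-disease detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdblocks)
```

# Scope and model

`rdblocks` re-implements, as a tested R library, the bespoke components of a
lightweight single-stage rice-disease detector: a decomposed
large-separable-kernel attention operator (LSKAC), the SPPFLKC
pooling-attention block built around it, the CAFormer/CGLU
spatial-and-channel reconstruction pair (C3k2-CFCGLU), the joint
channel-spatial attention CSCBAM (C3k2-CSCBAM), an extra high-resolution
small-object detection head, the full model assembly with closed-form
complexity accounting, a YOLO-format data pipeline, a synthetic paddy-scene
generator, and a detection-metrics evaluator. Everything runs on the CPU on
top of a compact dense conv-net engine with reverse-mode differentiation
that is part of the package (`src/nn_ops.cpp`, `R/autograd.R`); its
gradients are verified against finite differences in the test suite.

The three object classes are the foliar diseases Brown Spot (small dark
punctate-to-necrotic spots), Rice Blast (spindle-shaped lesions with pale
centers) and Bacterial Blight (elongated marginal stripes).

# LSKAC

A large $k \times k$ depth-wise convolution is decomposed into

1. a cascaded pair of 1-D depth-wise kernels, $1\times(2d-1)$ followed by
   $(2d-1)\times 1$, capturing the local neighbourhood;
2. a $\lfloor k/d\rfloor \times \lfloor k/d\rfloor$ depth-wise convolution
   with dilation $d$ covering long-range context;
3. a $1\times1$ channel-mixing convolution.

The chain output is an attention map $A$ applied as a Hadamard gate,
$\bar F = A \odot F$. There is no nonlinearity inside the chain, so the
attention response is homogeneous in the input — a property the tests
exercise directly.

The closed-form complexity is
$$\mathrm{Param}_{\mathrm{LSKAC}} = (2d-1)\,C\cdot 2 +
\lfloor k/d\rfloor^2 C + C^2, \qquad
\mathrm{FLOPs} = \mathrm{Param}\cdot H W,$$
with the LSKA reference variant replacing the first term by $(2d-1)^2C$.
One multiply-accumulate counts as one FLOP throughout the package — this is
the convention under which the formula "parameters × positions" is exact.
Two design points keep the formula/structure equality exact, and the test
suite asserts it over randomized $(C,k,d)$:

* all LSKAC convolutions are bias-free (a bias would add $C$ parameters the
  closed form does not contain);
* the two 1-D *dilated* kernels sometimes drawn as intermediate steps of
  the decomposition are realized by the single 2-D dilated kernel whose
  separable composition they describe; instantiating them separately would
  add $2\lfloor k/d\rfloor C$ parameters and break the closed form.

Defaults are $k=23$, $d=3$, a standard large-kernel decomposition setting.

# SPPFLKC

The block keeps the SPPF skeleton — $1\times1$ reduction to half width,
three serial stride-1 max-pools with a kernel of 5 — and adds
(a) an LSKAC gate after the reduction, (b) a parallel stride-1 average-pool
branch, and (c) a single-head channel self-attention before the output
$1\times1$ convolution. The five concatenated maps are re-weighted by
$1 + n\,\mathrm{softmax}(\mathrm{GAP}(U))$, a residual form chosen so an
uninformative descriptor leaves channels approximately unscaled instead of
crushing them by $1/n$. Max-pool padding uses $-\infty$ semantics; average
pooling excludes padded cells. The exact branch topology of the original
block is not published wire-by-wire; this wiring uses exactly the named
ingredients (LSKAC, MaxPool2d, AvgPool2d, self-attention, Concat) and is a
documented choice of this package.

# CAFormer and CGLU (C3k2-CFCGLU)

CAFormer treats the learnable per-channel scale $\gamma$ of a group
normalization as an informativeness signal. With
$W_\gamma = \gamma / \sum_c \gamma_c$ and $r_c$ the spatial mean response
of channel $c$ of the normalized map, the gate weight is
$w_c = \sigma(W_{\gamma,c}\, r_c) \in (0,1)$. A threshold $t$ (default 0.5)
splits channels into informative weights $W_1 = w\,\mathbb{1}[w \ge t]$ and
non-informative $W_2 = w\,\mathbb{1}[w < t]$; the masks multiply the weight
value (soft gating) so the split stays differentiable. The depth-wise
separable sub-branch (a depth-wise $3\times3$ followed by a point-wise
$1\times1$; learned resampling offsets are not modelled) produces the map
weighted by $W_1$, the raw input is weighted by $W_2$, and the two weighted
maps are cross-reconstructed by contiguous channel halves
($X^W_1 = X_{11}{+}X_{22}$, $X^W_2 = X_{21}{+}X_{12}$, concatenated — the
final fusion is channel concatenation).

The CGLU mixer splits channels (after a $1\times1$ compression) into an
upper segment ($\alpha C$, default $\alpha=0.5$), a lower segment
($\beta C$, default $\beta=0.25$) and an identity bypass. The upper segment
runs a group-wise $3\times3$ ($g=2$) in parallel with a point-wise
$1\times1$, summed; the lower segment runs a depth-wise separable
$3\times3$ with a GELU. Both branch outputs are globally pooled, fused by
one linear layer into sigmoid channel scales, re-applied, concatenated with
the bypass and projected to the block width. $\alpha=\beta$ ranges are
constrained to $[0,1]$, $\alpha+\beta\le1$, and ratios that empty a segment
are configuration errors.

`C3k2-CFCGLU` swaps the first two bottleneck units of the cross-stage
block for CAFormer followed by CGLU; the split/concat paths are untouched.
At equal widths its parameter count is strictly below the plain block —
asserted structurally in the tests.

# CSCBAM (C3k2-CSCBAM)

Compression pools the map twice per attention kind: spatial max/average
pooling feeds a shared bottleneck MLP (reduction 16) whose two outputs are
added into one channel descriptor; channel-wise max/average maps are
stacked and fused by a $7\times7$ convolution into one spatial descriptor.
A per-position MLP on an $H\times W\times1$ map would degenerate to scalar
scaling, so the convolutional fusion (the CBAM convention) is used
deliberately. Interaction flattens the spatial descriptor, concatenates the
channel descriptor — a joint vector of length $HW + C$ — and passes it
through an MLP (hidden width $0.25\,(HW+C)$). Because a dense joint MLP
cannot be resolution-agnostic, the module pools the spatial descriptor to a
fixed $S\times S$ token grid before interaction and upsamples the returned
gate; the default is $S=8$. $S=20$ was rejected because the
$(S^2+C)$-square MLP would then *exceed* the bottleneck parameters it
replaces at neck widths around $C=128$, contradicting the block's purpose
of saving parameters. Separation splits the joint vector back, applies
sigmoids, and gates the input channel-first then spatially; all attention
weights therefore lie strictly in $(0,1)$ and the output magnitude never
exceeds the input elementwise.

`C3k2-CSCBAM` replaces every bottleneck unit with a CSCBAM gate and keeps
exactly one BN and one ReLU, inserted before the fusion convolution; the
block's own $1\times1$ convolutions run bare (bias, SiLU) so the inventory
constraint holds — the suite counts both the BN modules and the executed
ReLU calls. The descriptor MLPs use SiLU for the same reason.

# Assembly, small-object head, complexity accounting

The assembly follows the YOLO family: a five-stage backbone (stem convs and
four cross-stage blocks), SPPF at the end of the backbone, an FPN/PAN neck,
and detection heads at strides 8/16/32. Substitution flags mirror the
ablation table: `cfcglu` replaces the backbone blocks, `sppflkc` the SPPF,
`cscbam` the two upsampling (top-down) neck blocks, and `sdl` adds the
small-object branch: the backbone's high-resolution P2 tap (the /4 feature,
stage index 2 of the backbone as laid out above) is concatenated with an
SPPFLKC-gated context path upsampled from the P3 neck feature, refined by a
cross-stage block, and terminated by a detail-enhanced-convolution (DEConv)
head. DEConv sums a vanilla $3\times3$ kernel with four
difference-constrained kernels (central, angular, horizontal, vertical);
by linearity the five kernels collapse into one $3\times3$ at inference,
and the module executes in that re-parameterized form. The head runs at
stride 4 by default: a stride-2 grid at 640-px input (a true
$320\times320$ map) is prohibitively expensive and the published figure of
320 most plausibly refers to the deployment input resolution; `head_stride
= 2` remains available.

Each head cell predicts `(tx, ty, tw, th, obj, cls...)`, decoded as center
offsets $2\sigma - 0.5$ (so neighbouring cells can describe the same
object) and sizes $(2\sigma)^3$ strides (bounded, spanning up to 8 strides,
with no exponential blow-up).

**Complexity accounting.** Parameters are counted from the stored weight
arrays. FLOPs are measured by tracing an actual forward pass at the
requested input size: every convolution, linear layer and normalization
logs its multiply-accumulates as it executes. The two routes — stored
weights and executed trace — agree within 1% on every variant (the only
known divergence is the DEConv head, whose five stored branches execute as
one re-parameterized kernel).

**Scale calibration.** The reference description reports a baseline of
11.5 M parameters and 8.9 GFLOPs, which no off-the-shelf nano-width model
matches (official nano scales count about 2.6 M). The package therefore
treats the stage-width profile as a calibration parameter: widths
$(16,32,80,200,488)$ with two units per block reproduce *both* baseline
figures to better than 1% under the multiply-accumulate convention. This
calibration targets only the baseline row; the substituted variants then
land wherever the architecture puts them. Under this resolution all four
ablation directions hold (parameters fall when C3k2-CFCGLU or C3k2-CSCBAM
is enabled and rise with SPPFLKC or the small-object head), but the
magnitude of the published per-module savings (e.g. −3.77 M from the
backbone blocks alone) would require those blocks to hold the majority of
all parameters, which is incompatible with any YOLO-family layout whose
baseline simultaneously measures 8.9 GFLOPs; the package reports its own
measured counts rather than forcing them. An `official_n` scale
(16/32/64/128/256) and a `micro` desk scale ship alongside.

# Data pipeline

YOLO text labels (`class cx cy w h`, normalized) are read and written
losslessly to six decimals; records without label files carry empty
annotation lists and unreadable images become record-level error entries.
The stratified split shuffles deterministically under a seed, apportions
`floor(ratio * n)` validation and test quotas over the dominant-class
strata by largest remainder (every stratum within one image of its
proportional share) and sends all remainders to train; 4000 records at
0.7/0.2/0.1 give exactly 2800/800/400. Augmentation covers horizontal and
vertical flips (boxes transformed consistently; flips are involutions),
contrast about the image mean, and an edge-renormalized Gaussian blur that
preserves a constant image exactly. Preprocessing letterboxes to a square
input with gray padding (114/255) and divide-by-255 scaling only, and the
recorded transform maps boxes back to source coordinates within $10^{-6}$.

# Synthetic scenes: what they emulate and what they do not

The generator renders leaf-blade backgrounds (linear gradients plus
oriented blade streaks and Gaussian pixel noise) under three scenarios —
sunny (bright, higher contrast), cloudy (flat, dim) and dense planting
(more blades, clustered lesions with overlap forced at rate ≥ 0.5) — and
paints parametric lesions: Brown Spot as small near-round dark ellipses
with a pale halo, Rice Blast as L1-profile spindles with pale centers and
brown rims, Bacterial Blight as long wavy-edged stripes. Every lesion
yields one tight box; everything is bit-deterministic given the seed.
Dominant-class image counts follow the 4:3:3 ratio by largest remainder
(1600/1200/1200 at n = 4000), with minority-class lesions mixed in at a low
rate, mirroring field imagery where one disease dominates a view. A
rule-based classifier inverts the renderer from geometry and color alone at
≥ 95% accuracy, which is the package's operational statement that the
classes are visually separable. The scenes deliberately do *not* emulate
real paddy statistics: no perspective, no specular water background, no
plant architecture, no label noise. Tests passing on these scenes establish
that the pipeline and optimization behave correctly, not that the detector
reaches field accuracy.

# Training and the desk-scale sanity run

Training is plain SGD with momentum 0.937, weight decay 0.005, linear
decay from `lr0 = 0.01` to `lr0 * lrf` with a 3-epoch warmup (momentum 0.8
during warmup), batch 32 at 640 px for 300 epochs by default — the
reference protocol; an Adam variant is selectable. Gradients are clipped
to a global norm of 10: the class-balanced objectness term produces large
spikes on batches with few positive cells, and unclipped SGD at these tiny
batch sizes is visibly chaotic from one run to the next. The loss combines
balanced binary cross-entropy on objectness over every grid cell (positives
re-weighted to match the negative mass, targets blended 0.5 + 0.5·CIoU so
ranking tracks box quality), BCE on one-hot class logits of assigned
cells, and a complete-IoU (CIoU) box term. Assignment is anchor-free and
multi-scale: every head whose decode range covers a box (size between 0.75
and 8 strides) trains on it, at its center cell plus the two nearest
neighbour cells; duplicate detections across heads are merged by NMS. A
task-aligned assigner with distribution-focal box regression was
considered and rejected: at the desk scales this package targets, the
centre-cell assigner is simpler, fully testable, and sufficient, and the
reference description never states its loss.

The learning sanity check overfits 16 synthetic images at 320 px on the
smallest (`micro`) scale with every substitution enabled, within 200
optimizer steps, and asserts training-set mAP50. Problem sizes throughout
the test suite (96–320 px inputs, 4–16 images, the `micro` scale) were
chosen so the whole suite completes on one CPU core in well under half an
hour; they are desk-scale choices, not statements about the reference
training protocol.

# Evaluation

AP uses COCO-style 101-point interpolated precision–recall integration per
class and IoU threshold; mAP50 averages classes at IoU 0.5 and mAP50-95
additionally averages thresholds 0.50–0.95 in steps of 0.05 (hence
mAP50-95 ≤ mAP50 always). The matcher is greedy in confidence order with
one-to-one ground-truth claiming per class and image. The exhaustive
oracle in the tests rebuilds the PR curve from scratch at every distinct
confidence cutoff and agrees with the cumulative implementation to 1e-6;
whether the original evaluation used 101-point or all-point integration is
unknown, so the choice is documented here and quantified by that test. The
confusion matrix follows the common detector convention (IoU 0.45,
confidence 0.25, any-class matching, background row/column).

# Numerical choices and limitations

* Same-padding everywhere; even kernels pad asymmetrically
  (floor/ceil).
* Max-pool padding is $-\infty$; average pooling excludes padded cells;
  adaptive pooling uses floor-spaced bin edges.
* BN uses minibatch statistics with momentum 0.03 running averages;
  group-norm groups default to 4 (falling back to a divisor of C).
* Gate thresholds compare against soft sigmoid weights; ties
  ($w = t$) side with the informative branch.
* The engine is float64 and single-threaded apart from BLAS; determinism
  holds under a fixed seed and single-threaded BLAS.
* Known limitations: no mosaic/mixup augmentation (the reference protocol
  disables mosaic), no deformable sampling offsets in CAFormer, no
  multi-scale training, and the synthetic scenes' simplicity means
  detection metrics on them say nothing quantitative about field imagery.
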