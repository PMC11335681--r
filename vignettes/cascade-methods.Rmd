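---
title: "Cascaded coarse-to-fine tumor segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded coarse-to-fine tumor segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancseg)
```

## The problem

Pancreatic tumors on axial CT slices are small (often well under 2% of the
image), sit inside or against the pancreas, and differ from surrounding
tissue by only a slight intensity offset with indistinct boundaries. A
single-stage segmenter trained on whole slices spends almost all of its
capacity on background and is easily distracted by texture, producing both
false positives and missed tumors. `pancseg` implements a two-stage cascade
that mirrors how a radiologist works: first find the pancreas, then examine
a tight, re-weighted crop around it for the tumor.

## Stage 1: multi-scale dual-encoder U-Net

Stage 1 is a U-Net variant with two contraction branches. Writing
$C_{i,1}, C_{i,2}$ for the two branch states at block $i$, $p(\cdot)$ for
2×2 max pooling and $\oplus$ for channel concatenation:

$$C_{i+1,1} = p(\mathrm{conv}_{3\times3}(\mathrm{conv}_{3\times3}(C_{i,1})))$$
$$C_{i+1,2} = p(\mathrm{conv}_{3\times3}(\mathrm{conv}_{1\times1}(C_{i,2}))
 \oplus \mathrm{conv}_{3\times3}(\mathrm{conv}_{5\times5}(C_{i,2})))$$

so each block sees the image at 1×1, 3×3 and 5×5 kernel scales. The central
layer fuses three paths (1×1→3×3 on branch 1; 3×3→3×3 and 5×5→3×3 on branch
2) by concatenation. The decoder upsamples with stride-2 transposed
convolutions and has **two** skip connections per level — branch 1's
pre-pool features join after the upsample, branch 2's after the first
decoder convolution:

$$U_{i-1} = \mathrm{conv}_{3\times3}((\mathrm{conv}_{3\times3}(\mathrm{DeConv}(U_i)
 \oplus C_{i-1,1})) \oplus C_{i-1,2})$$

A 1×1 head plus logistic squashing yields the pancreas probability map.

**Channel plan.** The architecture does not pin down widths, so they are a
package decision, fully configuration-driven: a stem maps the image to
`base_channels` (default 32), each block doubles the width (pre-pool skip
widths $32\cdot2^l$), branch 2's concatenation is fused back to nominal
width by a trailing 1×1, and the central layer's three 512-wide paths fuse
to 1024. Tests and desk-scale runs use `base_channels = 8`. Every
convolution is followed by batch normalization and ReLU; the probability
head has neither.

**Normalization.** Training uses batch size 1 (as in the original recipe),
so batch normalization degenerates to per-slice, per-channel normalization
over the spatial extent. The package computes current-sample statistics in
both training and inference — deterministic, with no running averages. This
is a deliberate simplification; it means inference statistics adapt per
slice, which suits the single-slice batch regime.

## The salient-change coupling and the crop

The stage-1 probability map $P$ is binarized at 0.5, the minimal bounding
box of the nonzero pixels is enlarged by a margin of $K$ pixels (default:
20 px at 512 resolution, scaled proportionally at other sizes) and clamped
to the image; an empty binarization falls back to the full image so
inference never fails. Inside the crop, stage 2 receives

$$x_2 = \mathrm{resize}\big(\mathrm{crop}(I) \odot (\varepsilon +
(1-\varepsilon)\,\mathrm{crop}(P))\big),$$

a probability-reweighted intensity image. The $\varepsilon$ floor (default
0.5) keeps the whole crop visible even where stage 1 is unsure, and the
multiplication makes the coupling differentiable: gradients from the tumor
losses flow back into the pancreas network, which is the point of the
cascade being *jointly* optimized rather than trained as two frozen
stages. Images are resized bilinearly, mask targets by nearest neighbour;
the stage-2 input size defaults to 96×96 (48×48 in slim runs).

## Stage 2: localization and focusing

Stage 2 runs its own multi-scale U-Net over the crop and reduces the five
decoder features (finest to coarsest) to a common width with 1×1
convolutions.

**Non-local localization.** On the coarsest feature map $F$ (C×H×W,
N = H·W), channel attention computes a C×C map by row-wise softmax of
$FF^\top$ (no learned projections; queries, keys and values are the
reshaped features) and adds the attended result back through a learnable
scale $\gamma_c$ initialized at 1. Spatial attention then projects with
three 1×1 convolutions to $Q', K'$ (width $\max(1,\lfloor C/8\rfloor)$) and
$V'$ (width C), softmax-normalizes the N×N affinities so that each output
position's weights over source positions sum to 1, and adds back through
$\gamma_s$. The affinity orientation is chosen as the standard non-local
formulation and verified against a nested-loop oracle in the tests; the
softmax is max-stabilized (mathematically identical). A 7×7 convolution
(padding 3) produces the coarse tumor logits. With both scales at zero the
module is exactly its 7×7 head — a degeneracy the tests assert.

**Focusing modules.** Each of the four finer levels refines the prediction
from above. The upsampled higher-level logits are squashed to an attention
map $a$ (logistic squashing — the two-class softmax of a single-channel
map), splitting the level's features into foreground $F_c \odot a$ and
background $F_c \odot (1-a)$ parts that reconstruct $F_c$ exactly. Two
context-exploration blocks with disjoint parameters mine false-positive
interference from the foreground part and false-negative interference from
the background part. Each block has four chained branches (3×3 reduce,
$K_i\times K_i$ local, 3×3 dilated at rate $r_i$; $K = 1,3,5,7$,
$r = 1,2,4,8$, all with BN + ReLU); branch $i$'s output is *added* to
branch $i+1$'s reduced input (the chaining is stated but its form is not;
addition keeps widths fixed and is config-switchable to concatenation), so
receptive fields grow strictly (5, 11, 21, 37 pixels). The refinement is

$$F_{up} = U(\mathrm{CBR}(F_h)),\quad
F_r = \mathrm{BR}(F_{up} - \lambda F_{fpd}),\quad
F_r' = \mathrm{BR}(F_r + \gamma F_{fnd})$$

with $U$ bilinear upsampling, $\lambda, \gamma$ learnable scales
initialized at 1, and a 3×3 head on $F_r'$ giving the level's logits.
Subtraction suppresses ambiguous background (false positives); addition
restores missed foreground (false negatives).

## Losses

* Stage 1: soft Dice loss, $1 - (2\sum pg + \epsilon)/(\sum p + \sum g +
  \epsilon)$, $\epsilon = 10^{-6}$.
* Localization output: BCE + IoU loss.
* Focusing outputs: boundary-weighted BCE + IoU with pixel weights
  $w = 1 + \mu\,|\mathrm{boxmean}_{15}(g) - g|$, $\mu = 5$ — boundary and
  cavity pixels, where small-tumor errors live, are emphasized. The box
  filter divides by the full kernel area with zero padding (the framework
  convention).
* Deep supervision: $L_{seg2} = L_{pm} + \sum_{i=2}^{5} 2^{4-i}
  L_{fm}^i$, coarse levels weighted higher (the printed form of this
  weight is ambiguous; $2^{4-i}$ follows deep-supervision convention and
  is config-exposed).
* Inter-class shared boundary: for hard labels, $m_{isb}(i,j)$ is the
  shared boundary length between classes $i, j$ divided by class $i$'s
  perimeter. Boundaries are counted as 4-adjacent pixel-pair edges; the
  image border counts toward perimeter but no shared boundary, making row
  sums ≤ 1 and the worked 3×3 example exact. $L_{isb}$ is the mean squared
  difference between predicted and reference matrices. Because hardening
  is an argmax, this term is non-differentiable; it is evaluated on hard
  labels, contributes no gradient, and is added (weight $\beta$) to the
  reported total — a penalty that tracks boundary structure, exactly as
  specified, with a config flag to exclude it from reported totals.
* Total: $L = L_{seg1} + \alpha L_{seg2} + \beta L_{isb}$ with
  $\alpha = 0.9$, $\beta = 0.4$.

## Training schedule

Training runs in three steps with one persistent SGD optimizer (momentum
0.9, weight decay 1e-7, batch size 1; reference learning rate 1e-5):

| step | epochs | crop source | saliency coupling |
|------|--------|-------------|-------------------|
| S | 2 | ground-truth pancreas box | off (stages decoupled) |
| I | 4 | ground-truth pancreas box | on |
| J | 50 | stage-1 model output | on (matches test time) |

In step S the stage-2 losses send no gradient into stage 1 (asserted in
the tests); steps I and J couple the stages. The crop source in the final
step follows the stage-1 probability map, consistent with how the crop is
defined at test time.

## The phantom generator

The generator emulates the stated difficulties of the real task: a
pancreas ellipse (2–8% of the image) at mean intensity 0.5 on a textured
background (mean 0.35, smoothed-noise texture, sd 0.04), containing a
strictly nested tumor ellipse (0.2–2% of the image) at only
`tumor_contrast_delta` (default 0.05) above the pancreas mean, plus i.i.d.
noise (sd 0.03). Pixels belong to an ellipse iff their centre satisfies
the ellipse inequality, so masks are exact and reproducible; geometry that
cannot satisfy the area and nesting constraints is resampled with a
bounded retry budget. Cases have the pancreas on every slice and tumor on
a contiguous slice subrange, mirroring how only part of a real CT series
is tumor-positive.

What the phantom does *not* emulate: anatomical shape variability, CT
physics (beam hardening, HU calibration), organ neighbourhoods that mimic
tumor intensity, or inter-slice 3D continuity. Passing tests therefore
demonstrate that the implementation is faithful and trainable, not that
benchmark-level clinical accuracy transfers to real CT data.

## Numerical choices and problem sizes

* He-normal initialization; attention and interference scales start at 1.
* BCE probabilities are clamped to $[10^{-7}, 1-10^{-7}]$.
* Bilinear resizing uses half-pixel centres; max-pool ties route to the
  first maximal position (fixed order) for determinism.
* The argmax tie rule for hard labels is "lowest class index".
* All randomness (phantom geometry, initialization, epoch shuffling) flows
  from explicit integer seeds; a fixed seed reproduces runs bit-for-bit.
* Desk-scale runs in the tests and the acceptance script use base width 8,
  48×48 phantoms with a 48×48 stage-2 input (32×32 for schedule-contract
  checks), 2–4 training cases, and a learning rate of 1e-3; the
  end-to-end script lengthens the final joint step to 120 epochs because a
  handful of slices is revisited far fewer times per epoch than a full
  dataset. These sizes were chosen so the full schedule and a 200-epoch
  overfit run complete on a single CPU while still exercising every
  module. The methods themselves are size-agnostic; 512×512 inputs with
  the default widths use the same code paths.

## Known limitations

* The ISB term cannot influence gradients (argmax); it acts as a reported
  penalty, which is the behaviour the formulation implies.
* Stage-1 supervision is much weaker than the coupled stage-2 gradient at
  small batch counts; the S step mitigates this by decoupled warm-up, but
  at desk scale the pancreas Dice typically trails the tumor Dice.
* Per-slice normalization statistics (batch size 1) mean that activations
  are not comparable across slices in the way running-statistics batch
  norm would make them.
* The evaluation reports both slice-mean and pixel-pooled aggregations
  because a single headline metric can follow either convention; per-case
  means are also emitted so case-level claims can be audited.
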