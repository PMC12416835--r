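---
title: "Distance-map regression for whole-cell instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-map regression for whole-cell instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distseg)
```

## The problem and the model

Label-free microscopy of cells in culture produces images in which cell
boundaries are weak, ambiguous, and frequently shared between tightly
clumped cells. Direct per-pixel classification (cell / background, or
cell / border / background) merges touching cells along weak edges;
per-object approaches need prompts or detections that are impractical at
hundreds of cells per frame.

`distseg` instead poses instance segmentation as a *regression* problem.
For a ground-truth label mask, each cell pixel is assigned the Euclidean
distance to the nearest pixel outside its own cell (background *or* a
different cell, so touching cells produce a valley of low values along
their shared boundary), and each cell's distances are divided by that
cell's maximum:

$$ D(p) \;=\; \frac{d\!\left(p,\; \complement\,c(p)\right)}{\max_{q \in c(p)} d\!\left(q,\; \complement\,c(p)\right)} \in [0, 1], $$

with $D(p) = 0$ off cells. Every cell — whatever its size — rises to
exactly 1 somewhere in its interior and falls toward 0 at its boundary.
A backbone network is trained to predict $D$ from the image with a plain
L2 (mean squared) loss; instances are recovered from the predicted map
by a dual-threshold, marker-controlled watershed:

1. **fill mask** — pixels with $D > t_\mathrm{fill}$ (default 0.09)
   belong to some cell;
2. **markers** — 8-connected components of $D > t_\mathrm{peak}$
   (default 0.47), one component per cell center;
3. **flood** — a priority flood from the markers over elevation $-D$,
   restricted to the fill mask; fronts from different markers meet at
   the valley between touching cells.

Both thresholds use strict inequalities. The defaults are the globally
best pair reported for the method; both are exposed in
`postprocess_config()` and on the command line.

## Pipeline details

**Preprocessing.** Contrast-limited adaptive histogram equalization
(CLAHE: 8×8 tile grid, 256 bins, clip limit 2 — the de-facto defaults of
mainstream implementations, which the method does not override) removes
field-level illumination nonuniformity, followed by per-image
z-scoring. CLAHE runs on the whole image before tiling, since its
purpose here is field-level correction; z-scoring is per image rather
than with fixed dataset constants to stay backbone-agnostic.

**Tiled inference.** The backbone operates on 256×256 patches. Images
are reflect-padded by a 32-pixel margin and covered by windows every
`stride = 256 − 2·32 = 192` pixels: each window carries a disposable
32-pixel margin per side, so only its central core is stitched into the
result and window borders never touch the output ("areas partially in
frame" are always someone's core). The last window per axis is pulled
back flush with the padded canvas and core boundaries are truncated at
the neighbouring core, so the cores partition the canvas exactly; with
a translation-equivariant backbone, tiled inference is identical to
whole-image application. Hard core-cropping (rather than averaging of
overlaps) keeps output independent of window order and bit-reproducible.
The stated overlap could also be read as stride 224 with 32 pixels of
pairwise window overlap; the margin reading was chosen because it is the
one under which the margin actually shields partially-in-frame content,
and it reproduces the documented window counts (e.g. 4×3 windows on a
704×520 frame).

**Augmentation.** Per epoch, every training image contributes exactly
one augmented 256×256 crop: horizontal mirroring (p = 0.5), rotation
uniform in [−180°, 180°], rescaling in [0.8, 1.2], brightness in
[0.95, 1.05], and intensity inversion (p = 0.5; dark-field vs.
phase-contrast polarity). Geometric transforms are applied to image and
target alike in one bilinear pass (exact integer paths for axis-aligned
cases); the photometric transforms never touch the target. The
per-cell normalization makes the target scale-invariant up to
interpolation error, which is what justifies precomputing targets once
before training. Fill outside the frame is mirror continuation for the
image and 0 (the defined background value) for the target; the target
is re-clipped to [0, 1] after interpolation. The method does not fix an
operation order or the mirror/invert probabilities; this package uses
geometric → brightness → inversion → CLAHE → z-scoring and p = 0.5.

**Training protocol.** AdamW (β₁ = 0.9, β₂ = 0.999, decoupled weight
decay 0.1), initial learning rate 10⁻⁴, batch size 8, a 250-iteration
linear warm-up then linear decay to zero over the full scheduled
horizon (`max_epochs` × iterations/epoch, fixed up front; early
stopping only truncates it), early stopping on validation loss with
patience 7 and minimum improvement 10⁻⁴ inside a 35–100 epoch range,
keeping the lowest-validation-loss checkpoint. The protocol does not
specify the monitored split; this package holds out a seeded 10% of
images and monitors validation loss. Training is bitwise reproducible
from the seed on a fixed platform.

**Backbones.** Anything satisfying the contract — preprocessed 256×256
patch in, same-shaped map in [0, 1] out (sigmoid head) — plugs in via
`as_backbone()`. The bundled `reference_backbone()` is a ~55k-parameter
U-Net-style convolutional encoder–decoder (four pooling stages, widths
8/16/32/32, skip connections, leaky-ReLU activations, 1×1 sigmoid
head) that trains on a CPU in minutes; it exists so the whole pipeline
can be exercised and validated end-to-end at desk scale. Two numerical
choices matter at this scale: leaky rather than hard ReLU, and a
small-gain head initialized at a negative bias, both of which prevent
the early collapse to a constant predictor that the sparse (mostly
background) regression target otherwise induces. The SAM-scale
fine-tuning route (1024×1024 encoder input via bilinear patch
upsampling, frozen prompt encoder, trainable image encoder and mask
decoder) is described by `sam_adapter()` as an optional integration
point; it requires an external tensor runtime and weights and is not
needed by anything in the package.

## Evaluation

`seg_score()` is the Cell Tracking Challenge SEG measure: each
reference cell is matched to the predicted cell covering a strict
majority of its pixels (the majority rule makes matches unique) and
scores its Jaccard index, 0 if unmatched; SEG is the mean over
reference cells. `det_score()` is the detection measure DET
$= 1 - \min(\mathrm{AOGM_D}, \mathrm{AOGM_{D0}}) / \mathrm{AOGM_{D0}}$,
where AOGM-D counts the weighted node edits turning the predicted
detection graph into the reference graph — false negatives (weight 10),
false positives (weight 1), splits (weight 5, $k-1$ per prediction
claiming $k$ references). The weights are the Cell Tracking Challenge
canon (the method references the measure without restating them) and
are configurable arguments. `op_csb()` is the exact mean of the two.
Empty-versus-empty comparisons score 1 by convention so that perfect
agreement always scores 1. `culture_metrics()` reports the quantities a
culture workflow needs: cell count, mean area, confluency, and per-cell
neighbor counts (dilation adjacency with a 2-px disc; the neighbor
notion is otherwise undefined and the radius is an argument).

## Synthetic validation data

`synth_generate()` builds images with *exact* ground truth. Cells are
random ellipses (optionally perturbed by low-frequency radial noise for
irregular morphologies) placed by rejection sampling — at most 100
attempts per cell — with ≥ 2 px separation, except a configurable
fraction forced into 1-px contact with an existing cell to create the
touching-cell valleys the watershed must resolve. Foreground intensity
is the true distance field scaled onto a plateau (0.35 + 0.6·D over a
0.08 background), blurred, modulated by a linear illumination gradient,
polarity-flipped for dark-on-bright imaging, and corrupted by Gaussian
noise. Tying intensity to the distance field is deliberate: it gives a
desk-scale backbone a learnable signal so that end-to-end training
recovery is meaningful on a CPU. The `round_easy` profile (round cells,
10% clumping, crisp edges) mirrors an easy circular-cell culture; the
`clumped_hard` profile (irregular, 60% clumping, soft edges) mirrors a
dense weak-boundary culture.

What passing on synthetic data does *not* show: real phase-contrast
optics (halos, shade-off), annotation noise, heavy-tailed cell-size
distributions, or out-of-focus debris are not modeled, so synthetic
scores say nothing quantitative about performance on real cultures —
they validate the machinery (target construction, tiling, training
dynamics, watershed recovery, metrics), not the biology.

## Numerical choices and degenerate inputs

* Distance transform: exact Euclidean on pixel centers (a
  boundary-adjacent cell pixel has raw distance 1), computed per label
  on one-pixel-expanded bounding boxes — exact, because the nearest
  outside pixel of any cell pixel lies inside that crop. Cells touching
  the image border see only in-image pixels; a cell filling the entire
  image has no outside pixel and maps to 1 everywhere. Single-pixel and
  1-px-thin cells normalize to 1 rather than being dropped.
* Watershed tie-break: the flood queue orders by (−value, row, column,
  insertion index), so meeting fronts resolve deterministically.
  Marker components smaller than `min_peak_area` (default 16 px, well
  below any plausible cell) are discarded as speckle; there is no
  cell-size filter by default. Fill-mask pixels unreachable from any
  marker drop to background. Peanut-shaped (dividing) cells
  intentionally split into two — that is the method's documented
  behavior, not a defect to fix.
* A dividing-cell-free zoo of degenerate inputs is defined everywhere:
  constant images pass CLAHE unchanged and z-score to zero (flagged),
  empty masks produce empty maps and empty segmentations, and empty
  reference/prediction pairs score 1.
* The 32-bit label-mask writer exists because no installed image
  package writes 32-bit integer TIFF samples; reading goes through the
  standard TIFF reader.

## Desk-scale study sizes

The package's own validation runs at sizes chosen for a single CPU: the
distance-map oracle checks 200 random masks up to 32×32; the watershed
round trip uses 50 `round_easy` images of 20–40 cells; the end-to-end
recovery study trains the reference backbone on 40 synthetic images and
evaluates on 10 held out, with the warm-up shortened to 10 iterations
and the epoch range to about a dozen epochs (the 250-iteration warm-up
and 35-epoch minimum are calibrated to SAM-scale fine-tuning, not to a
55k-parameter network seeing 36 images per epoch), and the learning
rate raised to 10⁻³ — a 55k-parameter network trained from scratch
needs a larger step than a fine-tuned foundation model.

## Known limitations

* With *exact* ground-truth maps, the fill threshold 0.09 removes the
  outermost pixel rings of large cells (a ring at raw distance $k$
  survives only if $k > 0.09 \cdot d_{max}$), so round-trip IoU through
  `segment_distance_map(compute_distance_map(m))` degrades with cell
  size even though counts stay exact: the default thresholds are tuned
  for smooth *predicted* maps, not for the piecewise-exact target.
* The reference backbone is a validation instrument, not a
  state-of-the-art segmenter; no claim is made about its accuracy on
  real microscopy.
* Only 2-D, single-channel segmentation is covered; no tracking, no 3-D.
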