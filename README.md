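# distseg

Whole-cell instance segmentation for label-free microscopy by
**distance-map regression** and **marker-controlled watershed**, in R.

Biologists monitoring cells in culture need per-cell segmentations to
read off confluency, counts, morphology and neighborhood structure —
but label-free images have weak, ambiguous boundaries, and densely
clumped cells defeat per-pixel classifiers, which merge neighbors along
soft edges. `distseg` implements the regression alternative end to end:

1. **Target construction.** For a ground-truth label mask, every cell
   pixel gets the Euclidean distance to the nearest pixel outside its
   cell (background *or* another cell), normalized per cell so each
   cell peaks at exactly 1:
   `D(p) = d(p, ∁c(p)) / max_{q∈c(p)} d(q, ∁c(p))` — touching cells
   leave a valley of low values along their shared boundary.
2. **Regression.** A pluggable backbone (any function from a
   preprocessed 256×256 patch to a [0,1] map; a desk-scale ~55k-parameter
   convolutional encoder–decoder is bundled) is trained with L2 loss,
   AdamW, learning-rate warm-up + linear decay, and early stopping —
   one augmented patch per image per epoch.
3. **Inference.** CLAHE → per-image z-scoring → overlapped 256×256
   sliding windows (stride 192; only each window's core is kept) →
   per-patch prediction → deterministic stitching.
4. **Instance recovery.** Dual thresholds on the predicted map — fill
   0.09 for cell-vs-background support, peak 0.47 for one marker per
   cell — then a priority-flood watershed over `-D` with a
   deterministic tie-break: `DET`-style boundaries where floods meet.
5. **Evaluation.** Cell Tracking Challenge SEG (majority-matched mean
   Jaccard), DET (`1 − min(AOGM_D, AOGM_D0)/AOGM_D0` with weights
   10/1/5 for false negatives / false positives / splits), their mean
   OP_CSB, and culture metrics (count, mean area, confluency, neighbor
   counts).

A synthetic-data module generates microscopy-like images with exact
ground truth (round or irregular cells, controllable clumping, edge
softness, polarity, illumination gradients, noise) so the whole
pipeline is testable without external datasets.

## Worked example

```r
library(distseg)

# a synthetic culture with exact ground truth
g <- synth_generate(synth_config(n_cells = 30, seed = 5))

# ground-truth target, and recovery through the watershed
dm  <- compute_distance_map(g$mask)
rec <- segment_distance_map(dm, postprocess_config())
evaluate_masks(g$mask, rec)
#>         seg det    op_csb
#> 1 0.9193394   1 0.9596697

cm <- culture_metrics(rec)
str(cm[1:3])
#> List of 3
#>  $ cell_count    : int 30
#>  $ mean_cell_area: num 654
#>  $ confluency    : num 0.0749
```

All 30 cells are recovered (DET = 1). SEG is ~0.92 rather than 1.0
because the 0.09 fill threshold removes the outermost ring of large
cells on an *exact* distance map — the thresholds are calibrated for
smooth predicted maps (see the vignette's limitations section).

Training and applying the bundled reference backbone:

```r
suite <- lapply(1:12, function(i)
  synth_generate(synth_config(n_cells = 20, seed = i)))
fit <- distseg_fit(lapply(suite, `[[`, "image"),
                   lapply(suite, `[[`, "mask"),
                   config = train_config(lr_init = 1e-3, warmup_iters = 10,
                                         max_epochs = 8, min_epochs = 4,
                                         seed = 1))
print(fit)
pred <- predict(fit, suite[[1]]$image)          # instance label mask
plot(fit)                                       # loss curves
```

The command-line wrapper (installed at
`system.file("cli", "distseg", package = "distseg")`) exposes the same
pipeline as `distseg synth | train | segment | evaluate`.

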