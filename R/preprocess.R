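# CLAHE + z-normalization, overlapped sliding-window decomposition, and
# stitching of per-patch predictions into a full-image distance map.

#' Preprocessing / tiling configuration
#'
#' @param clahe_clip_limit CLAHE clip limit (multiples of the uniform
#'   histogram level; default 2).
#' @param clahe_grid Tiles per axis for CLAHE, length-2 integer (default
#'   8x8).
#' @param patch_size Sliding-window patch edge in pixels (default 256,
#'   the backbone's native resolution).
#' @param overlap_margin Disposable margin per patch side in pixels
#'   (default 32); the stitching stride is
#'   `patch_size - 2 * overlap_margin`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 2, clahe_grid = c(8L, 8L),
                              patch_size = 256L, overlap_margin = 32L) {
  clahe_grid <- rep(as.integer(clahe_grid), length.out = 2L)
  stopifnot(clahe_clip_limit > 0, all(clahe_grid >= 1L),
            patch_size > 2L * overlap_margin, overlap_margin >= 0L)
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_grid = clahe_grid,
                 patch_size = as.integer(patch_size),
                 overlap_margin = as.integer(overlap_margin)),
            class = "preprocess_config")
}

# Reflecting (mirror, no edge duplication) index lookup: maps any integer
# position onto 1..n with period 2n-2. Handles pads wider than the image.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

#' Reflect-pad a matrix
#'
#' Mirror padding without edge duplication (the border pixel is not
#' repeated), used for CLAHE grid alignment and sliding-window margins.
#'
#' @param x Numeric matrix.
#' @param top,left,bottom,right Non-negative pad widths.
#' @return The padded matrix.
#' @export
reflect_pad <- function(x, top = 0L, left = 0L, bottom = 0L, right = 0L) {
  ri <- reflect_index(seq.int(1L - top, nrow(x) + bottom), nrow(x))
  ci <- reflect_index(seq.int(1L - left, ncol(x) + right), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' Contrast-limited adaptive histogram equalization
#'
#' Min–max scales the image, partitions it into a tile grid, equalizes
#' each tile's 256-bin histogram with the clip limit (excess redistributed
#' uniformly) and blends the per-tile transfer functions bilinearly
#' between tile centers. The image is reflect-padded to a grid multiple
#' internally and cropped back. Output range is `[0, 255]`. A constant
#' image is returned unchanged (there is no contrast to equalize).
#'
#' @param img Numeric single-channel matrix.
#' @param clip_limit,grid See [preprocess_config()].
#' @return Numeric matrix in `[0, 255]` (same shape).
#' @export
clahe_equalize <- function(img, clip_limit = 2, grid = c(8L, 8L)) {
  stopifnot(is.matrix(img))
  grid <- rep(as.integer(grid), length.out = 2L)
  rng <- range(img)
  if (rng[2] == rng[1]) return(img + 0)  # constant: nothing to equalize
  x <- (img - rng[1]) / (rng[2] - rng[1])
  h <- nrow(x); w <- ncol(x)
  # EBImage requires each dimension divisible by its tile count (and at
  # least 2 px per tile)
  ph <- max(2L * grid[1], as.integer(ceiling(h / grid[1]) * grid[1]))
  pw <- max(2L * grid[2], as.integer(ceiling(w / grid[2]) * grid[2]))
  xp <- reflect_pad(x, bottom = ph - h, right = pw - w)
  eq <- EBImage::clahe(xp, nx = grid[1], ny = grid[2], bins = 256L,
                       limit = clip_limit, keep.range = FALSE)
  eq <- as.matrix(eq)[seq_len(h), seq_len(w), drop = FALSE]
  pmin(pmax(eq, 0), 1) * 255
}

#' Z-score normalization
#'
#' Scales an image to zero mean and unit standard deviation (population
#' SD, per image). A constant image has no scale and maps to all zeros.
#'
#' @param img Numeric matrix.
#' @return Numeric matrix with mean 0 and SD 1 (unless constant).
#' @export
znorm <- function(img) {
  stopifnot(is.matrix(img))
  mu <- mean(img)
  s <- sqrt(mean((img - mu)^2))
  if (s == 0) {
    message("znorm: constant image, returning zeros")
    return(img * 0)
  }
  (img - mu) / s
}

#' Plan the overlapped sliding-window tiling of an image
#'
#' Windows are `patch_size` squares anchored every
#' `stride = patch_size - 2 * overlap_margin` pixels over the image
#' reflect-padded by `overlap_margin` on every side (the padded canvas is
#' grown to at least one full window); the last window per axis is pulled
#' back flush with the padded border. Each window contributes only its
#' core region to the stitched result: nominally its central
#' `stride`-wide band, expanded to the window edge at the canvas border
#' and truncated at the neighbouring window's core, so the cores
#' partition the padded canvas exactly.
#'
#' @param height,width Image dimensions in pixels.
#' @param config A [preprocess_config()].
#' @return A list of class `patch_grid` with the padding spec, 0-based
#'   window anchors, and per-window core intervals (1-based, inclusive,
#'   in padded coordinates).
#' @export
plan_tiles <- function(height, width, config = preprocess_config()) {
  stopifnot(height >= 1L, width >= 1L)
  ps <- config$patch_size; ov <- config$overlap_margin
  stride <- ps - 2L * ov
  axis_plan <- function(n) {
    k <- as.integer(ceiling(n / stride))          # windows along this axis
    padded <- max(n + 2L * ov, ps)
    anchors <- pmin(stride * (seq_len(k) - 1L), padded - ps)  # 0-based
    # core boundaries: window i owns [bnd[i], bnd[i+1]) (0-based)
    bnd <- c(0L, if (k > 1L) anchors[-1L] + ov, padded)
    list(n = n, padded = padded, anchors = anchors,
         core_start = bnd[-length(bnd)], core_end = bnd[-1L])
  }
  rows <- axis_plan(as.integer(height))
  cols <- axis_plan(as.integer(width))
  structure(list(
    height = as.integer(height), width = as.integer(width),
    patch_size = ps, overlap_margin = ov, stride = stride,
    padded_height = rows$padded, padded_width = cols$padded,
    pad = c(top = ov, left = ov,
            bottom = rows$padded - height - ov,
            right = cols$padded - width - ov),
    row_anchors = rows$anchors, col_anchors = cols$anchors,
    row_core = cbind(start = rows$core_start, end = rows$core_end),
    col_core = cbind(start = cols$core_start, end = cols$core_end),
    n_windows = length(rows$anchors) * length(cols$anchors)
  ), class = "patch_grid")
}

# Pad an image according to a patch grid's pad spec.
pad_for_grid <- function(img, grid) {
  reflect_pad(img, top = grid$pad["top"], left = grid$pad["left"],
              bottom = grid$pad["bottom"], right = grid$pad["right"])
}

#' Extract the planned patches from an image
#'
#' @param img Numeric matrix matching the grid's image dimensions.
#' @param grid A [plan_tiles()] result.
#' @return List of `patch_size` x `patch_size` matrices in row-major
#'   window order (rows outer, columns inner).
#' @export
extract_patches <- function(img, grid) {
  if (nrow(img) != grid$height || ncol(img) != grid$width)
    stop("image shape does not match the planned grid")
  ps <- grid$patch_size
  padded <- pad_for_grid(img, grid)
  out <- vector("list", grid$n_windows)
  k <- 1L
  for (ar in grid$row_anchors) {
    for (ac in grid$col_anchors) {
      out[[k]] <- padded[(ar + 1L):(ar + ps), (ac + 1L):(ac + ps),
                         drop = FALSE]
      k <- k + 1L
    }
  }
  out
}

#' Stitch per-patch outputs into a full-image map
#'
#' Copies each window's core region onto the padded canvas (every canvas
#' pixel comes from exactly one window, so the result is independent of
#' window order) and crops the padding away.
#'
#' @param patch_outputs List of `patch_size` x `patch_size` matrices, one
#'   per window, in the order produced by [extract_patches()].
#' @param grid The [plan_tiles()] result the patches came from.
#' @return Numeric matrix of the original image shape.
#' @export
stitch <- function(patch_outputs, grid) {
  if (length(patch_outputs) != grid$n_windows)
    stop("expected ", grid$n_windows, " patch outputs, got ",
         length(patch_outputs))
  canvas <- matrix(NA_real_, grid$padded_height, grid$padded_width)
  k <- 1L
  for (i in seq_along(grid$row_anchors)) {
    ar <- grid$row_anchors[i]
    rs <- grid$row_core[i, 1L]; re <- grid$row_core[i, 2L]
    for (j in seq_along(grid$col_anchors)) {
      ac <- grid$col_anchors[j]
      cs <- grid$col_core[j, 1L]; ce <- grid$col_core[j, 2L]
      p <- patch_outputs[[k]]
      if (!is.matrix(p) || nrow(p) != grid$patch_size ||
          ncol(p) != grid$patch_size)
        stop("patch output ", k, " has the wrong shape")
      canvas[(rs + 1L):re, (cs + 1L):ce] <-
        p[(rs - ar + 1L):(re - ar), (cs - ac + 1L):(ce - ac), drop = FALSE]
      k <- k + 1L
    }
  }
  ov <- grid$overlap_margin
  canvas[(ov + 1L):(ov + grid$height), (ov + 1L):(ov + grid$width),
         drop = FALSE]
}

#' Bilinear resampling of a patch
#'
#' Bilinear interpolation with the half-pixel-center (corner-aligned-off)
#' convention, clamped at the borders. `upsample_patch` scales a patch up
#' by an integer factor (used by backbone adapters whose native input
#' exceeds the patch size); `downsample_pred` maps back down.
#'
#' @param patch Numeric matrix.
#' @param factor Integer scale factor (>= 1).
#' @return The resampled matrix.
#' @export
upsample_patch <- function(patch, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(patch)
  bilinear_resize(patch, nrow(patch) * factor, ncol(patch) * factor)
}

#' @rdname upsample_patch
#' @param out_height,out_width Target shape for `downsample_pred`.
#' @export
downsample_pred <- function(patch, out_height, out_width) {
  bilinear_resize(patch, out_height, out_width)
}

bilinear_resize <- function(x, oh, ow) {
  h <- nrow(x); w <- ncol(x)
  if (oh == h && ow == w) return(x)
  src <- function(o, n, on) pmin(pmax((seq_len(on) - 0.5) * n / on - 0.5, 0),
                                 n - 1)
  sr <- src(NULL, h, oh); sc <- src(NULL, w, ow)
  r0 <- pmin(floor(sr), h - 1); r1 <- pmin(r0 + 1, h - 1); fr <- sr - r0
  c0 <- pmin(floor(sc), w - 1); c1 <- pmin(c0 + 1, w - 1); fc <- sc - c0
  A <- x[r0 + 1, c0 + 1, drop = FALSE]; B <- x[r0 + 1, c1 + 1, drop = FALSE]
  C <- x[r1 + 1, c0 + 1, drop = FALSE]; D <- x[r1 + 1, c1 + 1, drop = FALSE]
  FR <- matrix(fr, oh, ow); FC <- matrix(fc, oh, ow, byrow = TRUE)
  A * (1 - FR) * (1 - FC) + B * (1 - FR) * FC +
    C * FR * (1 - FC) + D * FR * FC
}

#' Full-image tiled inference
#'
#' Runs the whole inference pipeline on one image: CLAHE, z-scoring,
#' overlapped tiling, per-patch backbone prediction, and core-region
#' stitching back to the image shape.
#'
#' @param img Numeric image matrix (native intensity scale).
#' @param predict_patch Function mapping a preprocessed `patch_size`
#'   square matrix to a same-shaped prediction in `[0, 1]`.
#' @param config A [preprocess_config()].
#' @return The stitched distance-map prediction (image-shaped, `[0, 1]`).
#' @export
infer_distance_map <- function(img, predict_patch,
                               config = preprocess_config()) {
  pre <- znorm(clahe_equalize(img, config$clahe_clip_limit,
                              config$clahe_grid))
  grid <- plan_tiles(nrow(img), ncol(img), config)
  patches <- extract_patches(pre, grid)
  stitch(lapply(patches, predict_patch), grid)
}
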