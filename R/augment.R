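# Training-time augmentation: mirroring, rotation, rescaling, brightness,
# inversion, and the random 256x256 training crop. Photometric transforms
# (brightness, inversion) never touch the distance-map target.

# Run fn under a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Sample an augmentation specification
#'
#' Draws one fully reproducible transform: mirror and inversion are
#' Bernoulli(0.5); rotation is uniform on `[-180, 180]` degrees; scale is
#' uniform on `[0.8, 1.2]`; brightness is uniform on `[0.95, 1.05]`; the
#' crop anchor is uniform over all valid positions for a
#' `patch_size` crop. The same seed always yields the same spec.
#'
#' @param seed Integer seed.
#' @param image_shape Length-2 integer (rows, cols); must admit a
#'   `patch_size` crop (pad the image first otherwise).
#' @param patch_size Training crop size (default 256).
#' @return A list of class `augment_spec`.
#' @export
sample_augment_spec <- function(seed, image_shape, patch_size = 256L) {
  if (any(image_shape < patch_size))
    stop("image smaller than the training crop; pad it first")
  with_seed(seed, function() {
    structure(list(
      mirror = runif(1) < 0.5,
      rotation_deg = runif(1, -180, 180),
      scale = runif(1, 0.8, 1.2),
      brightness = runif(1, 0.95, 1.05),
      invert = runif(1) < 0.5,
      crop_anchor = c(row = sample.int(image_shape[1] - patch_size + 1L, 1L),
                      col = sample.int(image_shape[2] - patch_size + 1L, 1L)),
      patch_size = as.integer(patch_size),
      seed = as.integer(seed)
    ), class = "augment_spec")
  })
}

#' Identity augmentation spec (crop only)
#' @param crop_anchor 1-based (row, col) of the crop.
#' @param patch_size Crop size.
#' @return An `augment_spec` that only crops.
#' @export
identity_spec <- function(crop_anchor = c(1L, 1L), patch_size = 256L) {
  structure(list(mirror = FALSE, rotation_deg = 0, scale = 1,
                 brightness = 1, invert = FALSE,
                 crop_anchor = c(row = crop_anchor[1], col = crop_anchor[2]),
                 patch_size = as.integer(patch_size), seed = NA_integer_),
            class = "augment_spec")
}

# Geometric resampling shared by image and target: horizontal mirror, then
# rotation about the image center, then isotropic rescaling, in one
# bilinear pass (inverse mapping). `fill` chooses how samples outside the
# source are produced: "reflect" continues the image by mirroring, "zero"
# uses the distance map's defined background value. Axis-aligned cases
# (rotation a multiple of 90 degrees at scale 1) take an exact integer
# path so e.g. a 90-degree rotation commutes bitwise with target
# construction.
warp_geometric <- function(x, mirror, rotation_deg, scale,
                           fill = c("reflect", "zero")) {
  fill <- match.arg(fill)
  h <- nrow(x); w <- ncol(x)
  if (mirror) x <- x[, rev(seq_len(w)), drop = FALSE]
  quarter <- rotation_deg / 90
  if (scale == 1 && abs(quarter - round(quarter)) < 1e-12) {
    k <- as.integer(round(quarter)) %% 4L
    # counter-clockwise quarter turns (square canvases in training)
    for (dummy in seq_len(k)) x <- t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
    return(x)
  }
  theta <- rotation_deg * pi / 180
  cs <- cos(theta); sn <- sin(theta)
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  oi <- matrix(seq_len(h) - 1, h, w) - cr
  oj <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - cc
  # inverse map: unscale, then rotate back
  ui <- oi / scale; uj <- oj / scale
  si <- cs * ui + sn * uj + cr
  sj <- -sn * ui + cs * uj + cc
  bilinear_sample(x, si, sj, fill)
}

bilinear_sample <- function(x, si, sj, fill) {
  h <- nrow(x); w <- ncol(x)
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  gather <- function(ii, jj) {
    if (fill == "reflect") {
      v <- x[cbind(as.vector(reflect_index(as.vector(ii) + 1, h)),
                   as.vector(reflect_index(as.vector(jj) + 1, w)))]
    } else {
      ok <- ii >= 0 & ii < h & jj >= 0 & jj < w
      v <- numeric(length(ii))
      v[ok] <- x[cbind(as.vector(ii[ok]) + 1, as.vector(jj[ok]) + 1)]
    }
    matrix(v, nrow(si), ncol(si))
  }
  A <- gather(i0, j0); B <- gather(i0, j0 + 1)
  C <- gather(i0 + 1, j0); D <- gather(i0 + 1, j0 + 1)
  A * (1 - fi) * (1 - fj) + B * (1 - fi) * fj +
    C * fi * (1 - fj) + D * fi * fj
}

#' Apply an augmentation spec to an image and its distance map
#'
#' The image receives mirror, rotation and rescaling (bilinear, reflect
#' continuation outside the frame), then multiplicative brightness, then
#' optional intensity inversion (`max(x) - x` on the pre-normalization
#' scale). The distance map receives the geometric transforms only
#' (bilinear, zero fill) and is re-clipped to `[0, 1]`. Both are then
#' cropped at the spec's anchor to `patch_size`.
#'
#' @param img Numeric image matrix.
#' @param dmap Numeric distance-map matrix of the same shape.
#' @param spec An [sample_augment_spec()] / [identity_spec()] result.
#' @return List with elements `image` and `dmap`, both
#'   `patch_size` x `patch_size`.
#' @export
apply_augment <- function(img, dmap, spec) {
  stopifnot(identical(dim(img), dim(dmap)))
  ps <- spec$patch_size
  a <- spec$crop_anchor
  if (a[1] < 1 || a[2] < 1 || a[1] + ps - 1 > nrow(img) ||
      a[2] + ps - 1 > ncol(img))
    stop("crop anchor outside bounds; pad the input first")
  gi <- warp_geometric(img, spec$mirror, spec$rotation_deg, spec$scale,
                       fill = "reflect")
  gd <- warp_geometric(dmap, spec$mirror, spec$rotation_deg, spec$scale,
                       fill = "zero")
  gd <- pmin(pmax(gd, 0), 1)
  gi <- gi * spec$brightness
  if (spec$invert) gi <- max(gi) - gi
  rows <- a[1]:(a[1] + ps - 1L); cols <- a[2]:(a[2] + ps - 1L)
  list(image = gi[rows, cols, drop = FALSE],
       dmap = gd[rows, cols, drop = FALSE])
}

#' One augmented training pair per image, per epoch
#'
#' Draws one fresh [sample_augment_spec()] for every image in the dataset
#' (seeded per image from `epoch_seed`, so the whole epoch stream is
#' reproducible) and returns the augmented pairs in shuffled order.
#' Images smaller than the crop are reflect-padded (their targets
#' zero-padded) first.
#'
#' @param dataset List of `list(image =, dmap =)` pairs.
#' @param epoch_seed Integer seed for this epoch.
#' @param patch_size Training crop size.
#' @return List of `list(image =, dmap =, index =)` in presentation
#'   order.
#' @export
epoch_sampler <- function(dataset, epoch_seed, patch_size = 256L) {
  if (length(dataset) == 0L) stop("empty dataset")
  n <- length(dataset)
  perm <- with_seed(epoch_seed, function() sample.int(n))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- perm[k]
    img <- dataset[[i]]$image; dm <- dataset[[i]]$dmap
    if (nrow(img) < patch_size || ncol(img) < patch_size) {
      pb <- max(0L, patch_size - nrow(img))
      pr <- max(0L, patch_size - ncol(img))
      img <- reflect_pad(img, bottom = pb, right = pr)
      dmp <- matrix(0, nrow(img), ncol(img))
      dmp[seq_len(nrow(dm)), seq_len(ncol(dm))] <- dm
      dm <- dmp
    }
    seed_i <- as.integer((as.numeric(epoch_seed) * 1009 + i) %% 2147483647)
    spec <- sample_augment_spec(seed_i, dim(img), patch_size)
    pair <- apply_augment(img, dm, spec)
    out[[k]] <- list(image = pair$image, dmap = pair$dmap, index = i)
  }
  out
}
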