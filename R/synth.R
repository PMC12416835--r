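# Synthetic microscopy-like images with exact ground-truth label masks.
# The generator emulates the structural features the method targets —
# clumped cells with weak edges, round vs. irregular morphologies, both
# intensity polarities, illumination gradients — while tying foreground
# intensity to the true distance field so that the regression target is
# learnable from the rendered image.

#' Synthetic image configuration
#'
#' @param image_size Length-2 (rows, cols), default 512 x 512.
#' @param n_cells Number of cells to place.
#' @param morphology `"round"` (ellipses) or `"irregular"` (ellipses
#'   perturbed by low-frequency radial noise).
#' @param radius_range Semi-axis range in pixels (default 8-24).
#' @param clump_fraction Fraction of cells forced to touch an existing
#'   cell (1-px contact, no overlap).
#' @param edge_softness Gaussian blur sigma (px) applied to the rendered
#'   intensities.
#' @param illumination_gradient Maximum relative amplitude of the linear
#'   illumination ramp.
#' @param polarity `"bright_on_dark"` or `"dark_on_bright"`.
#' @param noise_sigma Gaussian pixel noise SD (relative to unit range).
#' @param seed Integer; output is fully determined by it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_size = c(512L, 512L), n_cells = 30L,
                         morphology = c("round", "irregular"),
                         radius_range = c(8, 24), clump_fraction = 0.1,
                         edge_softness = 1, illumination_gradient = 0.2,
                         polarity = c("bright_on_dark", "dark_on_bright"),
                         noise_sigma = 0.02, seed = 1L) {
  structure(list(image_size = rep(as.integer(image_size), length.out = 2L),
                 n_cells = as.integer(n_cells),
                 morphology = match.arg(morphology),
                 radius_range = radius_range,
                 clump_fraction = clump_fraction,
                 edge_softness = edge_softness,
                 illumination_gradient = illumination_gradient,
                 polarity = match.arg(polarity),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

# Rasterize one cell shape: an ellipse (optionally radially perturbed) as
# a logical stamp plus its local extent.
rasterize_cell <- function(a, b, phi, irregular) {
  amps <- if (irregular) runif(3, 0, 0.22) else numeric(3)
  phases <- if (irregular) runif(3, 0, 2 * pi) else numeric(3)
  rmax <- ceiling(max(a, b) * (1 + sum(amps)) + 1)
  n <- 2L * rmax + 1L
  ii <- matrix(seq_len(n) - rmax - 1, n, n)
  jj <- t(ii)
  # rotate coordinates into the ellipse frame
  u <- cos(phi) * ii + sin(phi) * jj
  v <- -sin(phi) * ii + cos(phi) * jj
  rho <- sqrt((u / a)^2 + (v / b)^2)
  if (irregular) {
    theta <- atan2(v, u)
    mod <- 1 + amps[1] * cos(2 * theta + phases[1]) +
               amps[2] * cos(3 * theta + phases[2]) +
               amps[3] * cos(4 * theta + phases[3])
    rho <- rho / pmax(mod, 0.3)
  }
  stamp <- rho <= 1
  list(stamp = stamp, r = rmax)
}

# Candidate placement fits if the stamp overlaps no forbidden pixel.
stamp_fits <- function(stamp, r, center, forbidden) {
  h <- nrow(forbidden); w <- ncol(forbidden)
  r0 <- center[1] - r; c0 <- center[2] - r
  n <- nrow(stamp)
  if (r0 < 1 || c0 < 1 || r0 + n - 1 > h || c0 + n - 1 > w) return(FALSE)
  sub <- forbidden[r0:(r0 + n - 1), c0:(c0 + n - 1)]
  !any(sub & stamp)
}

place_stamp <- function(mask, stamp, r, center, label) {
  r0 <- center[1] - r; c0 <- center[2] - r
  n <- nrow(stamp)
  sub <- mask[r0:(r0 + n - 1), c0:(c0 + n - 1)]
  sub[stamp] <- label
  mask[r0:(r0 + n - 1), c0:(c0 + n - 1)] <- sub
  mask
}

#' Generate one synthetic image and its label mask
#'
#' Cells are placed sequentially with rejection sampling (at most 100
#' attempts per cell): non-clumped cells keep at least 2 px separation
#' from all previous cells; clumped cells are forced into 1-px contact
#' with an existing cell without overlapping it. The image renders each
#' cell as an intensity plateau shaded by the ground-truth distance
#' field, blurred by `edge_softness`, modulated by a linear illumination
#' gradient, and corrupted by Gaussian noise; `polarity` flips the
#' foreground/background intensities (never the mask).
#'
#' @param config A [synth_config()].
#' @return List with `image` (numeric matrix in `[0, 1]`), `mask`
#'   (integer label matrix), and `placed` (cells actually placed; fewer
#'   than requested sets attribute `warning` on the result).
#' @export
synth_generate <- function(config = synth_config()) {
  with_seed(config$seed, function() synth_generate_impl(config))
}

synth_generate_impl <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  mask <- matrix(0L, h, w)
  sep_brush <- EBImage::makeBrush(5L, shape = "disc")   # 2 px separation
  touch_brush <- EBImage::makeBrush(3L, shape = "box")  # 8-adjacency
  forbidden_sep <- matrix(FALSE, h, w)  # occupancy dilated for separation
  occupied <- matrix(FALSE, h, w)
  adjacency_ring <- matrix(FALSE, h, w) # occupied dilated by 1 (touch zone)
  placed <- 0L
  irregular <- config$morphology == "irregular"
  for (k in seq_len(config$n_cells)) {
    want_clump <- placed > 0L && runif(1) < config$clump_fraction
    done <- FALSE
    for (attempt in seq_len(100L)) {
      a <- runif(1, config$radius_range[1], config$radius_range[2])
      b <- runif(1, config$radius_range[1], config$radius_range[2])
      cell <- rasterize_cell(a, b, runif(1, 0, pi), irregular)
      if (!any(cell$stamp)) next
      r <- cell$r
      if (want_clump) {
        # aim near a random occupied pixel so contact is plausible
        anchor_px <- which(occupied)
        if (length(anchor_px) == 0L) break
        ap <- anchor_px[sample.int(length(anchor_px), 1L)]
        ar <- (ap - 1L) %% h + 1L; ac <- (ap - 1L) %/% h + 1L
        off <- round(runif(2, -(r + 2), r + 2))
        center <- c(ar + off[1], ac + off[2])
        if (!stamp_fits(cell$stamp, r, center, occupied)) next
        # must touch: some stamp pixel inside the 1-px ring of occupancy
        r0 <- center[1] - r; c0 <- center[2] - r
        ring <- adjacency_ring[r0:(r0 + nrow(cell$stamp) - 1),
                               c0:(c0 + nrow(cell$stamp) - 1)]
        if (!any(ring & cell$stamp)) next
      } else {
        center <- c(sample.int(h, 1L), sample.int(w, 1L))
        if (!stamp_fits(cell$stamp, r, center, forbidden_sep)) next
      }
      mask <- place_stamp(mask, cell$stamp, r, center, k)
      placed <- placed + 1L
      # update occupancy summaries incrementally around the new cell
      r0 <- max(1L, center[1] - r - 3L); r1 <- min(h, center[1] + r + 3L)
      c0 <- max(1L, center[2] - r - 3L); c1 <- min(w, center[2] + r + 3L)
      occ <- mask[r0:r1, c0:c1] > 0L
      occupied[r0:r1, c0:c1] <- occ
      # OR with the previous state: cells outside this window may already
      # project dilation into it
      forbidden_sep[r0:r1, c0:c1] <- forbidden_sep[r0:r1, c0:c1] |
        (EBImage::dilate(occ, sep_brush) > 0)
      adjacency_ring[r0:r1, c0:c1] <- adjacency_ring[r0:r1, c0:c1] |
        (EBImage::dilate(occ, touch_brush) > 0)
      done <- TRUE
      break
    }
    if (!done && !want_clump) next
  }
  # relabel to consecutive ids in placement order
  labs <- sort(unique(mask[mask > 0L]))
  remap <- integer(max(labs, 1L)); remap[labs] <- seq_along(labs)
  mask[mask > 0L] <- remap[mask[mask > 0L]]

  dmap <- compute_distance_map(mask)
  fg <- 0.35 + 0.6 * dmap        # plateau shaded by the distance field
  img <- ifelse(mask > 0L, fg, 0.08)
  if (config$edge_softness > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = config$edge_softness))
  if (config$polarity == "dark_on_bright") img <- 1 - img
  ramp <- matrix(seq(-0.5, 0.5, length.out = w), h, w, byrow = TRUE)
  img <- img * (1 + config$illumination_gradient * ramp)
  if (config$noise_sigma > 0)
    img <- img + rnorm(length(img), sd = config$noise_sigma)
  img <- pmin(pmax(img, 0), 1)
  out <- list(image = img, mask = mask, placed = length(labs))
  if (length(labs) < config$n_cells)
    attr(out, "warning") <- sprintf("placed %d of %d cells",
                                    length(labs), config$n_cells)
  out
}

synth_profiles <- list(
  round_easy = list(morphology = "round", clump_fraction = 0.1,
                    edge_softness = 0.8, noise_sigma = 0.02,
                    illumination_gradient = 0.15),
  clumped_hard = list(morphology = "irregular", clump_fraction = 0.6,
                      edge_softness = 2.0, noise_sigma = 0.04,
                      illumination_gradient = 0.25)
)

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` image/mask pairs plus a JSON manifest. The
#' `round_easy` profile has round cells, 10% clumping, and crisp edges
#' (circular, well-separated cultures); `clumped_hard` has irregular
#' cells, 60% clumping, and soft edges (dense, weak-boundary cultures).
#' Cell counts per image are drawn uniformly from `n_cells_range`.
#'
#' @param profile `"round_easy"` or `"clumped_hard"`.
#' @param n_images Number of images.
#' @param seed Integer master seed; datasets are byte-reproducible.
#' @param out_dir Output directory (created if needed).
#' @param n_cells_range Range of cells per image (default 20-40).
#' @param image_size Image shape (default 512 x 512).
#' @return Invisibly, the manifest as a list.
#' @export
synth_suite <- function(profile = c("round_easy", "clumped_hard"),
                        n_images, seed, out_dir,
                        n_cells_range = c(20L, 40L),
                        image_size = c(512L, 512L)) {
  profile <- match.arg(profile)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prof <- synth_profiles[[profile]]
  entries <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- as.integer((as.numeric(seed) * 48271 + i) %% 2147483647)
    ncell <- with_seed(si, function()
      sample(seq.int(n_cells_range[1], n_cells_range[2]), 1L))
    cfg <- do.call(synth_config, c(
      list(image_size = image_size, n_cells = ncell,
           seed = as.integer((si + 7L) %% 2147483647)), prof))
    gen <- synth_generate(cfg)
    img_file <- sprintf("img_%03d.tif", i)
    mask_file <- sprintf("mask_%03d.tif", i)
    save_image(gen$image, file.path(out_dir, img_file))
    save_labels(gen$mask, file.path(out_dir, mask_file))
    entries[[i]] <- list(image = img_file, mask = mask_file,
                         n_cells = gen$placed, seed = cfg$seed)
  }
  manifest <- list(profile = profile, n_images = n_images, seed = seed,
                   images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
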