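# Ground-truth regression target: per-cell normalized Euclidean distance maps.

#' Compute the per-cell normalized distance map of a label mask
#'
#' For every cell, each of its pixels gets the Euclidean distance (pixel
#' centers) to the nearest pixel *not* belonging to that cell — background
#' or a different label — so touching cells produce a valley between them.
#' Each cell's distances are then divided by that cell's maximum, making
#' the per-cell maximum exactly 1; background stays exactly 0. Distances
#' are computed per label (the transform of a cell touching the image
#' border only sees pixels inside the image), with the boundary-adjacent
#' convention that a cell pixel next to the outside has raw distance 1.
#'
#' @param mask Integer matrix; 0 = background, positive labels = cells.
#' @return Numeric matrix in `[0, 1]` of the same shape.
#' @export
compute_distance_map <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) == 0L) return(out)
  # pixel index lists per label, one pass
  pos <- which(mask > 0L)
  by_lab <- split(pos, mask[pos])
  for (lab in labs) {
    px <- by_lab[[as.character(lab)]]
    rows <- (px - 1L) %% h + 1L
    cols <- (px - 1L) %/% h + 1L
    r0 <- max(1L, min(rows) - 1L); r1 <- min(h, max(rows) + 1L)
    c0 <- max(1L, min(cols) - 1L); c1 <- min(w, max(cols) + 1L)
    # the nearest non-cell pixel of any cell pixel lies inside this crop
    # (clamping any outside candidate onto the one-pixel ring can only
    # shorten the distance), so the crop is exact
    crop <- mask[r0:r1, c0:c1, drop = FALSE] == lab
    d <- as.matrix(EBImage::distmap(crop, metric = "euclidean"))
    raw <- d[crop]
    mx <- max(raw)
    vals <- if (is.finite(mx)) raw / mx else rep(1, length(raw))
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[crop] <- vals
    out[r0:r1, c0:c1][crop] <- sub[crop]
  }
  out
}

# Content hash of a decoded label mask (dimensions + values).
mask_hash <- function(mask) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  writeBin(dim(mask), con)
  writeBin(as.integer(mask), con)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Precompute and cache distance-map targets
#'
#' Computes [compute_distance_map()] for a collection of masks once,
#' before training, caching each result to disk as a 32-bit float TIFF
#' keyed by the mask's content hash (a changed mask file therefore misses
#' the cache and is recomputed; corrupt cache entries are recomputed and
#' overwritten). A JSON manifest maps inputs to cache entries.
#'
#' @param masks Character vector of mask paths, or a list of integer
#'   matrices.
#' @param cache_dir Directory for cached targets (created if missing).
#' @return Named list of distance-map matrices (names follow the input
#'   paths or list names), with attribute `recomputed` giving the number
#'   of cache misses.
#' @export
precompute_targets <- function(masks, cache_dir) {
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  from_paths <- is.character(masks)
  nm <- if (from_paths) masks else
    (if (!is.null(names(masks))) names(masks) else
       paste0("mask", seq_along(masks)))
  manifest_path <- file.path(cache_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  out <- vector("list", length(masks))
  names(out) <- nm
  recomputed <- 0L
  for (i in seq_along(masks)) {
    m <- if (from_paths) load_labels(masks[[i]]) else masks[[i]]
    hash <- mask_hash(m)
    target_file <- file.path(cache_dir, paste0(hash, ".tif"))
    dm <- NULL
    if (file.exists(target_file)) {
      dm <- tryCatch({
        v <- tiff::readTIFF(target_file)
        if (!identical(dim(v), dim(m))) stop("shape mismatch")
        v
      }, error = function(e) NULL)
    }
    if (is.null(dm)) {
      dm <- compute_distance_map(m)
      write_tiff_float32(dm, target_file)
      dm <- tiff::readTIFF(target_file)  # hand back the cached precision
      recomputed <- recomputed + 1L
    }
    manifest[[nm[i]]] <- list(hash = hash, target = basename(target_file))
    out[[i]] <- dm
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  attr(out, "recomputed") <- recomputed
  out
}
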