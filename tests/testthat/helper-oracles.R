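# Independent oracles and fixture builders shared across the suite.

# Brute-force per-cell normalized distance map: O(N^2) nearest
# different-label search over pixel centers.
brute_distance_map <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (lab in setdiff(unique(as.vector(mask)), 0L)) {
    px <- which(mask == lab, arr.ind = TRUE)
    other <- which(mask != lab, arr.ind = TRUE)
    raw <- vapply(seq_len(nrow(px)), function(k) {
      if (nrow(other) == 0L) return(Inf)
      sqrt(min((other[, 1] - px[k, 1])^2 + (other[, 2] - px[k, 2])^2))
    }, numeric(1))
    mx <- max(raw)
    out[px] <- if (is.finite(mx)) raw / mx else 1
  }
  out
}

# Random label mask with a few rectangular cells (possibly touching).
random_rect_mask <- function(h, w, n_cells, seed) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  for (k in seq_len(n_cells)) {
    r0 <- sample.int(h, 1L); c0 <- sample.int(w, 1L)
    r1 <- min(h, r0 + sample.int(5, 1L)); c1 <- min(w, c0 + sample.int(5, 1L))
    patch <- m[r0:r1, c0:c1]
    patch[patch == 0L] <- k          # never overwrite existing cells
    m[r0:r1, c0:c1] <- patch
  }
  m
}

# Mask of well-separated axis-aligned squares (side, margin control).
squares_mask <- function(h, w, side, centers) {
  m <- matrix(0L, h, w)
  half <- side %/% 2L
  for (k in seq_len(nrow(centers))) {
    r <- centers[k, 1]; c <- centers[k, 2]
    m[(r - half):(r - half + side - 1L),
      (c - half):(c - half + side - 1L)] <- k
  }
  m
}

# Brute-force DET: minimum weighted edit cost over all subsets of
# predicted nodes kept/deleted. Deleting a predicted node costs w_fp and
# orphans its claimed references (w_fn each); a kept node claiming k
# references needs max(k - 1, 0) splits (w_split each) and, if it claims
# none, counts as a false positive.
brute_det <- function(reference, predicted, w_fn = 10, w_fp = 1,
                      w_split = 5) {
  refs <- setdiff(sort(unique(as.vector(reference))), 0L)
  preds <- setdiff(sort(unique(as.vector(predicted))), 0L)
  n_ref <- length(refs)
  if (n_ref == 0L) return(if (length(preds) == 0L) 1 else 0)
  claimed_by <- vapply(refs, function(r) {
    area <- sum(reference == r)
    hits <- vapply(preds, function(s)
      sum(reference == r & predicted == s) > 0.5 * area, logical(1))
    if (any(hits)) preds[which(hits)] else NA_integer_
  }, integer(1))
  best <- Inf
  n_pred <- length(preds)
  for (code in seq_len(2^n_pred) - 1L) {
    keep <- as.logical(bitwAnd(code, 2^(seq_len(n_pred) - 1L)))
    cost <- w_fp * sum(!keep)                       # deleted predictions
    claimed <- claimed_by %in% preds[keep]
    cost <- cost + w_fn * sum(!claimed)             # unclaimed references
    for (s in preds[keep]) {
      k <- sum(claimed_by == s, na.rm = TRUE)
      cost <- cost + if (k == 0L) w_fp else w_split * (k - 1L)
    }
    best <- min(best, cost)
  }
  d0 <- w_fn * n_ref
  1 - min(best, d0) / d0
}

# Deterministic dummy dataset for training-loop tests.
tiny_dataset <- function(n, seed = 1, size = 256L) {
  lapply(seq_len(n), function(i) {
    g <- synth_generate(synth_config(image_size = c(size, size),
                                     n_cells = 6L, radius_range = c(6, 12),
                                     seed = seed * 100 + i))
    list(image = g$image, mask = g$mask)
  })
}
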