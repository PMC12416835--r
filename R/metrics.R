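# Cell Tracking Challenge SEG and DET (AOGM-D) measures, OP_CSB, and
# culture metrics (count, area, confluency, neighbors).

# Joint overlap table between two label masks: one row per (ref, pred)
# label pair with a positive pixel overlap (pred 0 = uncovered).
overlap_table <- function(reference, predicted) {
  if (!identical(dim(reference), dim(predicted)))
    stop("masks must share shape")
  idx <- reference > 0L
  if (!any(idx))
    return(data.frame(ref = integer(), pred = integer(), n = integer()))
  tab <- table(ref = reference[idx], pred = predicted[idx])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  data.frame(ref = as.integer(df$ref), pred = as.integer(df$pred),
             n = as.integer(df$Freq))
}

#' Match reference cells to predicted cells
#'
#' A predicted cell S matches a reference cell R iff it covers a strict
#' majority of R's pixels (`|R ∩ S| > 0.5 |R|`); the majority rule makes
#' the match unique per reference cell.
#'
#' @param reference,predicted Integer label masks of the same shape.
#' @return Data frame with one row per reference cell: `ref_label`,
#'   `ref_area`, `matched_pred` (NA if unmatched), `overlap`.
#' @export
match_cells <- function(reference, predicted) {
  ov <- overlap_table(reference, predicted)
  ref_labels <- sort(unique(reference[reference > 0L]))
  areas <- vapply(ref_labels, function(l) sum(ov$n[ov$ref == l]), integer(1))
  matched <- rep(NA_integer_, length(ref_labels))
  overlap <- rep(0L, length(ref_labels))
  for (k in seq_along(ref_labels)) {
    rows <- ov[ov$ref == ref_labels[k] & ov$pred > 0L, ]
    hit <- rows[rows$n > 0.5 * areas[k], ]
    if (nrow(hit) == 1L) {
      matched[k] <- hit$pred
      overlap[k] <- hit$n
    }
  }
  data.frame(ref_label = ref_labels, ref_area = areas,
             matched_pred = matched, overlap = overlap)
}

#' SEG: mean Jaccard index over reference cells
#'
#' Each reference cell scores the Jaccard index `|R ∩ S| / |R ∪ S|` with
#' its majority-matched predicted cell, or 0 if unmatched; SEG is the
#' mean over all reference cells. With no reference cells the score is
#' vacuously 1 when the prediction is also empty, else 0.
#'
#' @param reference,predicted Integer label masks of the same shape.
#' @return SEG in `[0, 1]`.
#' @export
seg_score <- function(reference, predicted) {
  mt <- match_cells(reference, predicted)
  if (nrow(mt) == 0L)
    return(if (!any(predicted > 0L)) 1 else 0)
  pred_area <- tabulate(predicted[predicted > 0L],
                        nbins = max(predicted, 1L))
  js <- ifelse(is.na(mt$matched_pred), 0,
               mt$overlap / (mt$ref_area +
                             pred_area[pmax(mt$matched_pred, 1L)] -
                             mt$overlap))
  mean(js)
}

# Claims table for DET: reference cell r is claimed by predicted cell s
# iff s covers a strict majority of r. Returns per-pred claim counts and
# the set of unclaimed refs.
det_claims <- function(reference, predicted) {
  ov <- overlap_table(reference, predicted)
  ref_labels <- sort(unique(reference[reference > 0L]))
  pred_labels <- sort(unique(predicted[predicted > 0L]))
  areas <- vapply(ref_labels, function(l) sum(ov$n[ov$ref == l]), integer(1))
  claimed_by <- rep(NA_integer_, length(ref_labels))
  for (k in seq_along(ref_labels)) {
    rows <- ov[ov$ref == ref_labels[k] & ov$pred > 0L, ]
    hit <- rows[rows$n > 0.5 * areas[k], ]
    if (nrow(hit) == 1L) claimed_by[k] <- hit$pred
  }
  claims_per_pred <- vapply(pred_labels,
                            function(s) sum(claimed_by == s, na.rm = TRUE),
                            integer(1))
  list(ref_labels = ref_labels, pred_labels = pred_labels,
       claimed_by = claimed_by, claims_per_pred = claims_per_pred)
}

#' DET: normalized detection accuracy (AOGM-D)
#'
#' Builds the detection assignment with the majority-overlap rule and
#' counts the weighted node operations needed to edit the predicted
#' detection graph into the reference graph: false negatives (reference
#' cells claimed by no prediction, cost `w_fn`), false positives
#' (predictions claiming nothing, cost `w_fp`), and splits (a prediction
#' claiming k >= 2 reference cells needs k-1 splits, cost `w_split`
#' each). `DET = 1 - min(AOGM_D, AOGM_D0) / AOGM_D0`, where `AOGM_D0 =
#' w_fn * (number of reference cells)` is the cost of building the
#' reference graph from nothing. Weights default to the Cell Tracking
#' Challenge canon (10 / 1 / 5).
#'
#' @param reference,predicted Integer label masks of the same shape.
#' @param w_fn,w_fp,w_split Operation costs.
#' @return DET in `[0, 1]`.
#' @export
det_score <- function(reference, predicted, w_fn = 10, w_fp = 1,
                      w_split = 5) {
  cl <- det_claims(reference, predicted)
  n_ref <- length(cl$ref_labels)
  if (n_ref == 0L)
    return(if (length(cl$pred_labels) == 0L) 1 else 0)
  fn <- sum(is.na(cl$claimed_by))
  fp <- sum(cl$claims_per_pred == 0L)
  ns <- sum(pmax(cl$claims_per_pred - 1L, 0L))
  aogm_d <- w_fn * fn + w_fp * fp + w_split * ns
  aogm_d0 <- w_fn * n_ref
  1 - min(aogm_d, aogm_d0) / aogm_d0
}

#' OP_CSB: overall performance
#'
#' The exact arithmetic mean of the SEG and DET scores.
#'
#' @param seg,det Scores in `[0, 1]`.
#' @return `0.5 * (seg + det)`.
#' @export
op_csb <- function(seg, det) {
  stopifnot(seg >= 0, seg <= 1, det >= 0, det <= 1)
  0.5 * (seg + det)
}

#' Culture metrics from a label mask
#'
#' The quantities a cell-culture workflow reads off a segmentation: cell
#' count, mean cell area (pixels), confluency (cell pixels / total
#' pixels), and the number of neighbors per cell. Two cells are neighbors
#' when one intersects the other's dilation by a disc of radius
#' `dilation_px`.
#'
#' @param mask Integer label mask.
#' @param dilation_px Neighbor adjacency radius in pixels (default 2).
#' @return List with `cell_count`, `mean_cell_area`, `confluency`, and
#'   `neighbor_counts` (named integer vector, one entry per cell).
#' @export
culture_metrics <- function(mask, dilation_px = 2L) {
  stopifnot(is.matrix(mask))
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) == 0L)
    return(list(cell_count = 0L, mean_cell_area = 0, confluency = 0,
                neighbor_counts = integer(0)))
  h <- nrow(mask); w <- ncol(mask)
  areas <- vapply(labs, function(l) sum(mask == l), integer(1))
  brush <- EBImage::makeBrush(2L * dilation_px + 1L, shape = "disc")
  r <- dilation_px + 1L
  neigh <- vapply(labs, function(l) {
    px <- which(mask == l)
    rows <- (px - 1L) %% h + 1L; cols <- (px - 1L) %/% h + 1L
    r0 <- max(1L, min(rows) - r); r1 <- min(h, max(rows) + r)
    c0 <- max(1L, min(cols) - r); c1 <- min(w, max(cols) + r)
    crop <- mask[r0:r1, c0:c1, drop = FALSE]
    dil <- EBImage::dilate(crop == l, brush) > 0
    length(setdiff(unique(crop[dil]), c(0L, l)))
  }, integer(1))
  names(neigh) <- labs
  list(cell_count = length(labs),
       mean_cell_area = mean(areas),
       confluency = sum(areas) / (h * w),
       neighbor_counts = neigh)
}

#' Evaluate a predicted mask against a reference mask
#'
#' @param reference,predicted Integer label masks of the same shape.
#' @return One-row data frame with `seg`, `det`, `op_csb`.
#' @export
evaluate_masks <- function(reference, predicted) {
  s <- seg_score(reference, predicted)
  d <- det_score(reference, predicted)
  data.frame(seg = s, det = d, op_csb = op_csb(s, d))
}
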