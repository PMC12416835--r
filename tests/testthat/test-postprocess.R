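test_that("binarize uses a strict inequality", {
  dm <- matrix(c(0, 0.05, 0.5, 0.09), 2, 2)
  b <- binarize(dm, 0.09)
  expect_identical(as.vector(b), c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(binarize(matrix(0, 4, 4), 0.2)))
})

test_that("marker extraction finds one component per disk and filters size", {
  # two disjoint radius-6 disks: the > 0.47 region of the exact field is
  # one blob per disk
  m <- matrix(0L, 40, 40)
  for (ij in which(outer(1:40, 1:40, function(i, j)
    (i - 12)^2 + (j - 12)^2 <= 36))) m[ij] <- 1L
  for (ij in which(outer(1:40, 1:40, function(i, j)
    (i - 30)^2 + (j - 30)^2 <= 36))) m[ij] <- 2L
  dm <- compute_distance_map(m)
  markers <- extract_markers(dm)
  expect_equal(max(markers), 2L)
  expect_equal(max(extract_markers(matrix(0, 10, 10))), 0L)
  # a 4-px component above peak threshold dies to min_peak_area = 16
  small <- matrix(0, 20, 20); small[5:6, 5:6] <- 0.9
  expect_equal(max(extract_markers(small)), 0L)
  expect_equal(max(extract_markers(
    small, postprocess_config(min_peak_area = 1L))), 1L)
})

test_that("component labeling is 8-connected", {
  b <- matrix(FALSE, 4, 4); b[1, 1] <- TRUE; b[2, 2] <- TRUE; b[4, 4] <- TRUE
  lab <- label_components(b)
  expect_equal(lab[1, 1], lab[2, 2])  # diagonal neighbors join
  expect_false(lab[4, 4] == lab[1, 1])
  expect_equal(max(lab), 2L)
})

test_that("watershed recovers well-separated cells exactly", {
  m <- squares_mask(60, 60, 9L, rbind(c(15, 15), c(45, 40)))
  dm <- compute_distance_map(m)
  rec <- segment_distance_map(dm)
  expect_equal(max(rec), 2L)
  # same partition up to label names
  for (lab in 1:2) {
    rl <- unique(rec[m == lab])
    expect_length(rl, 1L)
    expect_setequal(which(rec == rl), which(m == lab))
  }
  # no markers -> empty mask
  expect_equal(max(watershed_segment(dm, matrix(0L, 60, 60),
                                     binarize(dm, 0.09))), 0L)
})

test_that("touching cells split along the valley between their peaks", {
  # two-peak 1D profile extended in 2D: valley at column 21
  w <- 41; h <- 21
  prof <- c(seq(0.1, 1, length.out = 20), 0.08, seq(1, 0.1, length.out = 20))
  dm <- matrix(prof, h, w, byrow = TRUE)
  markers <- extract_markers(dm, postprocess_config(min_peak_area = 4L))
  expect_equal(max(markers), 2L)
  seg <- watershed_segment(dm, markers, dm > 0.05)
  expect_equal(max(seg), 2L)
  left <- unique(seg[, 1:19]); right <- unique(seg[, 23:41])
  expect_length(setdiff(left, 0L), 1L)
  expect_length(setdiff(right, 0L), 1L)
  expect_false(setdiff(left, 0L) == setdiff(right, 0L))
})

test_that("segmentation is deterministic and respects the fill mask", {
  g <- synth_generate(synth_config(n_cells = 25L, seed = 12))
  dm <- compute_distance_map(g$mask)
  s1 <- segment_distance_map(dm)
  s2 <- segment_distance_map(dm)
  expect_identical(s1, s2)
  expect_true(all(s1[!binarize(dm, 0.09)] == 0L))
  # every output label contains exactly one marker component
  markers <- extract_markers(dm)
  for (lab in setdiff(unique(as.vector(s1)), 0L)) {
    mk <- unique(markers[s1 == lab])
    expect_length(setdiff(mk, 0L), 1L)
  }
})

test_that("raising the peak threshold never adds markers", {
  g <- synth_generate(synth_config(n_cells = 20L, seed = 13))
  dm <- compute_distance_map(g$mask)
  counts <- vapply(c(0.2, 0.35, 0.47, 0.6, 0.8), function(thr)
    max(extract_markers(dm, postprocess_config(cell_peak_threshold = thr))),
    integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("round trip recovers counts and high IoU for compact cells", {
  # convex cells with modest radii (max interior distance well above the
  # fill cutoff) and >= 2 px separation: recovery is near-exact
  ious <- c(); count_ok <- TRUE
  for (s in 1:6) {
    g <- synth_generate(synth_config(n_cells = 25L, radius_range = c(4, 10),
                                     clump_fraction = 0, seed = 400 + s))
    dm <- compute_distance_map(g$mask)
    rec <- segment_distance_map(dm)
    n_ref <- length(unique(g$mask[g$mask > 0]))
    if (length(unique(rec[rec > 0])) != n_ref) count_ok <- FALSE
    mt <- match_cells(g$mask, rec)
    pa <- tabulate(rec[rec > 0], nbins = max(rec, 1))
    ious <- c(ious, ifelse(is.na(mt$matched_pred), 0,
                           mt$overlap / (mt$ref_area +
                                         pa[pmax(mt$matched_pred, 1)] -
                                         mt$overlap)))
  }
  expect_true(count_ok)
  expect_gte(mean(ious), 0.95)
})
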