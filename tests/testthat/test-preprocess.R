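test_that("CLAHE keeps range, flattens gradients, passes constants through", {
  const <- matrix(5, 64, 64)
  out <- clahe_equalize(const)
  expect_true(all(out == out[1, 1]))  # spatially constant
  set.seed(1)
  texture <- matrix(runif(128 * 128, 0, 40), 128, 128)
  gradient <- matrix(seq(0, 200, length.out = 128), 128, 128, byrow = TRUE)
  img <- texture + gradient
  eq <- clahe_equalize(img)
  expect_true(all(eq >= 0 & eq <= 255))
  tile_means <- function(x) {
    sapply(split(seq_len(128), rep(1:8, each = 16)), function(cols)
      mean(x[, cols]))
  }
  expect_lt(diff(range(tile_means(eq))), diff(range(tile_means(img))))
})

test_that("znorm standardizes, is idempotent, zeroes constants", {
  x <- matrix(c(0, 2), 10, 10)
  z <- znorm(x)
  expect_equal(sort(unique(as.vector(z))), c(-1, 1))
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-6)
  expect_equal(znorm(z), z, tolerance = 1e-12)
  expect_message(zc <- znorm(matrix(3, 4, 4)), "constant")
  expect_true(all(zc == 0))
})

test_that("tile plans follow the stride/padding arithmetic", {
  g <- plan_tiles(256, 256)
  expect_equal(c(g$padded_height, g$padded_width), c(320L, 320L))
  expect_equal(g$n_windows, 4L)
  g <- plan_tiles(192, 192)
  expect_equal(c(g$padded_height, g$padded_width), c(256L, 256L))
  expect_equal(g$n_windows, 1L)
  # 704x520 frame: ceil(704/192) = 4 columns, ceil(520/192) = 3 rows
  g <- plan_tiles(520, 704)
  expect_equal(length(g$row_anchors), 3L)
  expect_equal(length(g$col_anchors), 4L)
  expect_equal(g$n_windows, 12L)
})

test_that("core regions partition the padded canvas for all sizes", {
  cfg <- preprocess_config()
  for (n in c(1:3, 63:65, 191:193, 255:257, 383:385, 500, 777, 1000)) {
    g <- plan_tiles(n, 1, cfg)
    covered <- integer(g$padded_height)
    for (i in seq_along(g$row_anchors)) {
      s <- g$row_core[i, 1]; e <- g$row_core[i, 2]
      expect_gte(s, g$row_anchors[i])
      expect_lte(e, g$row_anchors[i] + cfg$patch_size)
      covered[(s + 1):e] <- covered[(s + 1):e] + 1L
    }
    expect_true(all(covered == 1L))
  }
})

test_that("patch extraction and stitching invert each other", {
  set.seed(2)
  img <- matrix(runif(300 * 450), 300, 450)
  g <- plan_tiles(nrow(img), ncol(img))
  patches <- extract_patches(img, g)
  expect_length(patches, g$n_windows)
  expect_true(all(vapply(patches, function(p) all(dim(p) == 256L),
                         logical(1))))
  # adjacent patches agree on their shared strip
  p1 <- patches[[1]]; p2 <- patches[[2]]
  expect_identical(p1[, 193:256], p2[, 1:64])
  # identity per-patch function reproduces the image exactly
  expect_identical(stitch(patches, g), img)
  expect_error(stitch(patches[-1], g), "expected")
})

test_that("tiled inference equals whole-image application of a
           translation-equivariant backbone", {
  kern <- matrix(c(0, 1, 0, 1, 2, 1, 0, 1, 0) / 6, 3, 3)
  conv3 <- function(x) {
    h <- nrow(x); w <- ncol(x)
    xp <- rbind(0, cbind(0, x, 0), 0)
    out <- matrix(0, h, w)
    for (dr in -1:1) for (dc in -1:1)
      out <- out + kern[dr + 2, dc + 2] *
        xp[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    out
  }
  set.seed(3)
  sizes <- rbind(cbind(sample(100:700, 9), sample(100:700, 9)),
                 c(520, 704))
  for (k in seq_len(nrow(sizes))) {
    h <- sizes[k, 1]; w <- sizes[k, 2]
    img <- matrix(runif(h * w), h, w)
    g <- plan_tiles(h, w)
    tiled <- stitch(lapply(extract_patches(img, g), conv3), g)
    padded <- reflect_pad(img, g$pad["top"], g$pad["left"],
                          g$pad["bottom"], g$pad["right"])
    whole <- conv3(padded)[(g$pad["top"] + 1):(g$pad["top"] + h),
                           (g$pad["left"] + 1):(g$pad["left"] + w)]
    expect_lt(max(abs(tiled - whole)[2:(h - 1), 2:(w - 1)]), 1e-6)
  }
})

test_that("bilinear resampling is exact on constants and linear ramps", {
  p <- matrix(0.4, 20, 20)
  expect_identical(upsample_patch(p, 1), p)
  expect_true(all(abs(upsample_patch(p, 3) - 0.4) < 1e-12))
  ramp <- matrix(seq(0, 1, length.out = 64), 64, 64, byrow = TRUE)
  up <- upsample_patch(ramp, 2)
  # interior of the upsampled ramp is linear (border rows clamp)
  interior <- up[, 3:126]
  steps <- diff(interior[1, ])
  expect_lt(max(abs(steps - steps[1])), 1e-6)
  down <- downsample_pred(up, 64, 64)
  expect_lt(max(abs(down[, 2:63] - ramp[, 2:63])), 1e-6)
})
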