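test_that("augmentation specs are reproducible and within range", {
  s1 <- sample_augment_spec(42, c(512, 512))
  s2 <- sample_augment_spec(42, c(512, 512))
  expect_identical(s1, s2)
  set.seed(9)
  for (seed in sample.int(1e6, 200)) {
    s <- sample_augment_spec(seed, c(400, 300))
    expect_true(s$rotation_deg >= -180 && s$rotation_deg <= 180)
    expect_true(s$scale >= 0.8 && s$scale <= 1.2)
    expect_true(s$brightness >= 0.95 && s$brightness <= 1.05)
    expect_true(s$crop_anchor["row"] >= 1 && s$crop_anchor["row"] <= 145)
    expect_true(s$crop_anchor["col"] >= 1 && s$crop_anchor["col"] <= 45)
  }
})

test_that("mirror rate is near one half", {
  mirrors <- vapply(1:2000, function(seed)
    sample_augment_spec(seed, c(300, 300))$mirror, logical(1))
  expect_gt(mean(mirrors), 0.45)
  expect_lt(mean(mirrors), 0.55)
})

test_that("identity spec only crops; mirror is an involution", {
  g <- synth_generate(synth_config(image_size = c(300, 300), n_cells = 8L,
                                   seed = 5))
  dm <- compute_distance_map(g$mask)
  out <- apply_augment(g$image, dm, identity_spec(c(10L, 20L)))
  expect_identical(out$image, g$image[10:265, 20:275])
  expect_identical(out$dmap, dm[10:265, 20:275])
  m1 <- distseg:::warp_geometric(g$image, TRUE, 0, 1, "reflect")
  expect_identical(distseg:::warp_geometric(m1, TRUE, 0, 1, "reflect"),
                   g$image)
})

test_that("photometric transforms never touch the distance map", {
  g <- synth_generate(synth_config(image_size = c(300, 300), n_cells = 8L,
                                   seed = 6))
  dm <- compute_distance_map(g$mask)
  spec <- sample_augment_spec(17, dim(g$image))
  spec_inv <- spec; spec_inv$invert <- !spec$invert
  spec_inv$brightness <- spec$brightness * 1.03
  a <- apply_augment(g$image, dm, spec)
  b <- apply_augment(g$image, dm, spec_inv)
  expect_false(identical(a$image, b$image))
  expect_identical(a$dmap, b$dmap)  # bitwise
  expect_true(all(a$dmap >= 0 & a$dmap <= 1))
})

test_that("exact 90-degree rotation commutes with target construction", {
  rot90 <- function(x) t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
  m <- random_rect_mask(300, 300, 12, seed = 31)
  dm <- compute_distance_map(m)
  spec <- identity_spec(c(15L, 23L)); spec$rotation_deg <- 90
  out <- apply_augment(matrix(0, 300, 300), dm, spec)
  dm_rot <- compute_distance_map(rot90(m))
  expect_identical(out$dmap, dm_rot[15:270, 23:278])
})

test_that("augmented maps stay approximately valid on random specs", {
  g <- synth_generate(synth_config(image_size = c(400, 400), n_cells = 10L,
                                   seed = 8))
  dm <- compute_distance_map(g$mask)
  for (seed in 1:10) {
    spec <- sample_augment_spec(seed, dim(dm))
    out <- apply_augment(g$image, dm, spec)
    expect_lte(max(out$dmap), 1 + 1e-6)
    # far-background pixels stay near zero despite bilinear blur
    far_bg <- distseg:::warp_geometric(
      compute_distance_map(g$mask) == 0, spec$mirror, spec$rotation_deg,
      spec$scale, "zero")
    far_bg <- far_bg[spec$crop_anchor[1]:(spec$crop_anchor[1] + 255),
                     spec$crop_anchor[2]:(spec$crop_anchor[2] + 255)]
    expect_lt(max(out$dmap[far_bg == 1]), 0.05)
  }
})

test_that("epoch sampler yields one pair per image, reproducibly", {
  ds <- tiny_dataset(7, seed = 3, size = 300L)
  ds <- lapply(ds, function(d)
    list(image = d$image, dmap = compute_distance_map(d$mask)))
  e1 <- epoch_sampler(ds, 1001)
  e2 <- epoch_sampler(ds, 1001)
  expect_length(e1, 7L)
  expect_identical(e1, e2)
  expect_setequal(vapply(e1, `[[`, integer(1), "index"), 1:7)
  # different epochs give different crops at least once over 5 epochs
  anchors_differ <- FALSE
  for (e in 2:5) {
    ee <- epoch_sampler(ds, 1000 + e)
    if (!identical(lapply(ee, `[[`, "image"), lapply(e1, `[[`, "image")))
      anchors_differ <- TRUE
  }
  expect_true(anchors_differ)
})

test_that("geometric warp samples the correct source locations", {
  # a linear ramp is reproduced exactly by bilinear sampling, so the
  # warped value at each pixel must equal the ramp at the inverse-mapped
  # coordinate (away from the reflected border)
  h <- 101; w <- 101
  ramp <- outer(seq_len(h) - 1, seq_len(w) - 1, function(i, j) 2 * i + 3 * j)
  theta <- 35 * pi / 180; s <- 1.1
  out <- distseg:::warp_geometric(ramp, FALSE, 35, s, "reflect")
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  for (pt in list(c(51, 51), c(40, 60), c(60, 45))) {
    oi <- pt[1] - 1 - cr; oj <- pt[2] - 1 - cc
    si <- (cos(theta) * oi + sin(theta) * oj) / s + cr
    sj <- (-sin(theta) * oi + cos(theta) * oj) / s + cc
    expect_equal(out[pt[1], pt[2]], 2 * si + 3 * sj, tolerance = 1e-9)
  }
})
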