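test_that("L2 loss matches closed forms", {
  a <- matrix(runif(64), 8, 8)
  expect_equal(l2_loss(a, a), 0)
  expect_equal(l2_loss(matrix(0, 4, 4), matrix(1, 4, 4)), 1)
  expect_equal(l2_loss(matrix(0.5, 4, 4), matrix(0, 4, 4)), 0.25)
  expect_error(l2_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("learning-rate schedule warms up and decays linearly", {
  cfg <- train_config()
  total <- 1000L
  expect_equal(lr_at(249, total, cfg), 1e-4)          # end of warm-up
  expect_equal(lr_at(0, total, cfg), 1e-4 / 250)      # first step of ramp
  mid <- 250 + (total - 250) / 2
  expect_equal(lr_at(mid, total, cfg), 5e-5)          # decay midpoint
  expect_equal(lr_at(total - 1, total, cfg), 1e-4 / (total - 250))
  # continuity at the joint and global peak at warm-up end
  lrs <- vapply(0:(total - 1), lr_at, numeric(1), total, cfg)
  expect_lt(abs(lrs[251] - lrs[250]), 1e-4 / (total - 250) + 1e-12)
  expect_equal(which.max(lrs), 250L)                  # iteration 249
  expect_true(all(lrs >= 0))
  expect_error(lr_at(0, 250, cfg), "degenerate")
})

test_that("reference backbone honors the output contract", {
  bb <- reference_backbone(3)
  x <- matrix(rnorm(256 * 256), 256, 256)
  y <- predict_patch(bb, x)
  expect_equal(dim(y), c(256L, 256L))
  expect_true(all(y >= 0 & y <= 1))
  expect_lte(distseg:::n_parameters(bb$params), 1e6)
  # initialization is seed-reproducible
  expect_identical(reference_backbone(3)$params, bb$params)
})

test_that("network gradients agree with finite differences", {
  bb <- reference_backbone(7)
  x <- matrix(rnorm(32 * 32), 32, 32)
  tg <- matrix(runif(32 * 32), 32, 32)
  fw <- distseg:::net_forward(bb$params, x, keep = TRUE)
  gr <- distseg:::net_backward(bb$params, fw$cache, fw$y, tg)
  loss_of <- function(p) l2_loss(distseg:::net_forward(p, x)$y, tg)
  set.seed(3)
  for (li in c(1, 4, 6, 10)) {
    for (rep in 1:3) {
      i <- sample(length(bb$params[[li]]$W), 1)
      p2 <- bb$params
      p2[[li]]$W[i] <- p2[[li]]$W[i] + 1e-6
      numeric_grad <- (loss_of(p2) - loss_of(bb$params)) / 1e-6
      expect_equal(gr[[li]]$W[i], numeric_grad, tolerance = 1e-3)
    }
  }
})

test_that("training runs are reproducible and losses behave", {
  ds <- tiny_dataset(8, seed = 5)
  imgs <- lapply(ds, `[[`, "image"); masks <- lapply(ds, `[[`, "mask")
  cfg <- train_config(lr_init = 1e-3, warmup_iters = 1L, max_epochs = 3L,
                      min_epochs = 1L, batch_size = 4L, seed = 21L)
  f1 <- distseg_fit(imgs, masks, config = cfg)
  f2 <- distseg_fit(imgs, masks, config = cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  expect_identical(coef(f1), coef(f2))
  expect_equal(f1$history$best_val_loss, min(f1$history$val_loss))
  expect_length(f1$history$train_loss, 3L)
})

test_that("early stopping follows the patience / min-epochs rule", {
  ds <- tiny_dataset(6, seed = 6)
  imgs <- lapply(ds, `[[`, "image"); masks <- lapply(ds, `[[`, "mask")
  # constant-output stub backbone: validation loss frozen across epochs
  stub <- as_backbone(function(p) matrix(0.5, nrow(p), ncol(p)), "stub")
  cfg <- train_config(max_epochs = 30L, min_epochs = 2L,
                      patience_epochs = 7L, seed = 8L)
  fit <- distseg_fit(imgs, masks, backbone = stub, config = cfg)
  # first epoch improves from Inf; then patience runs out
  expect_equal(fit$history$stopped_at, 1L + 7L)
  expect_true(all(abs(diff(fit$history$val_loss)) <= 1e-12))
  # min_epochs dominates when it exceeds the patience window
  cfg2 <- train_config(max_epochs = 30L, min_epochs = 12L,
                       patience_epochs = 7L, seed = 8L)
  fit2 <- distseg_fit(imgs, masks, backbone = stub, config = cfg2)
  expect_equal(fit2$history$stopped_at, 12L)
  # strictly improving validation loss never stops early
  expect_error(distseg_fit(list(), list()), "empty")
})

test_that("model object methods expose the fit", {
  ds <- tiny_dataset(6, seed = 9)
  cfg <- train_config(lr_init = 1e-3, warmup_iters = 1L, max_epochs = 2L,
                      min_epochs = 1L, batch_size = 4L, seed = 4L)
  fit <- distseg_fit(lapply(ds, `[[`, "image"), lapply(ds, `[[`, "mask"),
                     config = cfg)
  expect_s3_class(fit, "distseg_model")
  expect_output(print(fit), "backbone")
  sm <- summary(fit)
  expect_output(print(sm), "val L2")
  expect_equal(length(coef(fit)), distseg:::n_parameters(fit$backbone$params))
  pred <- predict(fit, ds[[1]]$image, type = "distance")
  expect_equal(dim(pred), dim(ds[[1]]$image))
  expect_true(all(pred >= 0 & pred <= 1))
  lab <- predict(fit, ds[[1]]$image)
  expect_true(is.integer(lab))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("sam adapter reports its optional dependency clearly", {
  expect_error(sam_adapter("/nonexistent/sam.pth"), "optional")
})
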