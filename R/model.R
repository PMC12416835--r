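# Backbone contract, desk-scale reference backbone (small convolutional
# encoder-decoder with sigmoid head), L2 loss, warm-up + linear-decay
# learning-rate schedule, AdamW, early stopping, and the training loop.

#' Training configuration
#'
#' Defaults follow the method's training protocol: AdamW with initial
#' learning rate 1e-4, weight decay 0.1, betas (0.9, 0.999), batch size
#' 8, a 250-iteration linear warm-up followed by linear decay to zero
#' over the full scheduled horizon, early stopping on validation loss
#' with patience 7 epochs and minimum improvement 1e-4, within a 35-100
#' epoch range.
#'
#' @param batch_size,lr_init,weight_decay,beta1,beta2 Optimizer settings.
#' @param warmup_iters Warm-up length in iterations (batches).
#' @param max_epochs,min_epochs Epoch range.
#' @param patience_epochs,min_delta Early-stopping rule.
#' @param seed Master seed; the whole run is reproducible from it.
#' @param val_fraction Fraction of images held out for validation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, lr_init = 1e-4,
                         weight_decay = 0.1, beta1 = 0.9, beta2 = 0.999,
                         warmup_iters = 250L, max_epochs = 100L,
                         min_epochs = 35L, patience_epochs = 7L,
                         min_delta = 1e-4, seed = 1L,
                         val_fraction = 0.1) {
  stopifnot(batch_size >= 1, lr_init > 0, weight_decay >= 0,
            warmup_iters >= 1, max_epochs >= 1, min_epochs >= 1,
            min_epochs <= max_epochs, patience_epochs >= 1,
            min_delta >= 0, val_fraction > 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 warmup_iters = as.integer(warmup_iters),
                 max_epochs = as.integer(max_epochs),
                 min_epochs = as.integer(min_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 min_delta = min_delta, seed = as.integer(seed),
                 val_fraction = val_fraction),
            class = "train_config")
}

#' Mean squared (L2) pixel loss
#'
#' @param pred,target Numeric matrices of the same shape.
#' @return Mean of squared pixel differences.
#' @export
l2_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  mean((pred - target)^2)
}

#' Learning rate at a given iteration
#'
#' Linear warm-up over the first `warmup_iters` iterations (reaching
#' `lr_init` exactly at the last warm-up iteration), then linear decay to
#' zero over the remaining scheduled horizon; continuous at the joint.
#'
#' @param iteration 0-based iteration index.
#' @param total_iterations Scheduled horizon (fixed up front).
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
lr_at <- function(iteration, total_iterations, config = train_config()) {
  wu <- config$warmup_iters
  if (total_iterations <= wu)
    stop("degenerate schedule: total_iterations (", total_iterations,
         ") must exceed warmup_iters (", wu, ")")
  stopifnot(iteration >= 0, iteration < total_iterations)
  ifelse(iteration < wu,
         config$lr_init * (iteration + 1) / wu,
         config$lr_init * (total_iterations - iteration) /
           (total_iterations - wu))
}

# ---------------------------------------------------------------------------
# Backbone contract

#' Wrap a prediction function as a backbone
#'
#' Anything mapping a preprocessed `256 x 256` patch to a same-shaped map
#' in `[0, 1]` satisfies the backbone contract. Function-wrapped
#' backbones have no trainable parameters (useful as oracles and
#' stubs); the trainable reference backbone is [reference_backbone()].
#'
#' @param predict Function: numeric matrix patch -> numeric matrix map.
#' @param name Descriptive name.
#' @return An object of class `distseg_backbone`.
#' @export
as_backbone <- function(predict, name = "custom") {
  structure(list(type = "function", predict = predict, name = name),
            class = c("distseg_fn_backbone", "distseg_backbone"))
}

#' Predict one patch with a backbone
#' @param backbone A `distseg_backbone`.
#' @param patch Preprocessed square numeric matrix.
#' @return Same-shaped prediction in `[0, 1]`.
#' @export
predict_patch <- function(backbone, patch) UseMethod("predict_patch")

#' @export
predict_patch.distseg_fn_backbone <- function(backbone, patch) {
  backbone$predict(patch)
}

#' @export
predict_patch.distseg_reference_backbone <- function(backbone, patch) {
  net_forward(backbone$params, patch, keep = FALSE)$y
}

#' Desk-scale convolutional reference backbone
#'
#' A small U-Net-style encoder-decoder: four 2x-downsampling stages
#' (3x3 conv + ReLU + average pooling, widths 8/16/32/32), a 32-channel
#' bottleneck, four nearest-upsampling decoder stages with skip
#' concatenation, and a 1x1 sigmoid head — about 55k parameters,
#' operating natively at 256 x 256 and trainable on a CPU in minutes. It
#' stands in for heavyweight encoders during development and testing;
#' any other predictor can be plugged in through [as_backbone()].
#'
#' @param seed Seed for the (He-normal) weight initialization.
#' @return An object of class `distseg_reference_backbone`.
#' @export
reference_backbone <- function(seed = 1L) {
  widths <- list(
    c(1, 8, 3), c(8, 16, 3), c(16, 32, 3), c(32, 32, 3),   # encoder
    c(32, 32, 3),                                          # bottleneck
    c(64, 32, 3), c(64, 16, 3), c(32, 8, 3), c(16, 8, 3),  # decoder
    c(8, 1, 1))                                            # head
  params <- with_seed(seed, function() {
    lapply(widths, function(wd) {
      cin <- wd[1]; cout <- wd[2]; k <- wd[3]
      fan_in <- cin * k * k
      list(W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                      cout, fan_in),
           b = rep(0, cout), k = k)
    })
  })
  # small-gain head biased toward the sparse regression target: starts
  # the sigmoid near the background value instead of 0.5, avoiding the
  # early saturation that otherwise freezes the net at a constant
  params[[10]]$W <- params[[10]]$W * 0.05
  params[[10]]$b <- rep(-2.5, length(params[[10]]$b))
  structure(list(type = "reference", params = params, seed = seed),
            class = c("distseg_reference_backbone", "distseg_backbone"))
}

n_parameters <- function(params) {
  sum(vapply(params, function(p) length(p$W) + length(p$b), numeric(1)))
}

as_cube <- function(m) array(m, c(nrow(m), ncol(m), 1L))
# leaky ReLU (slope 0.1): keeps gradient alive in the sparse-foreground
# regime where plain ReLU units die early
relu <- function(x) { neg <- x < 0; x[neg] <- 0.1 * x[neg]; x }
cat_c <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# Forward pass; with keep = TRUE all intermediates needed for the
# backward pass are retained.
net_forward <- function(params, patch, keep = FALSE) {
  cv <- function(i, x) .conv2d_fwd(x, params[[i]]$W, params[[i]]$b,
                                   params[[i]]$k)
  x0 <- as_cube(patch)
  a1 <- cv(1, x0);  e1 <- relu(a1); p1 <- .avgpool2_fwd(e1)
  a2 <- cv(2, p1);  e2 <- relu(a2); p2 <- .avgpool2_fwd(e2)
  a3 <- cv(3, p2);  e3 <- relu(a3); p3 <- .avgpool2_fwd(e3)
  a4 <- cv(4, p3);  e4 <- relu(a4); p4 <- .avgpool2_fwd(e4)
  a5 <- cv(5, p4);  bn <- relu(a5)
  u4 <- .upsample2_fwd(bn); c4 <- cat_c(u4, e4)
  a6 <- cv(6, c4);  d4 <- relu(a6)
  u3 <- .upsample2_fwd(d4); c3 <- cat_c(u3, e3)
  a7 <- cv(7, c3);  d3 <- relu(a7)
  u2 <- .upsample2_fwd(d3); c2 <- cat_c(u2, e2)
  a8 <- cv(8, c2);  d2 <- relu(a8)
  u1 <- .upsample2_fwd(d2); c1 <- cat_c(u1, e1)
  a9 <- cv(9, c1);  d1 <- relu(a9)
  z <- cv(10, d1)
  y <- 1 / (1 + exp(-z[, , 1]))
  if (!keep) return(list(y = y))
  list(y = y, cache = list(x0 = x0, a1 = a1, p1 = p1, a2 = a2, p2 = p2,
                           a3 = a3, p3 = p3, a4 = a4, p4 = p4, a5 = a5,
                           c4 = c4, a6 = a6, c3 = c3, a7 = a7, c2 = c2,
                           a8 = a8, c1 = c1, a9 = a9))
}

# Backward pass for the reference net; returns per-layer gradients.
net_backward <- function(params, cache, y, target) {
  ch <- cache
  n <- length(y)
  gy <- 2 * (y - target) / n          # d(mean sq err)/d y
  gz <- gy * y * (1 - y)              # through the sigmoid
  grads <- vector("list", length(params))
  bwd <- function(i, x_in, gout) {
    r <- .conv2d_bwd(x_in, params[[i]]$W, gout, params[[i]]$k)
    grads[[i]] <<- list(W = r$gW, b = r$gb)
    r$gx
  }
  drelu <- function(a, g) { neg <- a <= 0; g[neg] <- 0.1 * g[neg]; g }
  split_c <- function(g, n_first) {
    list(first = g[, , seq_len(n_first), drop = FALSE],
         second = g[, , -seq_len(n_first), drop = FALSE])
  }
  g <- bwd(10, relu(ch$a9), as_cube(gz))
  g <- drelu(ch$a9, g)
  g <- bwd(9, ch$c1, g)
  s <- split_c(g, dim(ch$c1)[3] - dim(ch$a1)[3])  # u1 | e1
  ge1_skip <- s$second
  g <- .upsample2_bwd(s$first)
  g <- drelu(ch$a8, g)
  g <- bwd(8, ch$c2, g)
  s <- split_c(g, dim(ch$c2)[3] - dim(ch$a2)[3])
  ge2_skip <- s$second
  g <- .upsample2_bwd(s$first)
  g <- drelu(ch$a7, g)
  g <- bwd(7, ch$c3, g)
  s <- split_c(g, dim(ch$c3)[3] - dim(ch$a3)[3])
  ge3_skip <- s$second
  g <- .upsample2_bwd(s$first)
  g <- drelu(ch$a6, g)
  g <- bwd(6, ch$c4, g)
  s <- split_c(g, dim(ch$c4)[3] - dim(ch$a4)[3])
  ge4_skip <- s$second
  g <- .upsample2_bwd(s$first)
  g <- drelu(ch$a5, g)
  g <- bwd(5, ch$p4, g)
  g <- .avgpool2_bwd(g) + ge4_skip
  g <- drelu(ch$a4, g)
  g <- bwd(4, ch$p3, g)
  g <- .avgpool2_bwd(g) + ge3_skip
  g <- drelu(ch$a3, g)
  g <- bwd(3, ch$p2, g)
  g <- .avgpool2_bwd(g) + ge2_skip
  g <- drelu(ch$a2, g)
  g <- bwd(2, ch$p1, g)
  g <- .avgpool2_bwd(g) + ge1_skip
  g <- drelu(ch$a1, g)
  bwd(1, ch$x0, g)
  grads
}

# One AdamW step (decoupled weight decay; biases are not decayed).
adamw_step <- function(params, grads, state, lr, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- 1e-8
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    for (slot in c("W", "b")) {
      g <- grads[[i]][[slot]]
      state$m[[i]][[slot]] <- b1 * state$m[[i]][[slot]] + (1 - b1) * g
      state$v[[i]][[slot]] <- b2 * state$v[[i]][[slot]] + (1 - b2) * g^2
      mhat <- state$m[[i]][[slot]] / bc1
      vhat <- state$v[[i]][[slot]] / bc2
      upd <- mhat / (sqrt(vhat) + eps)
      if (slot == "W") upd <- upd + cfg$weight_decay * params[[i]][[slot]]
      params[[i]][[slot]] <- params[[i]][[slot]] - lr * upd
    }
  }
  list(params = params, state = state)
}

adamw_init <- function(params) {
  zeros <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  list(m = zeros, v = rapply(zeros, function(x) x, how = "replace"), t = 0L)
}

# Shared train/val patch preprocessing: CLAHE then z-scoring.
preprocess_patch <- function(patch, pre) {
  suppressMessages(
    znorm(clahe_equalize(patch, pre$clahe_clip_limit, pre$clahe_grid)))
}

# ---------------------------------------------------------------------------
# Training

#' Fit the distance-map regressor
#'
#' Trains a backbone to regress per-cell normalized distance maps from
#' preprocessed image patches, following the method's protocol: one
#' augmented 256x256 patch per training image per epoch, L2 loss, AdamW
#' with warm-up + linear-decay learning rate (the decay horizon is fixed
#' up front at `max_epochs`; early stopping merely truncates it), and
#' early stopping on validation loss. The best-validation checkpoint is
#' retained. Fully reproducible from `config$seed`.
#'
#' @param images List of image matrices (native intensity scale), or a
#'   character vector of image paths.
#' @param masks List of integer label masks (or paths), parallel to
#'   `images`. Ignored when `targets` is given.
#' @param targets Optional list of precomputed distance maps (e.g. from
#'   [precompute_targets()]).
#' @param backbone A trainable backbone ([reference_backbone()]) or any
#'   [as_backbone()] object (monitored but not updated). Default: a
#'   fresh reference backbone seeded from `config$seed`.
#' @param config A [train_config()].
#' @param preprocess A [preprocess_config()].
#' @param postprocess A [postprocess_config()] stored on the model for
#'   [predict.distseg_model()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `distseg_model` with the trained backbone,
#'   training history, and configurations.
#' @export
distseg_fit <- function(images, masks = NULL, targets = NULL,
                        backbone = NULL, config = train_config(),
                        preprocess = preprocess_config(),
                        postprocess = postprocess_config(),
                        verbose = FALSE) {
  if (is.character(images)) images <- lapply(images, load_image)
  if (length(images) == 0L) stop("empty dataset")
  if (is.null(targets)) {
    if (is.null(masks)) stop("either masks or targets must be supplied")
    if (is.character(masks)) masks <- lapply(masks, load_labels)
    targets <- lapply(masks, compute_distance_map)
  }
  stopifnot(length(targets) == length(images))
  n <- length(images)
  if (is.null(backbone)) backbone <- reference_backbone(config$seed)
  trainable <- inherits(backbone, "distseg_reference_backbone")

  idx <- with_seed(config$seed, function() sample.int(n))
  n_val <- max(1L, round(config$val_fraction * n))
  if (n_val >= n) stop("dataset too small for a validation split")
  val_idx <- idx[seq_len(n_val)]
  train_idx <- idx[-seq_len(n_val)]
  ds <- lapply(train_idx, function(i)
    list(image = images[[i]], dmap = targets[[i]]))

  ps <- preprocess$patch_size
  iters_per_epoch <- ceiling(length(ds) / config$batch_size)
  total_iters <- config$max_epochs * iters_per_epoch
  if (trainable && total_iters <= config$warmup_iters)
    stop("degenerate schedule: max_epochs x iterations/epoch (",
         total_iters, ") must exceed warmup_iters (", config$warmup_iters,
         "); lower warmup_iters or raise max_epochs")

  # deterministic validation patches: preprocessed center crops
  center_crop <- function(m) {
    if (nrow(m) < ps || ncol(m) < ps) {
      pb <- max(0L, ps - nrow(m)); pr <- max(0L, ps - ncol(m))
      mm <- reflect_pad(m, bottom = pb, right = pr)
      m <- mm
    }
    r0 <- (nrow(m) - ps) %/% 2L; c0 <- (ncol(m) - ps) %/% 2L
    m[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps), drop = FALSE]
  }
  val_pairs <- lapply(val_idx, function(i) {
    list(x = preprocess_patch(center_crop(images[[i]]), preprocess),
         t = center_crop(targets[[i]]))
  })

  val_loss_of <- function(params_or_backbone) {
    mean(vapply(val_pairs, function(p) {
      y <- if (trainable) net_forward(params_or_backbone, p$x)$y
           else predict_patch(backbone, p$x)
      l2_loss(y, p$t)
    }, numeric(1)))
  }

  params <- if (trainable) backbone$params else NULL
  opt <- if (trainable) adamw_init(params) else NULL
  hist <- list(train_loss = numeric(0), val_loss = numeric(0),
               lr = numeric(0))
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L; it <- 0L; stopped_at <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    eseed <- as.integer((as.numeric(config$seed) * 7919 + epoch) %%
                          2147483647)
    pairs <- epoch_sampler(ds, eseed, ps)
    ep_losses <- numeric(0)
    for (b0 in seq(1L, length(pairs), by = config$batch_size)) {
      batch <- pairs[b0:min(b0 + config$batch_size - 1L, length(pairs))]
      lr <- if (trainable) lr_at(it, total_iters, config) else 0
      gsum <- NULL
      bloss <- 0
      for (p in batch) {
        x <- preprocess_patch(p$image, preprocess)
        if (trainable) {
          fw <- net_forward(params, x, keep = TRUE)
          bloss <- bloss + l2_loss(fw$y, p$dmap)
          g <- net_backward(params, fw$cache, fw$y, p$dmap)
          gsum <- if (is.null(gsum)) g else
            mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   gsum, g, SIMPLIFY = FALSE)
        } else {
          bloss <- bloss + l2_loss(predict_patch(backbone, x), p$dmap)
        }
      }
      bloss <- bloss / length(batch)
      if (!is.finite(bloss))
        stop("non-finite training loss at epoch ", epoch,
             " (iteration ", it, "); aborting")
      ep_losses <- c(ep_losses, bloss)
      if (trainable) {
        gavg <- lapply(gsum, function(g)
          list(W = g$W / length(batch), b = g$b / length(batch)))
        st <- adamw_step(params, gavg, opt, lr, config)
        params <- st$params; opt <- st$state
      }
      hist$lr <- c(hist$lr, lr)
      it <- it + 1L
    }
    vl <- val_loss_of(params)
    hist$train_loss <- c(hist$train_loss, mean(ep_losses))
    hist$val_loss <- c(hist$val_loss, vl)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      mean(ep_losses), vl))
    if (best_val - vl > config$min_delta) {
      best_val <- vl; best_params <- params; best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= config$patience_epochs && epoch >= config$min_epochs) {
      stopped_at <- epoch
      break
    }
    stopped_at <- epoch
  }

  if (trainable) backbone$params <- best_params
  structure(list(
    backbone = backbone,
    history = list(train_loss = hist$train_loss, val_loss = hist$val_loss,
                   lr = hist$lr, best_epoch = best_epoch,
                   best_val_loss = best_val, stopped_at = stopped_at,
                   total_iterations = total_iters),
    config = config, preprocess = preprocess, postprocess = postprocess,
    n_train = length(train_idx), n_val = n_val,
    val_indices = val_idx
  ), class = "distseg_model")
}

#' SAM-style backbone adapter
#'
#' The method was designed around a promptless, fine-tuned
#' encoder/decoder of the Segment Anything family: patches are bilinearly
#' upsampled 256 -> 1024, embedded by the image encoder, decoded with the
#' frozen default prompt embedding, and squashed through a sigmoid head
#' at the native 256 x 256 output. Loading such weights requires a tensor
#' framework that this package deliberately does not depend on, so this
#' adapter is an optional integration point: it validates the weight
#' location and stops with an informative error rather than failing
#' somewhere deeper.
#'
#' @param weights_path Path to SAM-compatible weights.
#' @return Never returns; always signals the optional-dependency error.
#' @export
sam_adapter <- function(weights_path) {
  stop("sam_adapter is an optional feature requiring an external tensor ",
       "runtime and SAM-compatible weights; install and wrap them via ",
       "as_backbone() (patch -> upsample_patch(., 4) -> encoder/decoder ",
       "with the frozen default prompt -> sigmoid -> 256x256 map). ",
       if (!is.null(weights_path) && !file.exists(weights_path))
         paste0("(weights not found at ", weights_path, ")") else "")
}

# ---------------------------------------------------------------------------
# S3 methods for the fitted model

#' @export
print.distseg_model <- function(x, ...) {
  cat("Distance-map regression segmenter (distseg_model)\n")
  cat(sprintf("  backbone: %s (%s parameters)\n",
              class(x$backbone)[1],
              if (!is.null(x$backbone$params))
                format(n_parameters(x$backbone$params), big.mark = ",")
              else "no trainable"))
  cat(sprintf("  trained:  %d epochs (best epoch %d, val L2 %.6f)\n",
              x$history$stopped_at, x$history$best_epoch,
              x$history$best_val_loss))
  cat(sprintf("  data:     %d train / %d validation images\n",
              x$n_train, x$n_val))
  invisible(x)
}

#' @export
summary.distseg_model <- function(object, ...) {
  h <- object$history
  out <- list(
    epochs = h$stopped_at, best_epoch = h$best_epoch,
    best_val_loss = h$best_val_loss,
    final_train_loss = tail(h$train_loss, 1L),
    n_parameters = if (!is.null(object$backbone$params))
      n_parameters(object$backbone$params) else 0L,
    peak_threshold = object$postprocess$cell_peak_threshold,
    fill_threshold = object$postprocess$cell_fill_threshold)
  class(out) <- "summary.distseg_model"
  out
}

#' @export
print.summary.distseg_model <- function(x, ...) {
  cat("distseg_model summary\n")
  cat(sprintf("  epochs run        %d (best %d)\n", x$epochs, x$best_epoch))
  cat(sprintf("  best val L2 loss  %.6f\n", x$best_val_loss))
  cat(sprintf("  final train loss  %.6f\n", x$final_train_loss))
  cat(sprintf("  parameters        %d\n", x$n_parameters))
  cat(sprintf("  thresholds        peak %.2f / fill %.2f\n",
              x$peak_threshold, x$fill_threshold))
  invisible(x)
}

#' @export
coef.distseg_model <- function(object, ...) {
  if (is.null(object$backbone$params)) return(numeric(0))
  unlist(lapply(object$backbone$params, function(p) c(p$W, p$b)))
}

#' Segment new images with a fitted model
#'
#' Runs the full inference pipeline per image (CLAHE, z-scoring, tiled
#' backbone prediction, stitching, and — for `type = "labels"` — the
#' dual-threshold watershed).
#'
#' @param object A `distseg_model`.
#' @param images A matrix, a list of matrices, or a character vector of
#'   image paths.
#' @param type `"labels"` for instance masks, `"distance"` for the raw
#'   stitched distance-map predictions.
#' @param ... Unused.
#' @return A single mask/map, or a list of them for multiple inputs.
#' @export
predict.distseg_model <- function(object, images,
                                  type = c("labels", "distance"), ...) {
  type <- match.arg(type)
  single <- is.matrix(images)
  if (single) images <- list(images)
  if (is.character(images)) images <- lapply(images, load_image)
  out <- lapply(images, function(img) {
    dm <- infer_distance_map(img, function(p) predict_patch(object$backbone, p),
                             object$preprocess)
    if (type == "distance") dm else
      segment_distance_map(dm, object$postprocess)
  })
  if (single) out[[1]] else out
}

#' @export
plot.distseg_model <- function(x, ...) {
  h <- x$history
  ep <- seq_along(h$train_loss)
  graphics::matplot(ep, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "L2 loss", ...)
  graphics::abline(v = h$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
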