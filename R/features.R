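## Convolutional feature extractor. The backbone follows the VGG19
## convolutional layout (3x3 kernels, stride 1, zero padding, ReLU after
## every convolution, 2x2 max-pooling between blocks, channel widths
## 64-64 | 128-128 | 256x4 | 512x4 | 512x4, no fully connected layers).
## Only a scalar summary of its activations (the mean activation mu) feeds
## the fusion rule, so the pipeline is valid with pretrained, fine-tuned,
## seeded-random, or stub weights; random initialization is the default so
## nothing has to be downloaded.
##
## Forward and backward passes are implemented with im2col + BLAS matrix
## products; training uses Adam, a step learning-rate schedule and global
## gradient-norm clipping.

.vgg_widths <- c(64, 64, 128, 128, 256, 256, 256, 256,
                 512, 512, 512, 512, 512, 512, 512, 512)
.vgg_pool_after <- c(2L, 4L, 8L, 12L, 16L)  # conv indices ending each block

new_conv_layer <- function(kh, kw, cin, cout, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "he") {
    array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
          dim = c(kh, kw, cin, cout))
  } else {
    array(0, dim = c(kh, kw, cin, cout))
  }
  list(type = "conv", w = w, b = numeric(cout))
}

#' Construct a VGG19-style convolutional feature extractor
#'
#' @param weights `"random"` (seeded He initialization, the offline
#'   default) or `"zero"` (all-zero weights and biases; every activation,
#'   hence every mean activation, is zero).
#' @param seed integer seed for the random initialization.
#' @param width_scale positive scale applied to all channel widths; 1 is
#'   the full 64..512 layout, 1/8 gives a light backbone with the same
#'   depth and pooling structure for fast CPU experimentation.
#' @param input_size square input resolution the extractor expects
#'   (default 224).
#' @return object of class `feature_extractor`.
#' @export
vgg_backbone <- function(weights = c("random", "zero"), seed = 1L,
                         width_scale = 1, input_size = 224L) {
  weights <- match.arg(weights)
  widths <- pmax(1L, as.integer(round(.vgg_widths * width_scale)))
  layers <- list()
  cin <- 3L
  with_seed(seed, {
    for (i in seq_along(widths)) {
      layers[[length(layers) + 1L]] <- new_conv_layer(
        3L, 3L, cin, widths[i],
        init = if (weights == "zero") "zero" else "he")
      cin <- widths[i]
      if (i %in% .vgg_pool_after && i < length(widths)) {
        layers[[length(layers) + 1L]] <- list(type = "pool")
      }
    }
  })
  structure(list(layers = layers, input_size = as.integer(input_size),
                 arch = sprintf("vgg19-conv x%.3g", width_scale)),
            class = "feature_extractor")
}

#' Construct a stub feature extractor
#'
#' Degenerate single-layer backbones used to pin down the fusion algebra
#' independently of learned weights: `"identity"` is a 1x1 convolution
#' passing each channel through (so, after rectification, the mean
#' activation equals the mean positive value of the normalized input);
#' `"zero"` produces identically zero activations.
#'
#' @param kind `"identity"` or `"zero"`.
#' @param input_size square input resolution (default 224).
#' @return object of class `feature_extractor`.
#' @export
stub_backbone <- function(kind = c("identity", "zero"), input_size = 224L) {
  kind <- match.arg(kind)
  w <- array(0, dim = c(1, 1, 3, 3))
  if (kind == "identity") for (c in 1:3) w[1, 1, c, c] <- 1
  layers <- list(list(type = "conv", w = w, b = numeric(3)))
  structure(list(layers = layers, input_size = as.integer(input_size),
                 arch = paste0("stub-", kind)),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) {
    if (l$type == "conv") length(l$w) + length(l$b) else 0L
  }, numeric(1)))
  cat(sprintf("feature_extractor '%s': %d layers, %s parameters, input %dx%d\n",
              x$arch, length(x$layers), format(n_par, big.mark = ","),
              x$input_size, x$input_size))
  invisible(x)
}

## ---- conv / pool primitives ---------------------------------------------

## im2col for odd square kernels with zero 'same' padding.
im2col <- function(x, kh, kw) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, dim = c(h + 2L * ph, w + 2L * pw, cin))
  xp[ph + seq_len(h), pw + seq_len(w), ] <- x
  cols <- matrix(0, h * w, kh * kw * cin)
  idx <- 0L
  for (c in seq_len(cin)) {
    for (j in seq_len(kw)) {
      for (i in seq_len(kh)) {
        idx <- idx + 1L
        cols[, idx] <- xp[i:(i + h - 1L), j:(j + w - 1L), c]
      }
    }
  }
  cols
}

conv_forward <- function(x, layer) {
  kh <- dim(layer$w)[1]; kw <- dim(layer$w)[2]; cout <- dim(layer$w)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  cols <- im2col(x, kh, kw)
  wmat <- matrix(layer$w, ncol = cout)
  y <- cols %*% wmat
  y <- sweep(y, 2L, layer$b, "+")
  array(y, dim = c(h, w, cout))
}

conv_backward <- function(x, layer, dy) {
  kh <- dim(layer$w)[1]; kw <- dim(layer$w)[2]
  cin <- dim(layer$w)[3]; cout <- dim(layer$w)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  cols <- im2col(x, kh, kw)
  dymat <- matrix(dy, h * w, cout)
  dw <- array(crossprod(cols, dymat), dim = dim(layer$w))
  db <- colSums(dymat)
  dcols <- tcrossprod(dymat, matrix(layer$w, ncol = cout))
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dxp <- array(0, dim = c(h + 2L * ph, w + 2L * pw, cin))
  idx <- 0L
  for (c in seq_len(cin)) {
    for (j in seq_len(kw)) {
      for (i in seq_len(kh)) {
        idx <- idx + 1L
        dxp[i:(i + h - 1L), j:(j + w - 1L), c] <-
          dxp[i:(i + h - 1L), j:(j + w - 1L), c] + matrix(dcols[, idx], h, w)
      }
    }
  }
  dx <- dxp[ph + seq_len(h), pw + seq_len(w), , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

pool_forward <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  a <- x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE]
  b <- x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE]
  d <- x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE]
  e <- x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
  out <- pmax(a, b, d, e)
  ## deterministic argmax: first of (a,b,d,e) attaining the max
  which4 <- array(1L, dim = dim(out))
  which4[a < out & b == out] <- 2L
  which4[a < out & b < out & d == out] <- 3L
  which4[a < out & b < out & d < out & e == out] <- 4L
  list(out = out, which = which4)
}

pool_backward <- function(dy, which4, in_dim) {
  dx <- array(0, dim = in_dim)
  h2 <- dim(dy)[1]; w2 <- dim(dy)[2]
  oi <- seq(1, 2 * h2, 2); oj <- seq(1, 2 * w2, 2)
  for (q in 1:4) {
    mask <- which4 == q
    if (!any(mask)) next
    di <- oi + as.integer(q %in% c(2, 4))
    dj <- oj + as.integer(q %in% c(3, 4))
    sub <- array(0, dim = dim(dy))
    sub[mask] <- dy[mask]
    dx[di, dj, ] <- dx[di, dj, ] + sub
  }
  dx
}

## Forward pass. Returns the block outputs (post-ReLU activations of the
## last convolution in each block) and, when train = TRUE, the caches
## needed for backpropagation.
backbone_forward <- function(net, x, train = FALSE) {
  blocks <- list()
  caches <- if (train) vector("list", length(net$layers)) else NULL
  conv_i <- 0L
  n_conv <- sum(vapply(net$layers, function(l) l$type == "conv", logical(1)))
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      conv_i <- conv_i + 1L
      pre <- conv_forward(x, layer)
      out <- pmax(pre, 0)
      if (train) caches[[li]] <- list(x = x, mask = pre > 0)
      x <- out
      if (conv_i %in% .vgg_pool_after || conv_i == n_conv) {
        blocks[[length(blocks) + 1L]] <- x
      }
    } else {
      pf <- pool_forward(x)
      if (train) caches[[li]] <- list(which = pf$which, in_dim = dim(x))
      x <- pf$out
    }
  }
  list(out = x, blocks = blocks, caches = caches)
}

backbone_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dy <- dout
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      dy <- dy * caches[[li]]$mask
      g <- conv_backward(caches[[li]]$x, layer, dy)
      grads[[li]] <- list(dw = g$dw, db = g$db)
      dy <- g$dx
    } else {
      dy <- pool_backward(dy, caches[[li]]$which, caches[[li]]$in_dim)
    }
  }
  grads
}

## ---- user-facing operations ---------------------------------------------

#' Normalize an image for the feature extractor
#'
#' Resizes to the extractor's square input resolution, replicates a
#' grayscale plane to three channels, and maps intensities from \[0,1\] to
#' \[-1,1\] via (I - 0.5) / 0.5.
#'
#' @param img Image2D or H x W x 3 array with values in \[0,1\].
#' @param size output spatial size (default 224).
#' @return `size` x `size` x 3 array with values in \[-1,1\].
#' @export
normalize_for_backbone <- function(img, size = 224L) {
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  assert_plane3(img)
  x <- resize_bilinear(img, size, size)
  (unclass(x) - 0.5) / 0.5
}

#' Mean feature activation of an image
#'
#' Runs `normalize_for_backbone(img)` through the extractor and returns the
#' global mean over all channels and positions of the deepest block's
#' post-rectification output. This scalar is the per-modality ingredient of
#' the high-frequency fusion gate; it is non-negative and invariant to the
#' input's original spatial size.
#'
#' @param extractor a `feature_extractor`.
#' @param img Image2D or RGB array in \[0,1\] (high-frequency maps should
#'   be min-max rescaled first, see [rescale01()]).
#' @param block which block's output to average; `NULL` (default) = the
#'   deepest block.
#' @return scalar mu >= 0.
#' @export
mean_activation <- function(extractor, img, block = NULL) {
  stopifnot(inherits(extractor, "feature_extractor"))
  x <- normalize_for_backbone(img, extractor$input_size)
  fw <- backbone_forward(extractor, x)
  f <- if (is.null(block)) fw$blocks[[length(fw$blocks)]] else fw$blocks[[block]]
  mu <- mean(f)
  if (!is.finite(mu)) stop("non-finite activations in feature extractor", call. = FALSE)
  mu
}

#' Extract per-block feature maps
#'
#' @param extractor a `feature_extractor`.
#' @param img Image2D or RGB array in \[0,1\].
#' @return list of H_l x W_l x C_l arrays, one per convolutional block
#'   (post-rectification output of the last convolution in the block).
#' @export
extract_features <- function(extractor, img) {
  stopifnot(inherits(extractor, "feature_extractor"))
  x <- normalize_for_backbone(img, extractor$input_size)
  backbone_forward(extractor, x)$blocks
}

#' L1 feature-consistency loss
#'
#' `||f1 - f2||_1` with mean reduction by default (resolution-independent);
#' symmetric, non-negative, and zero iff the feature maps are identical.
#'
#' @param f1,f2 numeric arrays of identical shape.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return scalar loss.
#' @export
consistency_loss <- function(f1, f2, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!all(dim(f1) == dim(f2))) {
    stop("feature maps must have identical shapes", call. = FALSE)
  }
  d <- abs(f1 - f2)
  if (reduction == "mean") mean(d) else sum(d)
}

#' Training configuration for extractor fine-tuning
#'
#' Defaults follow the published recipe: Adam at learning rate 1e-5, step
#' schedule (step size 3, decay 0.7), global gradient-norm clip 1.0,
#' 10 epochs, and the augmentation set resize / horizontal flip p = 0.5 /
#' rotation within 15 degrees / color jitter / Gaussian blur with sigma in
#' \[0.1, 2\].
#'
#' @param epochs number of epochs (>= 1).
#' @param lr initial learning rate (> 0; 0 is allowed for a frozen run).
#' @param step_size scheduler step in epochs.
#' @param gamma scheduler decay factor.
#' @param grad_clip maximum global gradient norm.
#' @param seed integer seed driving shuffling and augmentation.
#' @param jitter list of color-jitter magnitudes
#'   (brightness, contrast, saturation, hue).
#' @param rotation max absolute rotation in degrees.
#' @param blur_sigma length-2 range of Gaussian blur sigma.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 10L, lr = 1e-5, step_size = 3L, gamma = 0.7,
                         grad_clip = 1.0, seed = 1L,
                         jitter = list(brightness = 0.2, contrast = 0.2,
                                       saturation = 0.2, hue = 0.05),
                         rotation = 15, blur_sigma = c(0.1, 2.0)) {
  stopifnot(epochs >= 1, lr >= 0, step_size >= 1, gamma > 0, grad_clip > 0)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 step_size = as.integer(step_size), gamma = gamma,
                 grad_clip = grad_clip, seed = as.integer(seed),
                 jitter = jitter, rotation = rotation, blur_sigma = blur_sigma),
            class = "train_config")
}

#' Scheduled learning rate for a given epoch
#'
#' Step decay: `lr * gamma^floor((epoch - 1) / step_size)` (1-indexed
#' epochs), so with step 3 and decay 0.7 epochs 1-3 run at `lr`, epoch 4
#' at `0.7 lr`, epoch 7 at `0.49 lr`.
#'
#' @param cfg a [train_config()].
#' @param epoch 1-indexed epoch number.
#' @return learning rate for that epoch.
#' @export
scheduled_lr <- function(cfg, epoch) {
  cfg$lr * cfg$gamma^floor((epoch - 1) / cfg$step_size)
}

## Seeded augmentation of a 3-channel array in [0,1] (draws from the
## ambient RNG stream; callers seed it once for the whole loop).
augment_image <- function(x, cfg) {
  ## horizontal flip
  if (stats::runif(1) < 0.5) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  ## rotation
  ang <- stats::runif(1, -cfg$rotation, cfg$rotation)
  for (c in 1:3) x[, , c] <- rotate_bilinear(x[, , c], ang)
  ## color jitter: brightness, contrast, saturation, hue (in that order)
  jb <- cfg$jitter
  x <- x * stats::runif(1, 1 - jb$brightness, 1 + jb$brightness)
  mu <- mean(x)
  x <- (x - mu) * stats::runif(1, 1 - jb$contrast, 1 + jb$contrast) + mu
  lum <- luminance(clip01(array(x, dim = dim(x))))
  fs <- stats::runif(1, 1 - jb$saturation, 1 + jb$saturation)
  for (c in 1:3) x[, , c] <- lum + fs * (x[, , c] - lum)
  th <- stats::runif(1, -jb$hue, jb$hue) * 2 * pi
  yuv <- rgb_to_yuv(clip01(array(x, dim = dim(x))))
  u <- plane(yuv, 2); v <- plane(yuv, 3)
  yuv[, , 2] <- cos(th) * u - sin(th) * v
  yuv[, , 3] <- sin(th) * u + cos(th) * v
  x <- unclass(yuv_to_rgb(yuv))
  ## Gaussian blur
  sg <- stats::runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2])
  for (c in 1:3) x[, , c] <- gaussian_blur(x[, , c], sg)
  clip01(x)
}

#' Fine-tune a feature extractor with the L1 consistency objective
#'
#' For each epoch and each training image, an augmented view is generated
#' (flip, rotation, color jitter, blur), both views are passed through the
#' extractor, and the L1 distance between their deepest-block feature maps
#' is minimized with Adam under a step learning-rate schedule and global
#' gradient-norm clipping. Self-supervised: no labels or fusion targets
#' are involved.
#'
#' @param extractor a `feature_extractor`.
#' @param images non-empty list of Image2D matrices or RGB arrays in
#'   \[0,1\].
#' @param cfg a [train_config()].
#' @return the updated `feature_extractor`, with attribute `"history"`: a
#'   data.frame with one row per optimization step (epoch, step, loss,
#'   grad_norm_raw, grad_norm, lr).
#' @export
finetune <- function(extractor, images, cfg = train_config()) {
  stopifnot(inherits(extractor, "feature_extractor"),
            inherits(cfg, "train_config"))
  if (length(images) == 0) stop("images must be a non-empty list", call. = FALSE)
  net <- extractor
  conv_idx <- which(vapply(net$layers, function(l) l$type == "conv", logical(1)))
  adam_m <- lapply(net$layers[conv_idx], function(l) list(w = l$w * 0, b = l$b * 0))
  adam_v <- adam_m
  t_step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  hist <- list()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr_e <- scheduled_lr(cfg, epoch)
      order_e <- sample(length(images))
      for (step in seq_along(order_e)) {
        img <- images[[order_e[step]]]
        x1 <- normalize_for_backbone(img, net$input_size)
        x01 <- (x1 + 1) / 2                     # augment on the [0,1] scale
        x2 <- unclass(augment_image(x01, cfg)) * 2 - 1
        fw1 <- backbone_forward(net, x1, train = TRUE)
        fw2 <- backbone_forward(net, x2, train = TRUE)
        f1 <- fw1$out; f2 <- fw2$out
        loss <- mean(abs(f1 - f2))
        dsign <- sign(f1 - f2) / length(f1)
        g1 <- backbone_backward(net, fw1$caches, dsign)
        g2 <- backbone_backward(net, fw2$caches, -dsign)
        ## total gradients and global norm
        sq <- 0
        grads <- vector("list", length(conv_idx))
        for (k in seq_along(conv_idx)) {
          li <- conv_idx[k]
          gw <- g1[[li]]$dw + g2[[li]]$dw
          gb <- g1[[li]]$db + g2[[li]]$db
          grads[[k]] <- list(w = gw, b = gb)
          sq <- sq + sum(gw^2) + sum(gb^2)
        }
        gnorm_raw <- sqrt(sq)
        scale <- if (gnorm_raw > cfg$grad_clip) cfg$grad_clip / gnorm_raw else 1
        t_step <- t_step + 1L
        for (k in seq_along(conv_idx)) {
          li <- conv_idx[k]
          gw <- grads[[k]]$w * scale
          gb <- grads[[k]]$b * scale
          adam_m[[k]]$w <- beta1 * adam_m[[k]]$w + (1 - beta1) * gw
          adam_m[[k]]$b <- beta1 * adam_m[[k]]$b + (1 - beta1) * gb
          adam_v[[k]]$w <- beta2 * adam_v[[k]]$w + (1 - beta2) * gw^2
          adam_v[[k]]$b <- beta2 * adam_v[[k]]$b + (1 - beta2) * gb^2
          mhat_w <- adam_m[[k]]$w / (1 - beta1^t_step)
          mhat_b <- adam_m[[k]]$b / (1 - beta1^t_step)
          vhat_w <- adam_v[[k]]$w / (1 - beta2^t_step)
          vhat_b <- adam_v[[k]]$b / (1 - beta2^t_step)
          net$layers[[li]]$w <- net$layers[[li]]$w -
            lr_e * mhat_w / (sqrt(vhat_w) + adam_eps)
          net$layers[[li]]$b <- net$layers[[li]]$b -
            lr_e * mhat_b / (sqrt(vhat_b) + adam_eps)
        }
        hist[[length(hist) + 1L]] <- data.frame(
          epoch = epoch, step = step, loss = loss,
          grad_norm_raw = gnorm_raw,
          grad_norm = min(gnorm_raw, cfg$grad_clip),
          lr = lr_e)
      }
    }
  })
  attr(net, "history") <- do.call(rbind, hist)
  net
}
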