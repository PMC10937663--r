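#' U-Net architecture specification
#'
#' A symmetric encoder/decoder segmentation network: a contracting path of
#' double 3x3 convolution blocks (ReLU) with 2x2 max pooling, and an
#' expansive path of 2x2 up-convolutions (transposed convolution, stride 2)
#' with skip connections concatenating same-resolution encoder features,
#' closed by a 1x1 convolution onto 2 classes (vessel / non-vessel).
#' Convolutions are size-preserving ("same" zero padding), so the output
#' matches the input B-scan size; inputs must have both dimensions divisible
#' by `2^length(widths)`.
#'
#' @param widths Encoder channel widths per level, strictly doubling
#'   (default `c(32, 64, 128, 256)`); the deepest feature map has
#'   `widths[4]` channels at 1/16 of the input extent.
#' @param in_channels Input channels (grayscale B-scans: 1).
#' @param classes Output classes (fixed at 2).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(widths = c(32, 64, 128, 256), in_channels = 1L,
                      classes = 2L) {
  widths <- as.integer(widths)
  if (length(widths) != 4L || any(diff(widths) <= 0) ||
      any(widths[-1] != 2L * widths[-length(widths)])) {
    stop("unet_spec: widths must be 4 strictly increasing values, doubling per level")
  }
  if (classes != 2L) stop("unet_spec: class count is fixed at 2")
  structure(
    list(widths = widths, in_channels = as.integer(in_channels), classes = 2L),
    class = "unet_spec"
  )
}

# He-normal initialized conv weight [Cout x (k2*Cin)] and zero bias
init_conv <- function(cout, cin, k2) {
  list(
    W = matrix(rnorm(cout * k2 * cin, sd = sqrt(2 / (k2 * cin))), cout, k2 * cin),
    b = numeric(cout)
  )
}

#' Build (initialize) a U-Net model
#'
#' Allocates He-initialized weights for the architecture in `spec`. The
#' returned model is an R list of parameter matrices; training state
#' (optimizer moments) is created by [unet_train()].
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for the weight initialization.
#' @param fg_bias Initial bias of the foreground (vessel) logit in the final
#'   1x1 convolution (default -2). Vessels occupy a small fraction of each
#'   B-scan; starting from a low foreground prior keeps the early Dice
#'   denominator small and substantially accelerates convergence.
#' @return An object of class `octl_unet` with elements `spec`, `params`
#'   (named list of `W`/`b`), `seed`.
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L, fg_bias = -2) {
  stopifnot(inherits(spec, "unet_spec"))
  w <- spec$widths
  params <- with_seed(seed, {
    p <- list()
    cin <- spec$in_channels
    for (l in 1:4) {
      p[[paste0("enc", l, ".conv1")]] <- init_conv(w[l], cin, 9L)
      p[[paste0("enc", l, ".conv2")]] <- init_conv(w[l], w[l], 9L)
      cin <- w[l]
    }
    p[["bott.conv1"]] <- init_conv(w[4], w[4], 9L)
    p[["bott.conv2"]] <- init_conv(w[4], w[4], 9L)
    up_in <- w[4]
    for (l in 4:1) {
      p[[paste0("dec", l, ".up")]] <- init_conv(w[l], up_in, 4L)
      p[[paste0("dec", l, ".conv1")]] <- init_conv(w[l], 2L * w[l], 9L)
      p[[paste0("dec", l, ".conv2")]] <- init_conv(w[l], w[l], 9L)
      up_in <- w[l]
    }
    p[["final"]] <- init_conv(spec$classes, w[1], 1L)
    p[["final"]]$b <- c(0, fg_bias)
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
    class = "octl_unet"
  )
}

#' @export
print.octl_unet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf(
    "<octl_unet> widths %s, %d classes, %s parameters\n",
    paste(x$spec$widths, collapse = "/"), x$spec$classes,
    format(np, big.mark = ",")
  ))
  invisible(x)
}

n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

as_cube <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

check_div16 <- function(h, w) {
  if (h %% 16L != 0L || w %% 16L != 0L) {
    stop(sprintf(
      "input size %dx%d is not divisible by 16; pad the B-scan (see pad16()) before inference",
      h, w
    ))
  }
}

# forward pass; x: H x W matrix in [0, 1]. Returns logits cube H x W x 2 and,
# when keep_cache, every intermediate needed for the backward pass.
unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  check_div16(nrow(x), ncol(x))
  cache <- list()
  a <- as_cube(x)
  skips <- list()
  for (l in 1:4) {
    n1 <- paste0("enc", l, ".conv1")
    n2 <- paste0("enc", l, ".conv2")
    z1 <- conv3_fwd(a, p[[n1]]$W, p[[n1]]$b)
    a1 <- relu(z1)
    z2 <- conv3_fwd(a1, p[[n2]]$W, p[[n2]]$b)
    a2 <- relu(z2)
    pool <- maxpool2_fwd(a2)
    if (keep_cache) {
      cache[[paste0("enc", l)]] <- list(x = a, a1 = a1, a2 = a2, idx = pool$idx)
    }
    skips[[l]] <- a2
    a <- pool$y
  }
  zb1 <- conv3_fwd(a, p[["bott.conv1"]]$W, p[["bott.conv1"]]$b)
  ab1 <- relu(zb1)
  zb2 <- conv3_fwd(ab1, p[["bott.conv2"]]$W, p[["bott.conv2"]]$b)
  ab2 <- relu(zb2)
  if (keep_cache) cache[["bott"]] <- list(x = a, a1 = ab1, a2 = ab2)
  a <- ab2
  for (l in 4:1) {
    nu <- paste0("dec", l, ".up")
    n1 <- paste0("dec", l, ".conv1")
    n2 <- paste0("dec", l, ".conv2")
    up <- upconv2_fwd(a, p[[nu]]$W, p[[nu]]$b)
    cat_in <- abind3(skips[[l]], up)
    z1 <- conv3_fwd(cat_in, p[[n1]]$W, p[[n1]]$b)
    a1 <- relu(z1)
    z2 <- conv3_fwd(a1, p[[n2]]$W, p[[n2]]$b)
    a2 <- relu(z2)
    if (keep_cache) {
      cache[[paste0("dec", l)]] <- list(
        x = a, up = up, cat_in = cat_in,
        a1 = a1, a2 = a2
      )
    }
    a <- a2
  }
  logits <- conv1_fwd(a, p[["final"]]$W, p[["final"]]$b)
  if (keep_cache) cache[["pre_final"]] <- a
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

abind3 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# backward pass from d(loss)/d(logits); returns named gradient list
unet_backward <- function(model, cache, glogits) {
  p <- model$params
  g <- list()
  bk <- conv1_bwd(cache[["pre_final"]], p[["final"]]$W, glogits)
  g[["final"]] <- list(W = bk$gW, b = bk$gb)
  ga <- bk$gx
  for (l in 1:4) {
    cc <- cache[[paste0("dec", l)]]
    nu <- paste0("dec", l, ".up")
    n1 <- paste0("dec", l, ".conv1")
    n2 <- paste0("dec", l, ".conv2")
    gz2 <- ga * (cc$a2 > 0)
    bk2 <- conv3_bwd(cc$a1, p[[n2]]$W, gz2)
    g[[n2]] <- list(W = bk2$gW, b = bk2$gb)
    gz1 <- bk2$gx * (cc$a1 > 0)
    bk1 <- conv3_bwd(cc$cat_in, p[[n1]]$W, gz1)
    g[[n1]] <- list(W = bk1$gW, b = bk1$gb)
    nskip <- dim(cc$cat_in)[3] - dim(cc$up)[3]
    gskip <- bk1$gx[, , seq_len(nskip), drop = FALSE]
    gup <- bk1$gx[, , nskip + seq_len(dim(cc$up)[3]), drop = FALSE]
    bku <- upconv2_bwd(cc$x, p[[nu]]$W, gup)
    g[[nu]] <- list(W = bku$gW, b = bku$gb)
    # gradient flowing into the decoder level below (or the bottleneck)
    ga_next <- bku$gx
    # stash the skip gradient for the matching encoder level
    g[[paste0("skip", l)]] <- gskip
    ga <- ga_next
  }
  # bottleneck
  cb <- cache[["bott"]]
  gz2 <- ga * (cb$a2 > 0)
  bk2 <- conv3_bwd(cb$a1, p[["bott.conv2"]]$W, gz2)
  g[["bott.conv2"]] <- list(W = bk2$gW, b = bk2$gb)
  gz1 <- bk2$gx * (cb$a1 > 0)
  bk1 <- conv3_bwd(cb$x, p[["bott.conv1"]]$W, gz1)
  g[["bott.conv1"]] <- list(W = bk1$gW, b = bk1$gb)
  gpool <- bk1$gx
  for (l in 4:1) {
    ce <- cache[[paste0("enc", l)]]
    n1 <- paste0("enc", l, ".conv1")
    n2 <- paste0("enc", l, ".conv2")
    da2 <- dim(ce$a2)
    ga2 <- maxpool2_bwd(gpool, ce$idx, da2[1], da2[2]) + g[[paste0("skip", l)]]
    g[[paste0("skip", l)]] <- NULL
    gz2 <- ga2 * (ce$a2 > 0)
    bk2 <- conv3_bwd(ce$a1, p[[n2]]$W, gz2)
    g[[n2]] <- list(W = bk2$gW, b = bk2$gb)
    gz1 <- bk2$gx * (ce$a1 > 0)
    bk1 <- conv3_bwd(ce$x, p[[n1]]$W, gz1)
    g[[n1]] <- list(W = bk1$gW, b = bk1$gb)
    gpool <- bk1$gx
  }
  g
}

softmax2 <- function(logits) {
  # returns foreground (class 2, vessel) probability, numerically stable
  1 / (1 + exp(logits[, , 1] - logits[, , 2]))
}

#' Dice loss between predicted probabilities and a binary target
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`, with the
#' smoothing constant `eps` (default 1) preventing division by zero for
#' empty targets. Zero iff the binary prediction matches the target
#' exactly (up to the eps term); close to 1 for disjoint masks.
#'
#' @param pred Per-pixel foreground probability in `[0, 1]`.
#' @param target Binary (logical or 0/1) array, same shape.
#' @param eps Smoothing constant (default 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1) {
  if (!all(dim(pred) == dim(target))) stop("dice_loss: shape mismatch")
  if (any(pred < 0 | pred > 1)) stop("dice_loss: pred must lie in [0, 1]")
  t <- as.numeric(target)
  s <- 2 * sum(pred * t) + eps
  d <- sum(pred) + sum(t) + eps
  1 - s / d
}

# gradient of dice_loss w.r.t. pred
dice_loss_grad <- function(pred, target, eps = 1) {
  t <- as.numeric(target)
  s <- 2 * sum(pred * t) + eps
  d <- sum(pred) + sum(t) + eps
  array(-(2 * t * d - s) / d^2, dim = dim(pred))
}

#' Convert a dB B-scan to 8-bit grayscale
#'
#' Linear map of `[0, vmax]` dB onto `[0, 255]`, clipping negatives and
#' values above `vmax`; `vmax` defaults to the 99.9th percentile of the
#' supplied reference data (pass the whole volume to fix one scale across
#' all its B-scans). Values are rounded half away from zero, so `vmax / 2`
#' maps to 128.
#'
#' @param image Numeric matrix (B-scan) in dB.
#' @param vmax Upper end of the dB scale; default the 99.9th percentile of
#'   `reference`.
#' @param reference Data from which the default `vmax` is taken (defaults to
#'   `image`).
#' @return Integer matrix with values in 0..255.
#' @export
to_uint8 <- function(image, vmax = NULL, reference = image) {
  if (!all(is.finite(image))) stop("to_uint8: image must be finite")
  if (is.null(vmax)) vmax <- quantile(reference, 0.999, names = FALSE)
  if (vmax <= 0 || diff(range(image)) == 0) {
    warning("to_uint8: constant or non-positive image; returning zeros")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  v <- pmin(pmax(image, 0), vmax) / vmax * 255
  matrix(as.integer(floor(v + 0.5)), nrow(image), ncol(image))
}

#' Randomly split B-scans into train/validation/test groups
#'
#' @param n Number of B-scans (>= 4).
#' @param fractions Length-3 fractions summing to 1
#'   (default `c(0.5, 0.25, 0.25)`, i.e. 300/150/150 out of 600).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with integer index vectors `train`, `val`, `test`:
#'   disjoint, exhaustive, sizes `round(n * fractions)`.
#' @export
split_dataset <- function(n, fractions = c(0.5, 0.25, 0.25), seed = 1L) {
  if (n < 4L) stop("split_dataset: need at least 4 B-scans")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("split_dataset: fractions must be length 3 and sum to 1")
  }
  sizes <- round(n * fractions)
  sizes[3] <- n - sizes[1] - sizes[2]
  perm <- with_seed(seed, sample.int(n))
  list(
    train = sort(perm[seq_len(sizes[1])]),
    val = sort(perm[sizes[1] + seq_len(sizes[2])]),
    test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  )
}

#' Training configuration
#'
#' @param lr Initial Adam learning rate (default 1e-4).
#' @param epochs Maximum epochs (default 150).
#' @param batch_size Images per optimization step (default 1: one Adam step
#'   per B-scan).
#' @param eps Dice smoothing constant (default 1).
#' @param seed Seed controlling shuffling (and initialization in
#'   [unet_train()] when the model is built there).
#' @param patience Stop early after this many consecutive epochs with
#'   training mean IOU >= `iou_target`; `Inf` disables early stopping.
#' @param iou_target Convergence level for early stopping (default 0.995).
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 150L, batch_size = 1L, eps = 1,
                         seed = 1L, patience = 5L, iou_target = 0.995) {
  stopifnot(lr >= 0, epochs >= 1, batch_size >= 1)
  structure(
    list(
      lr = lr, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), eps = eps,
      seed = as.integer(seed), patience = patience, iou_target = iou_target
    ),
    class = "train_config"
  )
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0,
    mb = p$b * 0, vb = p$b * 0
  ))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      adam_eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + adam_eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + adam_eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# one forward/backward on a single image; returns loss, grads, predicted mask
unet_grad_single <- function(model, x, target, eps = 1) {
  fw <- unet_forward(model, x, keep_cache = TRUE)
  prob <- softmax2(fw$logits)
  loss <- dice_loss(prob, target, eps = eps)
  gp <- dice_loss_grad(prob, target, eps = eps)
  gz2 <- gp * prob * (1 - prob)
  glogits <- array(0, dim = dim(fw$logits))
  glogits[, , 2] <- gz2
  glogits[, , 1] <- -gz2
  grads <- unet_backward(model, fw$cache, glogits)
  list(loss = loss, grads = grads, mask = prob > 0.5)
}

#' Train the U-Net on labelled B-scans
#'
#' Dice-loss training with the Adam optimizer (initial learning rate 1e-4 by
#' default), no augmentation. Per epoch, the mean intersection-over-union of
#' the thresholded predictions against the labels is recorded as the
#' accuracy for the training group (from the pre-update forward passes) and
#' the validation group (a dedicated forward pass); the best model is the
#' one with maximal validation accuracy.
#'
#' @param model An `octl_unet` from [build_unet()].
#' @param images List of input B-scans: numeric matrices in `[0, 1]`
#'   (uint8 / 255; see [to_uint8()]), all sizes divisible by 16.
#' @param labels List of binary matrices, same sizes as `images`.
#' @param val_images,val_labels Validation set, same conventions (>= 1
#'   image).
#' @param config A [train_config()].
#' @return The trained model, with `$history` (a `train_history` data.frame:
#'   `epoch`, `train_loss`, `val_loss`, `train_iou`, `val_iou`),
#'   `$best_epoch`, and `$config` attached. Parameters are those of the
#'   best-validation epoch.
#' @export
unet_train <- function(model, images, labels, val_images, val_labels,
                       config = train_config()) {
  stopifnot(inherits(model, "octl_unet"), inherits(config, "train_config"))
  if (length(images) < 1L || length(val_images) < 1L) {
    stop("unet_train: need at least one training and one validation image")
  }
  if (length(images) != length(labels)) stop("unet_train: images/labels length mismatch")
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == dim(labels[[i]]))) {
      stop("unet_train: label size must match image size")
    }
  }
  params <- model$params
  state <- adam_init(params)
  nb <- length(images)
  hist <- data.frame(
    epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0),
    train_iou = numeric(0), val_iou = numeric(0)
  )
  best <- list(iou = -Inf, params = params, epoch = 0L)
  t_step <- 0L
  converged_for <- 0L
  order_seed <- config$seed
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(order_seed + epoch, sample.int(nb))
    losses <- numeric(0)
    ious <- numeric(nb)
    k <- 1L
    while (k <= nb) {
      idx <- ord[k:min(nb, k + config$batch_size - 1L)]
      acc <- NULL
      bl <- 0
      for (i in idx) {
        model$params <- params
        r <- unet_grad_single(model, images[[i]], labels[[i]], eps = config$eps)
        bl <- bl + r$loss / length(idx)
        ious[i] <- iou(r$mask, labels[[i]] > 0)
        if (is.null(acc)) {
          acc <- r$grads
        } else {
          for (nm in names(acc)) {
            acc[[nm]]$W <- acc[[nm]]$W + r$grads[[nm]]$W
            acc[[nm]]$b <- acc[[nm]]$b + r$grads[[nm]]$b
          }
        }
      }
      for (nm in names(acc)) {
        acc[[nm]]$W <- acc[[nm]]$W / length(idx)
        acc[[nm]]$b <- acc[[nm]]$b / length(idx)
      }
      if (!is.finite(bl)) stop(sprintf("unet_train: NaN loss at epoch %d", epoch))
      t_step <- t_step + 1L
      if (config$lr > 0) {
        upd <- adam_step(params, acc, state, config$lr, t_step)
        params <- upd$params
        state <- upd$state
      }
      losses <- c(losses, bl)
      k <- k + config$batch_size
    }
    # validation pass with the updated parameters
    model$params <- params
    vloss <- 0
    viou <- numeric(length(val_images))
    for (i in seq_along(val_images)) {
      fw <- unet_forward(model, val_images[[i]])
      prob <- softmax2(fw$logits)
      vloss <- vloss + dice_loss(prob, val_labels[[i]], eps = config$eps) /
        length(val_images)
      viou[i] <- iou(prob > 0.5, val_labels[[i]] > 0)
    }
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = mean(losses), val_loss = vloss,
      train_iou = mean(ious), val_iou = mean(viou)
    ))
    if (mean(viou) > best$iou) {
      best <- list(iou = mean(viou), params = params, epoch = epoch)
    }
    if (mean(ious) >= config$iou_target) {
      converged_for <- converged_for + 1L
      if (converged_for >= config$patience) break
    } else {
      converged_for <- 0L
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- structure(hist, class = c("train_history", "data.frame"))
  model$config <- config
  model
}

#' Pad a B-scan up to the next multiple of 16
#'
#' Zero-pads on the high side of each dimension; [unet_predict()] removes
#' the padding after inference, so predictions are invariant to it.
#'
#' @param image Numeric matrix.
#' @param multiple Required divisor (default 16).
#' @return List: `image` (padded), `orig` (original dimensions).
#' @export
pad16 <- function(image, multiple = 16L) {
  d <- dim(image)
  target <- ceiling(d / multiple) * multiple
  out <- matrix(0, target[1], target[2])
  out[seq_len(d[1]), seq_len(d[2])] <- image
  list(image = out, orig = d)
}

#' Segment a flattened, cropped volume with a trained U-Net
#'
#' Applies the network B-scan by B-scan (padding each to a multiple of 16
#' and un-padding afterwards) and takes the per-pixel argmax over the two
#' classes; ties break toward non-vessel.
#'
#' @param model Trained `octl_unet`.
#' @param volume Flattened, cropped [oct_volume()] (or a plain 3-D dB
#'   array).
#' @param vmax dB scale ceiling for [to_uint8()]; default the volume's
#'   99.9th percentile.
#' @return A flattened-frame [vessel_mask()] with provenance `"dl"`.
#' @export
unet_predict <- function(model, volume, vmax = NULL) {
  stopifnot(inherits(model, "octl_unet"))
  arr <- if (inherits(volume, "oct_volume")) volume$data else volume
  d <- dim(arr)
  if (is.null(vmax)) vmax <- quantile(arr, 0.999, names = FALSE)
  out <- array(FALSE, dim = d)
  for (j in seq_len(d[2])) {
    img <- to_uint8(arr[, j, ], vmax = vmax) / 255
    pd <- pad16(img)
    fw <- unet_forward(model, pd$image)
    prob <- softmax2(fw$logits)
    out[, j, ] <- prob[seq_len(d[1]), seq_len(d[3])] > 0.5
  }
  m <- vessel_mask(out,
    frame = "flattened",
    crop_um = if (inherits(volume, "oct_volume")) {
      attr(volume, "crop_um") %||% NA_real_
    } else {
      NA_real_
    },
    provenance = "dl"
  )
  m
}
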