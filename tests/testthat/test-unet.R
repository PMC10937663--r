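# The U-Net segmenter: architecture contracts, Dice loss, gradients,
# optimization behavior, prediction.

test_that("uint8 conversion maps the dB scale linearly with documented rounding", {
  img <- matrix(c(0, 10, 20, -5, 25, 20), 2, 3) # column-major fill
  u <- to_uint8(img, vmax = 20)
  expect_identical(u[1, 1], 0L) # 0 dB -> 0
  expect_identical(u[2, 2], 0L) # negatives clip to 0
  expect_identical(u[1, 2], 255L) # vmax -> 255
  expect_identical(u[1, 3], 255L) # above vmax clips
  expect_identical(u[2, 1], 128L) # vmax/2 rounds half away from zero
  expect_warning(u0 <- to_uint8(matrix(5, 3, 3)), "constant")
  expect_true(all(u0 == 0L))
})

test_that("the architecture spec enforces doubling widths and 2 classes", {
  expect_error(unet_spec(c(8, 16, 32)), "4")
  expect_error(unet_spec(c(8, 16, 32, 48)), "doubling")
  expect_error(unet_spec(c(8, 16, 32, 64), classes = 3), "2")
  s <- unet_spec(c(32, 64, 128, 256))
  expect_identical(s$widths, c(32L, 64L, 128L, 256L))
})

test_that("the network maps HxW inputs to HxWx2 scores through a /16 bottleneck", {
  model <- build_unet(unet_spec(c(4, 8, 16, 32)), seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  fw <- octlseg:::unet_forward(model, x, keep_cache = TRUE)
  expect_identical(dim(fw$logits), c(64L, 64L, 2L))
  # deepest feature: 1/16 of the extent, last encoder width
  expect_identical(dim(fw$cache$bott$x), c(4L, 4L, 32L))
  expect_error(
    octlseg:::unet_forward(model, matrix(0, 65, 64)),
    "divisible by 16"
  )
  # capacity grows monotonically when widths double
  expect_gt(
    octlseg:::n_params(build_unet(unet_spec(c(8, 16, 32, 64)), seed = 1)),
    octlseg:::n_params(build_unet(unet_spec(c(4, 8, 16, 32)), seed = 1))
  )
})

test_that("dice loss matches hand computations and set enumeration", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(t, t), 0) # exact match, any eps
  expect_equal(dice_loss(matrix(0.5, 2, 2), t, eps = 0), 0.5) # 1 - 2/(2+2)
  expect_equal(dice_loss(matrix(0.5, 2, 2), t, eps = 1), 1 - 3 / 5)
  disj <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_gt(dice_loss(disj, t), 0.7) # disjoint: ~1 up to the eps term
  expect_error(dice_loss(matrix(0.5, 2, 3), t), "shape")
  expect_error(dice_loss(matrix(2, 2, 2), t), "\\[0, 1\\]")

  # binary masks: loss equals 1 - (2|A&B| + eps)/(|A| + |B| + eps)
  set.seed(4)
  for (k in 1:200) {
    a <- matrix(runif(16) < 0.5, 4, 4)
    b <- matrix(runif(16) < 0.5, 4, 4)
    oracle <- 1 - (2 * sum(a & b) + 1) / (sum(a) + sum(b) + 1)
    expect_equal(dice_loss(a * 1, b), oracle)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  model <- build_unet(unet_spec(c(2, 4, 8, 16)), seed = 3)
  x <- matrix(runif(32 * 16), 32, 16)
  t <- matrix(runif(32 * 16) > 0.7, 32, 16)
  g <- octlseg:::unet_grad_single(model, x, t)
  eps <- 1e-6
  for (layer in c("enc2.conv1", "bott.conv2", "dec3.up", "dec1.conv2", "final")) {
    idx <- sample(length(model$params[[layer]]$W), 2)
    for (i in idx) {
      m2 <- model
      m2$params[[layer]]$W[i] <- m2$params[[layer]]$W[i] + eps
      lp <- octlseg:::unet_grad_single(m2, x, t)$loss
      m2$params[[layer]]$W[i] <- m2$params[[layer]]$W[i] - 2 * eps
      lm_ <- octlseg:::unet_grad_single(m2, x, t)$loss
      num <- (lp - lm_) / (2 * eps)
      ana <- g$grads[[layer]]$W[i]
      expect_lt(abs(num - ana), 1e-6 + 1e-3 * abs(num))
    }
  }
})

test_that("the random split is exact, disjoint, exhaustive and seeded", {
  sp <- split_dataset(600, c(0.5, 0.25, 0.25), seed = 3)
  expect_length(sp$train, 300)
  expect_length(sp$val, 150)
  expect_length(sp$test, 150)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_identical(sort(all_idx), 1:600)
  expect_identical(sp, split_dataset(600, c(0.5, 0.25, 0.25), seed = 3))
  expect_false(identical(sp, split_dataset(600, seed = 4)))
  expect_error(split_dataset(3), "at least 4")
  expect_error(split_dataset(600, c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("zero learning rate freezes training; equal seeds reproduce it", {
  set.seed(9)
  imgs <- lapply(1:4, function(i) matrix(runif(32 * 32), 32, 32))
  labs <- lapply(1:4, function(i) matrix(runif(32 * 32) < 0.2, 32, 32))
  model <- build_unet(unet_spec(c(2, 4, 8, 16)), seed = 5)
  h0 <- unet_train(model, imgs[1:3], labs[1:3], imgs[4], labs[4],
    train_config(lr = 0, epochs = 4, seed = 2, patience = Inf)
  )$history
  expect_lt(max(abs(diff(h0$train_loss))), 1e-6)
  expect_lt(max(abs(diff(h0$val_loss))), 1e-12)

  cfg <- train_config(lr = 1e-4, epochs = 3, seed = 2, patience = Inf)
  h1 <- unet_train(model, imgs[1:3], labs[1:3], imgs[4], labs[4], cfg)$history
  h2 <- unet_train(model, imgs[1:3], labs[1:3], imgs[4], labs[4], cfg)$history
  expect_identical(h1, h2)
})

test_that("a single Adam step at lr 1e-4 rarely increases the Dice loss", {
  worse <- 0L
  n_trials <- 20L
  for (s in seq_len(n_trials)) {
    set.seed(s)
    x <- matrix(runif(32 * 32), 32, 32)
    t <- matrix(runif(32 * 32) < 0.3, 32, 32)
    model <- build_unet(unet_spec(c(2, 4, 8, 16)), seed = s)
    g <- octlseg:::unet_grad_single(model, x, t)
    st <- octlseg:::adam_init(model$params)
    upd <- octlseg:::adam_step(model$params, g$grads, st, 1e-4, 1)
    model$params <- upd$params
    after <- octlseg:::unet_grad_single(model, x, t)$loss
    if (after > g$loss) worse <- worse + 1L
  }
  expect_lte(worse / n_trials, 0.05)
})

test_that("the network can overfit a single B-scan (capacity check)", {
  set.seed(14)
  img <- matrix(0.75 + 0.05 * rnorm(64 * 64), 64, 64)
  lab <- matrix(FALSE, 64, 64)
  lab[20:30, 35:45] <- TRUE
  lab[45:52, 10:18] <- TRUE
  img[lab] <- img[lab] - 0.5
  img <- pmin(pmax(img, 0), 1)
  # capacity check, not the production protocol: a larger step size is fine
  model <- build_unet(unet_spec(c(8, 16, 32, 64)), seed = 1)
  model <- unet_train(model, list(img), list(lab), list(img), list(lab),
    train_config(lr = 1e-3, epochs = 200, batch_size = 1, seed = 1, iou_target = 2)
  )
  expect_lt(min(model$history$train_loss), 0.05)
})

test_that("prediction pads to /16, unpads, and breaks ties toward background", {
  model <- build_unet(unet_spec(c(2, 4, 8, 16)), seed = 8)
  arr <- array(rnorm(40 * 3 * 50, 15, 3), dim = c(40, 3, 50))
  vol <- oct_volume(arr, 5.6, c(12, 12), noise_normalized = TRUE)
  m <- unet_predict(model, vol)
  expect_identical(dim(m$mask), dim(arr))
  expect_identical(m$provenance, "dl")
  # manual padding to 16 vs 32 multiples: interior predictions agree
  img <- to_uint8(arr[, 2, ], vmax = quantile(arr, 0.999, names = FALSE)) / 255
  p16 <- pad16(img, 16L)$image
  p32 <- pad16(img, 32L)$image
  m16 <- octlseg:::softmax2(octlseg:::unet_forward(model, p16)$logits) > 0.5
  m32 <- octlseg:::softmax2(octlseg:::unet_forward(model, p32)$logits) > 0.5
  expect_lt(mean(m16[1:40, 1:50] != m32[1:40, 1:50]), 1e-3)
  # a probability of exactly 0.5 is non-vessel (strict >)
  expect_false(any(octlseg:::softmax2(array(0, dim = c(4, 4, 2))) > 0.5))
})
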