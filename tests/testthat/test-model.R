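test_that("relu follows its definition and subgradient", {
  expect_equal(relu(3), 3)
  expect_equal(relu(-2), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu_grad(c(-1, 0, 2)), c(0, 0, 1))
  m <- matrix(c(-1, 2, 0, 5), 2)
  expect_equal(relu(m), matrix(c(0, 2, 0, 5), 2))
})

test_that("channel attention reproduces a hand-computed toy case", {
  # C = 2 channels of 2x2, reduction r = 2; worked by hand:
  #   avg = (2.5, 0.5), max = (4, 2)
  #   W0 %*% avg = 1.125 -> relu -> W1: (1.125, -0.5625)
  #   W0 %*% max = 1.5   -> relu -> W1: (1.5, -0.75)
  #   pre-sigmoid sum = (2.625, -1.3125)
  f <- array(c(1, 3, 2, 4, 0, -1, 1, 2), c(2, 2, 2))
  W0 <- matrix(c(0.5, -0.25), 1, 2)
  W1 <- matrix(c(1, -0.5), 2, 1)
  expect_equal(channel_attention(f, W0, W1),
               stats::plogis(c(2.625, -1.3125)), tolerance = 1e-12)
  # zero weights give the neutral sigma(0) = 0.5 per channel
  expect_equal(channel_attention(f, 0 * W0, 0 * W1), c(0.5, 0.5))
})

test_that("spatial attention reproduces a hand-computed toy case", {
  # single channel 3x3, k = 3, kernel zero except the centre taps:
  # avg-plane centre 1, max-plane centre -0.5; avg = max = f, so the
  # pre-activation is 0.5 * f everywhere
  f <- array(matrix(1:9 / 3, 3, 3), c(3, 3, 1))
  w <- numeric(18); w[5] <- 1; w[14] <- -0.5
  expect_equal(spatial_attention(f, w, b = 0, k = 3),
               stats::plogis(0.5 * f[, , 1]), tolerance = 1e-12)
  # zero kernel and bias -> uniform 0.5 regardless of channel count
  f4 <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_equal(spatial_attention(f4, numeric(18), 0, 3),
               matrix(0.5, 3, 3))
})

test_that("attention modules match loop-based evaluation on random tensors", {
  set.seed(31)
  for (C in c(2, 3)) {
    f <- array(rnorm(4 * 4 * C), c(4, 4, C))
    W0 <- matrix(rnorm(1 * C), 1, C)
    W1 <- matrix(rnorm(C * 1), C, 1)
    expect_equal(channel_attention(f, W0, W1),
                 ref_channel_attention(f, W0, W1), tolerance = 1e-12)
    w <- rnorm(2 * 49); b <- rnorm(1)
    expect_equal(spatial_attention(f, w, b, 7),
                 ref_spatial_attention(f, w, b, 7), tolerance = 1e-12)
    # full block = channel gate then spatial gate, elementwise
    mc <- ref_channel_attention(f, W0, W1)
    fp <- sweep(f, 3, mc, `*`)
    ms <- ref_spatial_attention(fp, w, b, 7)
    expect_equal(cbam_block(f, W0, W1, w, b, 7),
                 sweep(fp, c(1, 2), ms, `*`), tolerance = 1e-12)
  }
})

test_that("zero-parameter CBAM scales the input by exactly 0.25", {
  f <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  out <- cbam_block(f, matrix(0, 1, 3), matrix(0, 3, 1), numeric(98), 0, 7)
  expect_identical(out, 0.25 * f)
  expect_equal(dim(out), dim(f))
})

test_that("same-padded convolution matches a direct stencil computation", {
  set.seed(8)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  w <- matrix(rnorm(3 * 2 * 49), 3, 2 * 49)
  b <- rnorm(3)
  y <- conv2d(x, w, b, k = 7)
  ref <- array(0, c(6, 5, 3))
  for (o in 1:3) for (i in 1:6) for (j in 1:5) {
    acc <- b[o]
    for (c in 1:2) for (dy in 0:6) for (dx in 0:6) {
      si <- i + dy - 3; sj <- j + dx - 3
      if (si >= 1 && si <= 6 && sj >= 1 && sj <= 5)
        acc <- acc + w[o, (c - 1) * 49 + dy * 7 + dx + 1] * x[si, sj, c]
    }
    ref[i, j, o] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  cfg <- model_config(conv_filters = c(2L, 3L), cbam_reduction = 1L,
                      batch_size = 4L, max_epochs = 1L, dropout_rate = 0)
  x <- array(runif(8 * 8 * 6), c(8, 8, 6))
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  p <- mibci:::init_params(cfg, input_size = 8L)
  g <- mibci:::cpp_nn_grad(p, x, y, cfg)
  eps <- 1e-6
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      pp <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- mibci:::cpp_nn_grad(pp, x, y, cfg)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- mibci:::cpp_nn_grad(pp, x, y, cfg)$loss
      expect_equal(g$grads[[nm]][i], (lp - lm) / (2 * eps),
                   tolerance = 1e-5,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
  }
})

test_that("forward pass yields valid, deterministic probabilities", {
  imgs <- small_images("subtract")
  y <- attr(imgs, "labels")
  fit <- cbam_cnn(imgs, y, tiny_model())
  pr <- predict(fit, imgs[, , 1:6], type = "prob")
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-12)
  expect_true(all(pr > 0 & pr < 1))
  expect_identical(pr, predict(fit, imgs[, , 1:6], type = "prob"))
  expect_identical(colnames(pr), c("left", "right"))
  cls <- predict(fit, imgs[, , 1:6])
  expect_true(all(cls %in% c("left", "right")))
  expect_error(predict(fit, matrix(0, 32, 32)), "expects 64 x 64")
  expect_error(cbam_cnn(array(0, c(30, 64, 4)), rep(c("l", "r"), 2),
                        tiny_model()), "square")
})

test_that("an untrained model classifies at chance on balanced data", {
  imgs <- small_images("subtract")
  y <- attr(imgs, "labels")
  cfg <- tiny_model(epochs = 1L)
  cfg$learning_rate <- 0                  # keep the random initialization
  fit <- cbam_cnn(imgs, y, cfg)
  acc <- mean(predict(fit, imgs) == y)
  # binomial band around 0.5 for n = 30 (about 3 sigma)
  expect_gt(acc, 0.2)
  expect_lt(acc, 0.8)
})

test_that("training is seed-reproducible and inert at zero learning rate", {
  imgs <- small_images("subtract")
  y <- attr(imgs, "labels")
  f1 <- cbam_cnn(imgs, y, tiny_model())
  f2 <- cbam_cnn(imgs, y, tiny_model())
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log, f2$log)
  cfg0 <- tiny_model(epochs = 3L)
  cfg0$learning_rate <- 0
  f0 <- cbam_cnn(imgs, y, cfg0)
  set.seed(cfg0$seed)
  expect_equal(f0$params, mibci:::init_params(cfg0, 64L), tolerance = 1e-15)
})

test_that("training separates strong-effect synthetic classes", {
  trials <- cached("acc_trials", simulate_dataset(sim_config(seed = 1L)))
  imgs <- cached("acc_imgs_sub", trials_to_images(trials, "subtract"))
  y <- attr(imgs, "labels")
  cfg <- model_config(conv_filters = c(4L, 8L), cbam_reduction = 4L,
                      batch_size = 8L, max_epochs = 30L, seed = 3L)
  fit <- cbam_cnn(imgs, y, cfg)
  # inference-mode accuracy on the training set (the in-training log
  # is measured under the heavy 0.8 dropout and understates the fit)
  expect_gt(mean(predict(fit, imgs) == y), 0.9)
  # cross-entropy decreases over training
  n <- nrow(fit$log)
  expect_lt(mean(fit$log$loss[(n - 2):n]), mean(fit$log$loss[1:3]))
  expect_error(cbam_cnn(imgs[, , y == "left"], y[y == "left"], cfg),
               "two classes")
})

test_that("model JSON serialization round-trips predictions", {
  imgs <- small_images("subtract")
  fit <- cbam_cnn(imgs, attr(imgs, "labels"), tiny_model())
  path <- withr::local_tempfile(fileext = ".json")
  write_cbam_cnn(fit, path)
  back <- read_cbam_cnn(path)
  expect_equal(predict(back, imgs[, , 1:5], type = "prob"),
               predict(fit, imgs[, , 1:5], type = "prob"),
               tolerance = 1e-12)
})

test_that("model_config enforces its invariants", {
  expect_error(model_config(dropout_rate = 1), "dropout")
  expect_error(model_config(cbam_reduction = 64), "cbam_reduction")
  expect_error(model_config(conv_filters = c(0, 8)), "conv_filters")
  cfg <- model_config(cbam = "first")
  expect_identical(cfg$cbam_blocks, c(TRUE, FALSE))
})
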