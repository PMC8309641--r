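test_that("morlet_cwt matches direct quadrature of the transform integral", {
  fs <- 250
  t <- (0:124) / fs                        # 0.5 s toys
  cfg <- cwt_config(freqs = c(8, 10, 14, 21, 30))
  for (x in list(sin(2 * pi * 10 * t),
                 sin(2 * pi * 9 * t) + 0.5 * cos(2 * pi * 24 * t),
                 exp(-((t - 0.25) / 0.08)^2) * sin(2 * pi * 20 * t))) {
    W <- morlet_cwt(x, fs, cfg)
    O <- quadrature_cwt(x, fs, cfg$freqs)
    expect_lt(max(Mod(W - O)) / max(Mod(O)), 1e-3)
  }
})

test_that("the power ridge localizes pure tones on the frequency axis", {
  # the transform's |a|^(-1/2) normalization biases the power ridge of
  # a tone down by roughly f/(2 omega0^2); on the 0.5 Hz grid that is
  # at most one row, and the quadrature oracle places the ridge on
  # exactly the same row as the implementation
  fs <- 250
  t <- (0:(2 * fs - 1)) / fs
  cfg <- cwt_config()                      # 8-30 Hz in 0.5 Hz steps
  for (f0 in c(8, 10.5, 17, 24, 30)) {
    W <- morlet_cwt(sin(2 * pi * f0 * t), fs, cfg)
    ridge <- cfg$freqs[which.max(rowMeans(Mod(W)^2))]
    expect_lte(abs(ridge - f0), 0.5)
  }
  # oracle agreement on the ridge row, at a coarse grid for speed
  coarse <- cwt_config(freqs = seq(20, 30, 0.5))
  x <- sin(2 * pi * 28 * (0:299) / fs)
  W <- morlet_cwt(x, fs, coarse)
  O <- quadrature_cwt(x, fs, coarse$freqs)
  expect_equal(which.max(rowMeans(Mod(W)^2)),
               which.max(rowMeans(Mod(O)^2)))
})

test_that("the transform is linear and maps zero to zero", {
  fs <- 250
  x <- sin(2 * pi * 12 * (0:499) / fs)
  cfg <- cwt_config(freqs = c(10, 12, 20))
  W <- morlet_cwt(x, fs, cfg)
  expect_equal(morlet_cwt(3.5 * x, fs, cfg)[, ], 3.5 * W[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(Mod(morlet_cwt(numeric(500), fs, cfg))), 0)
  expect_error(morlet_cwt(x, fs, cwt_config(freqs = c(10, 130))), "Nyquist")
})

test_that("a temporally confined burst stays localized within the wavelet width", {
  fs <- 250
  t <- (0:(4 * fs - 1)) / fs
  t1 <- 1.5; t2 <- 2.5; f0 <- 15
  x <- ifelse(t >= t1 & t <= t2, sin(2 * pi * f0 * t), 0)
  cfg <- cwt_config(freqs = c(10, 15, 25))
  W <- morlet_cwt(x, fs, cfg)
  p <- Mod(W[2, ])^2
  delta <- attr(W, "coi")[2]               # temporal half-width at 15 Hz
  inside <- t >= t1 - delta & t <= t2 + delta
  expect_gt(sum(p[inside]) / sum(p), 0.9)
})

test_that("effective temporal width shrinks as frequency grows", {
  W <- morlet_cwt(sin(2 * pi * 10 * (0:499) / 250), 250, cwt_config())
  expect_true(all(diff(attr(W, "coi")) < 0))
})

test_that("power maps are non-negative and transform-monotone", {
  x <- sin(2 * pi * 10 * (0:499) / 250) + rnorm(500, 0, 0.1)
  W <- morlet_cwt(x, 250, cwt_config(freqs = c(8, 10, 12)))
  lin <- tf_power(W, channel = "C3")
  lg <- tf_power(W, channel = "C3", power_transform = "log")
  expect_true(all(lin$power >= 0))
  expect_equal(which.max(lin$power), which.max(lg$power))
  expect_equal(dim(lin$power), c(3L, 500L))
  z <- tf_power(morlet_cwt(numeric(500), 250, cwt_config(freqs = c(8, 10, 12))),
                channel = "C4")
  expect_equal(max(z$power), 0)
  expect_error(tf_power(W, freqs = c(1, 2)), "axis")
})

test_that("bilinear resize agrees with a loop-based reference", {
  ref_resize <- function(m, nr, nc) {
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      y <- min(max((i - 0.5) * nrow(m) / nr + 0.5, 1), nrow(m))
      x <- min(max((j - 0.5) * ncol(m) / nc + 0.5, 1), ncol(m))
      y0 <- min(floor(y), nrow(m) - 1); x0 <- min(floor(x), ncol(m) - 1)
      wy <- y - y0; wx <- x - x0
      out[i, j] <- m[y0, x0] * (1 - wy) * (1 - wx) +
        m[y0 + 1, x0] * wy * (1 - wx) +
        m[y0, x0 + 1] * (1 - wy) * wx +
        m[y0 + 1, x0 + 1] * wy * wx
    }
    out
  }
  set.seed(4)
  for (dims in list(c(5, 9, 8, 8), c(45, 200, 64, 64), c(3, 3, 10, 7))) {
    m <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    expect_equal(resize_bilinear(m, dims[3], dims[4]),
                 ref_resize(m, dims[3], dims[4]), tolerance = 1e-12)
  }
})

test_that("classifier images are 64x64 in [0,1] with sane degenerate cases", {
  m <- matrix(rnorm(45 * 1750), 45, 1750)
  img <- to_image(m)
  expect_equal(dim(img), c(64L, 64L))
  expect_gte(min(img), 0); expect_lte(max(img), 1)
  # constant input -> neutral 0.5
  expect_equal(unclass(to_image(matrix(3, 10, 10)))[, ],
               matrix(0.5, 64, 64), ignore_attr = TRUE)
  # hot pixel lands at the geometrically corresponding location
  hot <- matrix(0, 45, 200); hot[30, 120] <- 1
  amax <- which(to_image(hot) == max(to_image(hot)), arr.ind = TRUE)[1, ]
  expect_equal(unname(amax["row"]), round((30 - 0.5) * 64 / 45 + 0.5),
               tolerance = 1)
  expect_equal(unname(amax["col"]), round((120 - 0.5) * 64 / 200 + 0.5),
               tolerance = 1)
  expect_error(to_image(matrix(1, 1, 5)), "at least 2")
})

test_that("trial maps carry matching axes and channel tags", {
  maps <- trial_tf_maps(small_trials()[[1]], cwt_config(freqs = seq(8, 30, 2)))
  expect_identical(maps$C3$channel, "C3")
  expect_identical(maps$C4$channel, "C4")
  expect_identical(maps$C3$freqs, maps$C4$freqs)
  expect_equal(length(maps$C3$times), ncol(small_trials()[[1]]$data))
})
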