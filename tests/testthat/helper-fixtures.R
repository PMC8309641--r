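# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache))
    assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# small simulated dataset (30 trials) and its images
small_trials <- function() cached("small_trials", {
  simulate_dataset(sim_config(n_trials_per_class = 15, seed = 7))
})

small_images <- function(representation = "subtract") {
  cached(paste0("imgs_", representation), {
    trials_to_images(small_trials(), representation)
  })
}

# fraction of total periodogram power of `x` inside [lo, hi] Hz,
# and absolute band power -- an independent spectral oracle (plain
# FFT periodogram, no package code)
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  sum(p[keep & f >= lo & f <= hi])
}

# nearest-centroid classifier on flattened images: a cheap stand-in
# model for exercising the cross-validation machinery
centroid_fit_predict <- function(train_x, train_y, test_x, fold_seed) {
  Xtr <- t(apply(train_x, 3, c))
  Xte <- t(apply(test_x, 3, c))
  classes <- sort(unique(train_y))
  d <- sapply(classes, function(cl) {
    mu <- colMeans(Xtr[train_y == cl, , drop = FALSE])
    colSums((t(Xte) - mu)^2)
  })
  classes[max.col(-matrix(d, ncol = length(classes)))]
}

# tiny model configuration for fast structural tests
tiny_model <- function(epochs = 2L, cbam = "both") {
  model_config(conv_filters = c(2L, 4L), cbam_reduction = 2L,
               batch_size = 4L, max_epochs = epochs, cbam = cbam,
               seed = 5L)
}
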