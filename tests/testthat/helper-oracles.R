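# Independent reference implementations used as oracles by both the
# unit tests and the acceptance suite.  They are deliberately written
# as plain loops/quadrature, sharing no code with the package.

# direct numerical quadrature of the wavelet transform integral
# W(a, tau) = |a|^{-1/2} int x(t) psi*((t - tau)/a) dt, with the same
# +/- 5 scale support truncation as the implementation
quadrature_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x); dt <- 1 / fs
  tt <- (seq_len(n) - 1) * dt
  psi <- function(u) pi^(-0.25) * exp(1i * omega0 * u - u^2 / 2)
  out <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    a <- omega0 / (2 * pi * freqs[i])
    for (k in seq_len(n)) {
      u <- (tt - tt[k]) / a
      keep <- abs(u) <= 5
      out[i, k] <- sum(x[keep] * Conj(psi(u[keep]))) * dt / sqrt(a)
    }
  }
  out
}

# channel attention: sigmoid(MLP(avgpool) + MLP(maxpool)), shared MLP
ref_channel_attention <- function(f, W0, W1) {
  C <- dim(f)[3]
  branch <- function(v) W1 %*% pmax(W0 %*% v, 0)
  avg <- sapply(seq_len(C), function(c) mean(f[, , c]))
  mx <- sapply(seq_len(C), function(c) max(f[, , c]))
  stats::plogis(as.numeric(branch(avg) + branch(mx)))
}

# spatial attention: sigmoid(conv_k([channel-avg; channel-max]))
ref_spatial_attention <- function(f, w, b, k) {
  H <- dim(f)[1]; W <- dim(f)[2]; p <- k %/% 2
  planes <- list(apply(f, c(1, 2), mean), apply(f, c(1, 2), max))
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- b
    for (cc in 1:2) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
      si <- i + dy - p; sj <- j + dx - p
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        acc <- acc + w[(cc - 1) * k * k + dy * k + dx + 1] *
          planes[[cc]][si, sj]
    }
    out[i, j] <- stats::plogis(acc)
  }
  out
}
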