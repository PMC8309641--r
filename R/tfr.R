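#' Configuration of the Morlet continuous wavelet transform
#'
#' @param freqs Strictly increasing vector of analysis frequencies in
#'   Hz.  The default, 8-30 Hz in 0.5 Hz steps (45 rows), spans the mu
#'   and beta rhythms.
#' @param omega0 Dimensionless centre parameter of the Morlet mother
#'   wavelet.  6 is the standard trade-off between time and frequency
#'   resolution.
#' @param power_transform `"linear"` for \eqn{|W|^2} or `"log"` for
#'   \eqn{\log(1 + |W|^2)}.
#' @return An object of class `"cwt_config"`.
#' @export
cwt_config <- function(freqs = seq(8, 30, by = 0.5), omega0 = 6,
                       power_transform = c("linear", "log")) {
  power_transform <- match.arg(power_transform)
  freqs <- as.numeric(freqs)
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(freqs <= 0)) stop("freqs must be positive")
  structure(list(freqs = freqs, omega0 = omega0,
                 power_transform = power_transform),
            class = "cwt_config")
}

# Morlet mother wavelet (subtracted correction term omitted: for
# omega0 >= 5 it is < 1e-5 and irrelevant at this precision).
morlet_psi <- function(t, omega0) {
  pi^(-0.25) * exp(1i * omega0 * t) * exp(-t^2 / 2)
}

# scale (seconds) at which the Morlet wavelet's carrier matches f Hz
morlet_scale <- function(f, omega0) omega0 / (2 * pi * f)

#' Morlet continuous wavelet transform
#'
#' Computes \eqn{W(a,\tau) = |a|^{-1/2} \int x(t)\,
#' \psi^*((t-\tau)/a)\, dt} with the Morlet mother wavelet
#' \eqn{\psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2}}, at the
#' scales \eqn{a(f) = \omega_0 / (2\pi f)} corresponding to
#' `config$freqs`.  The integral is evaluated as a Riemann sum, which
#' is carried out by FFT convolution per frequency; the wavelet is
#' truncated where its Gaussian envelope falls below
#' \eqn{e^{-12.5}} (|t/a| > 5).  The signal is implicitly
#' zero-padded, so coefficients within one temporal half-width
#' (`attr(, "coi")`, seconds per row) of either edge are damped —
#' the cone of influence.
#'
#' @param x Numeric vector, one channel of one trial.
#' @param sampling_rate Sampling frequency, Hz.
#' @param config A [cwt_config()].
#' @return Complex matrix of coefficients, `length(freqs)` x
#'   `length(x)`; attributes `freqs`, `times`, and `coi`.
#' @export
morlet_cwt <- function(x, sampling_rate, config = cwt_config()) {
  nyq <- sampling_rate / 2
  if (any(config$freqs >= nyq))
    stop("analysis frequencies must lie below the Nyquist frequency")
  n <- length(x)
  dt <- 1 / sampling_rate
  # longest wavelet support: 5 scales either side at the lowest freq
  max_half <- ceiling(5 * morlet_scale(min(config$freqs), config$omega0) / dt)
  # the segment must at least span two e-folding half-widths of the
  # widest wavelet, or every coefficient sits inside the cone of influence
  if (n * dt < 2 * sqrt(2) * morlet_scale(min(config$freqs), config$omega0))
    stop("signal too short for the lowest analysis frequency")
  nfft <- stats::nextn(n + 2 * max_half + 1, 2)
  fx <- stats::fft(c(x, numeric(nfft - n)))
  out <- matrix(0i, nrow = length(config$freqs), ncol = n)
  coi <- numeric(length(config$freqs))
  for (i in seq_along(config$freqs)) {
    a <- morlet_scale(config$freqs[i], config$omega0)
    half <- ceiling(5 * a / dt)
    tk <- (-half:half) * dt
    # correlation kernel: psi*((t_k)/a) / sqrt(a), times dt for the sum;
    # reversed so that FFT convolution realizes the correlation
    kern <- rev(Conj(morlet_psi(tk / a, config$omega0)) / sqrt(a) * dt)
    fk <- stats::fft(c(kern[(half + 1):(2 * half + 1)],
                       numeric(nfft - (2 * half + 1)),
                       kern[1:half]))
    conv <- stats::fft(fx * fk, inverse = TRUE) / nfft
    out[i, ] <- conv[1:n]
    coi[i] <- sqrt(2) * a
  }
  structure(out, freqs = config$freqs,
            times = (seq_len(n) - 1) * dt, coi = coi)
}

#' Time-frequency power map of one channel
#'
#' @param coeffs Complex coefficient matrix from [morlet_cwt()], or
#'   any matrix with matching axes.
#' @param freqs,times Axes (taken from `coeffs` attributes when
#'   omitted).
#' @param channel `"C3"` or `"C4"`.
#' @param power_transform `"linear"` (\eqn{|W|^2}) or `"log"`
#'   (\eqn{\log(1+|W|^2)}).
#' @return An object of class `"tf_map"` with fields `power`, `freqs`,
#'   `times`, `channel`.
#' @export
tf_power <- function(coeffs, freqs = attr(coeffs, "freqs"),
                     times = attr(coeffs, "times"),
                     channel = c("C3", "C4"),
                     power_transform = c("linear", "log")) {
  channel <- match.arg(channel)
  power_transform <- match.arg(power_transform)
  if (is.null(freqs) || is.null(times))
    stop("freqs and times must be supplied or present as attributes")
  if (nrow(coeffs) != length(freqs) || ncol(coeffs) != length(times))
    stop("axis lengths do not match the coefficient matrix")
  p <- Mod(coeffs)^2
  if (power_transform == "log") p <- log1p(p)
  structure(list(power = unname(p), freqs = freqs, times = times,
                 channel = channel),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %s: %d freqs (%.1f-%.1f Hz) x %d times (%.2f-%.2f s)\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Bilinear image resize
#'
#' Resamples a matrix to a new shape by bilinear interpolation with
#' pixel-centre sampling (output pixel centres are mapped uniformly
#' onto input pixel centres, edges clamped).  Because interpolation
#' weights are convex, the output range never exceeds the input range.
#'
#' @param m Numeric matrix with at least 2 rows and 2 columns.
#' @param nrow_out,ncol_out Output dimensions.
#' @return A `nrow_out` x `ncol_out` matrix.
#' @export
resize_bilinear <- function(m, nrow_out = 64, ncol_out = 64) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("input must have at least 2 rows and 2 columns")
  map_axis <- function(n_out, n_in) {
    # pixel-centre mapping: output centre i+0.5 -> input coordinate
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - 1L)
    list(lo = as.integer(lo), w = pos - lo)
  }
  ry <- map_axis(nrow_out, nrow(m))
  rx <- map_axis(ncol_out, ncol(m))
  top <- m[ry$lo, rx$lo, drop = FALSE] * (1 - rx$w)[col(matrix(0, nrow_out, ncol_out))] +
         m[ry$lo, rx$lo + 1L, drop = FALSE] * rx$w[col(matrix(0, nrow_out, ncol_out))]
  bot <- m[ry$lo + 1L, rx$lo, drop = FALSE] * (1 - rx$w)[col(matrix(0, nrow_out, ncol_out))] +
         m[ry$lo + 1L, rx$lo + 1L, drop = FALSE] * rx$w[col(matrix(0, nrow_out, ncol_out))]
  top * (1 - ry$w) + bot * ry$w
}

#' Build a 64 x 64 classifier image from a power map
#'
#' Bilinearly resizes the map to `out_size` x `out_size`, then min-max
#' scales it to `[0, 1]`.  A constant input has no contrast to scale
#' and maps to the neutral value 0.5 everywhere.
#'
#' @param map A [tf_power()] map or a plain numeric matrix.
#' @param out_size Output side length (the classifier expects 64).
#' @param kind Image kind recorded on the result.
#' @return An object of class `"classifier_image"`: a matrix in
#'   `[0, 1]` with a `kind` attribute.
#' @export
to_image <- function(map, out_size = 64, kind = "stacked") {
  m <- if (inherits(map, "tf_map")) map$power else as.matrix(map)
  r <- resize_bilinear(m, out_size, out_size)
  rng <- range(r)
  px <- if (diff(rng) == 0) matrix(0.5, out_size, out_size)
        else (r - rng[1]) / diff(rng)
  classifier_image(px, kind)
}

#' Construct/validate a classifier image
#' @param pixels 64 x 64 numeric matrix with values in `[0, 1]`.
#' @param kind `"subtracted"` or `"stacked"`.
#' @return The validated `"classifier_image"` object.
#' @export
classifier_image <- function(pixels, kind = c("subtracted", "stacked")) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels))
    stop("classifier images must be square")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixel values must lie in [0, 1]")
  structure(pmin(pmax(pixels, 0), 1), kind = kind,
            class = c("classifier_image", "matrix", "array"))
}

#' @export
print.classifier_image <- function(x, ...) {
  cat(sprintf("<classifier_image> %dx%d (%s), range [%.3f, %.3f]\n",
              nrow(x), ncol(x), attr(x, "kind"), min(x), max(x)))
  invisible(x)
}

#' Time-frequency maps of both channels of a trial
#'
#' Convenience wrapper: runs [morlet_cwt()] and [tf_power()] on the C3
#' and C4 rows of a trial.
#'
#' @param trial An [mi_trial()].
#' @param config A [cwt_config()].
#' @return List with elements `C3` and `C4`, each a [tf_power()] map.
#' @export
trial_tf_maps <- function(trial, config = cwt_config()) {
  mk <- function(row, ch) {
    co <- morlet_cwt(trial$data[row, ], trial$sampling_rate, config)
    tf_power(co, channel = ch, power_transform = config$power_transform)
  }
  list(C3 = mk(1L, "C3"), C4 = mk(2L, "C4"))
}

#' Export a power map or classifier image as a PNG
#'
#' @param x A [tf_power()] map, [classifier_image()], or matrix.
#' @param path Output file path.
#' @param colormap `"gray"` or `"viridis"`-like false colour
#'   (`grDevices::hcl.colors`).
#' @return Invisibly, `path`.
#' @export
export_png <- function(x, path, colormap = c("gray", "viridis")) {
  colormap <- match.arg(colormap)
  m <- if (inherits(x, "tf_map")) x$power else as.matrix(x)
  rng <- range(m)
  u <- if (diff(rng) == 0) matrix(0.5, nrow(m), ncol(m))
       else (m - rng[1]) / diff(rng)
  # flip so low frequencies / first rows appear at the bottom
  u <- u[rev(seq_len(nrow(u))), , drop = FALSE]
  if (colormap == "gray") {
    png::writePNG(u, path)
  } else {
    pal <- grDevices::hcl.colors(256, "viridis")
    idx <- pmin(255L, as.integer(u * 255)) + 1L
    rgb <- grDevices::col2rgb(pal[idx]) / 255
    arr <- array(0, c(nrow(u), ncol(u), 3))
    for (k in 1:3) arr[, , k] <- matrix(rgb[k, ], nrow(u), ncol(u))
    png::writePNG(arr, path)
  }
  invisible(path)
}
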