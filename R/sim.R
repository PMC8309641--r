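#' Configuration for the synthetic motor-imagery trial simulator
#'
#' Defines the timing, spectral, and effect-size parameters of the
#' two-channel (C3, C4) ERD/ERS simulator.  Each simulated trial is a
#' cue-locked segment: a pre-cue baseline followed by a motor-imagery
#' (MI) window during which mu-band (8-13 Hz) and beta-band (14-30 Hz)
#' oscillatory power is attenuated on one channel (event-related
#' desynchronization, ERD) and boosted on the other (event-related
#' synchronization, ERS), on top of a 1/f "pink" background.
#'
#' The laterality convention is fixed: for a *left*-hand trial the C3
#' band power rises and the C4 band power falls during the MI window;
#' for a *right*-hand trial the roles are mirrored.  Downstream code
#' (in particular [image_subtract()]) relies on this convention, so it
#' is part of the contract, not a free choice.
#'
#' @param sampling_rate Sampling frequency in Hz.
#' @param trial_duration Trial length in seconds.
#' @param cue_onset Cue time in seconds relative to trial start.
#' @param mi_duration Length of the motor-imagery window in seconds.
#' @param mu_band,beta_band Two-element Hz intervals of the mu and
#'   beta rhythms.
#' @param erd_depth Fractional band-power attenuation in `[0, 1]` on
#'   the energy-falling channel during the MI window (0 = no ERD,
#'   1 = complete suppression).
#' @param ers_gain Multiplicative band-power boost (>= 1) on the
#'   energy-rising channel during the MI window.
#' @param noise_scale Standard deviation of the 1/f background noise,
#'   in the same arbitrary amplitude units as the unit-amplitude mu
#'   oscillation.
#' @param n_trials_per_class Number of trials per class generated by
#'   [simulate_dataset()].
#' @param seed Integer seed used by [simulate_dataset()].
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_trials_per_class = 5)
#' trials <- simulate_dataset(cfg)
#' length(trials)
#' @export
sim_config <- function(sampling_rate = 250,
                       trial_duration = 8,
                       cue_onset = 3,
                       mi_duration = 4,
                       mu_band = c(8, 13),
                       beta_band = c(14, 30),
                       erd_depth = 0.7,
                       ers_gain = 1.5,
                       noise_scale = 0.5,
                       n_trials_per_class = 60,
                       seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate,
              trial_duration = trial_duration,
              cue_onset = cue_onset,
              mi_duration = mi_duration,
              mu_band = as.numeric(mu_band),
              beta_band = as.numeric(beta_band),
              erd_depth = erd_depth,
              ers_gain = ers_gain,
              noise_scale = noise_scale,
              n_trials_per_class = as.integer(n_trials_per_class),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(mu_band) != 2L || mu_band[1] >= mu_band[2])
      stop("invalid mu_band: lower edge must be below upper edge")
    if (length(beta_band) != 2L || beta_band[1] >= beta_band[2])
      stop("invalid beta_band: lower edge must be below upper edge")
    if (cue_onset + mi_duration > trial_duration)
      stop("cue_onset + mi_duration must not exceed trial_duration")
    if (erd_depth < 0 || erd_depth > 1)
      stop("erd_depth must be in [0, 1]")
    if (ers_gain < 1)
      stop("ers_gain must be >= 1")
    if (sampling_rate <= 2 * beta_band[2])
      stop("sampling_rate must exceed twice the upper beta edge")
    if (noise_scale < 0) stop("noise_scale must be non-negative")
  })
  invisible(cfg)
}

#' Construct an epoched two-channel trial
#'
#' Container for one fixed-length motor-imagery segment.  Channel
#' order is fixed as C3 then C4; this ordering is relied upon by
#' [image_subtract()] and must not be permuted.
#'
#' @param data Numeric 2 x n_samples matrix, rows C3 and C4.
#' @param sampling_rate Sampling frequency, Hz.
#' @param cue_onset Cue time in seconds relative to segment start.
#' @param label `"left"` or `"right"` (or `NA` for unlabeled data).
#' @return An object of class `"mi_trial"`.
#' @export
mi_trial <- function(data, sampling_rate, cue_onset, label = NA_character_) {
  data <- unname(as.matrix(data))
  if (nrow(data) != 2L)
    stop("a trial must have exactly two channels (C3, C4)")
  if (!is.na(label) && !label %in% c("left", "right"))
    stop("label must be 'left', 'right' or NA")
  structure(list(data = data,
                 sampling_rate = sampling_rate,
                 cue_onset = cue_onset,
                 label = label,
                 channels = c("C3", "C4")),
            class = "mi_trial")
}

#' @export
print.mi_trial <- function(x, ...) {
  cat(sprintf("<mi_trial> %s, %d samples @ %g Hz (%.2f s), cue at %g s\n",
              ifelse(is.na(x$label), "unlabeled", x$label),
              ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, x$cue_onset))
  invisible(x)
}

# 1/f (pink) noise by spectral shaping of white Gaussian noise:
# the rFFT of white noise is scaled by 1/sqrt(f) (power ~ 1/f), the DC
# term is zeroed, and the result is transformed back and standardized
# to unit variance before applying `scale`.
pink_noise <- function(n, scale) {
  if (scale == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  # frequency index of each FFT bin (two-sided); bin 1 is DC
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)           # fold to one-sided frequency index
  amp <- c(0, 1 / sqrt(k[-1]))
  shaped <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  scale * shaped / stats::sd(shaped)
}

# Raised-cosine step from 0 to 1 centred transitions of width `ramp`
# seconds at t0 (up) and t1 (down); returns the modulation envelope
# that interpolates amplitude between 1 (baseline) and `target`.
mi_envelope <- function(t, t0, t1, target, ramp = 0.25) {
  env <- numeric(length(t))
  up <- (t - t0) / ramp
  dn <- (t1 - t) / ramp
  frac <- pmin(1, pmax(0, pmin(up, dn)))
  frac <- 0.5 - 0.5 * cos(pi * frac)      # smooth 0 -> 1
  1 + (target - 1) * frac
}

# One band-limited oscillatory component: amplitude-modulated sinusoid
# with random phase and a random centre frequency inside the band.
band_oscillation <- function(t, band, base_amp, amp_target, cue0, cue1) {
  f0 <- mean(band) + stats::runif(1, -1, 1) * min(diff(band) / 4, 2)
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- base_amp * stats::runif(1, 0.8, 1.2)
  env <- mi_envelope(t, cue0, cue1, amp_target)
  amp * env * sin(2 * pi * f0 * t + phase)
}

#' Simulate one labeled motor-imagery trial
#'
#' Generates a two-channel (C3, C4) segment containing unit-scale mu
#' and beta oscillations over 1/f noise.  During the MI window the
#' oscillation *power* on the energy-rising channel is multiplied by
#' `ers_gain` and on the energy-falling channel by `1 - erd_depth`
#' (amplitudes scale with the square root).  For `label = "left"` C3
#' rises and C4 falls; for `"right"` the channels are mirrored.
#'
#' The caller controls the random state: wrap calls in `set.seed()` or
#' use [simulate_dataset()] for seeded batches.
#'
#' @param config A [sim_config()].
#' @param label `"left"` or `"right"`.
#' @return An [mi_trial()].
#' @export
simulate_trial <- function(config, label = c("left", "right")) {
  label <- match.arg(label)
  validate_sim_config(config)
  fs <- config$sampling_rate
  n <- round(fs * config$trial_duration)
  t <- (seq_len(n) - 1) / fs
  cue0 <- config$cue_onset
  cue1 <- config$cue_onset + config$mi_duration

  # power targets -> amplitude targets
  rise <- sqrt(config$ers_gain)
  fall <- sqrt(1 - config$erd_depth)
  # left: C3 rises / C4 falls; right: mirrored
  targets <- if (label == "left") c(rise, fall) else c(fall, rise)

  data <- matrix(0, nrow = 2L, ncol = n)
  for (ch in 1:2) {
    osc <- band_oscillation(t, config$mu_band, 1.0, targets[ch], cue0, cue1) +
           band_oscillation(t, config$beta_band, 0.5, targets[ch], cue0, cue1)
    data[ch, ] <- osc + pink_noise(n, config$noise_scale)
  }
  mi_trial(data, fs, cue0, label)
}

#' Simulate a balanced, shuffled motor-imagery dataset
#'
#' Draws `n_trials_per_class` trials of each class and shuffles their
#' order, all reproducibly from `config$seed`.  The caller's random
#' state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A list of [mi_trial()] objects of length
#'   `2 * n_trials_per_class`, with a `"labels"` attribute.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  if (config$n_trials_per_class < 1L)
    stop("n_trials_per_class must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  labels <- rep(c("left", "right"), each = config$n_trials_per_class)
  trials <- lapply(labels, function(lb) simulate_trial(config, lb))
  ord <- sample(length(trials))
  trials <- trials[ord]
  attr(trials, "labels") <- labels[ord]
  class(trials) <- "mi_dataset"
  trials
}

#' @export
print.mi_dataset <- function(x, ...) {
  lb <- vapply(x, function(tr) tr$label, character(1))
  cat(sprintf("<mi_dataset> %d trials (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(lb)), table(lb)),
                    collapse = ", ")))
  invisible(x)
}

#' Labels of a dataset
#' @param dataset A list of [mi_trial()] objects.
#' @return Character vector of trial labels.
#' @export
trial_labels <- function(dataset) {
  vapply(dataset, function(tr) tr$label, character(1))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes one CSV per trial (`trial_<i>.csv`: header `C3,C4`, one
#' sample per row), an `events.csv` sidecar (`onset_sample,label`, the
#' cue sample of each trial), and a two-column `labels.tsv`
#' (`trial_index`, `label`).
#'
#' @param dataset A list of [mi_trial()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of trial file paths.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(dataset))
  ev <- data.frame(onset_sample = integer(length(dataset)),
                   label = character(length(dataset)))
  for (i in seq_along(dataset)) {
    tr <- dataset[[i]]
    paths[i] <- file.path(dir, sprintf("trial_%03d.csv", i))
    df <- as.data.frame(t(tr$data))
    names(df) <- tr$channels
    utils::write.csv(df, paths[i], row.names = FALSE)
    ev$onset_sample[i] <- round(tr$cue_onset * tr$sampling_rate) + 1L
    ev$label[i] <- tr$label
  }
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.table(data.frame(trial_index = seq_along(dataset),
                                label = ev$label),
                     file.path(dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a dataset written by [write_dataset_csv()]
#' @param dir Directory containing `trial_*.csv`, `events.csv`.
#' @param sampling_rate Sampling rate in Hz of the stored signals.
#' @return A list of [mi_trial()] objects.
#' @export
read_dataset_csv <- function(dir, sampling_rate = 250) {
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) != nrow(ev))
    stop("events.csv does not match the number of trial files")
  trials <- vector("list", length(files))
  for (i in seq_along(files)) {
    df <- utils::read.csv(files[i])
    trials[[i]] <- mi_trial(t(as.matrix(df[, c("C3", "C4")])),
                            sampling_rate,
                            (ev$onset_sample[i] - 1L) / sampling_rate,
                            ev$label[i])
  }
  attr(trials, "labels") <- ev$label
  class(trials) <- "mi_dataset"
  trials
}
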