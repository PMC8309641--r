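#' Construct a raw multichannel recording
#'
#' @param data Numeric n_channels x n_samples matrix of amplitudes.
#' @param channel_names Character vector naming the rows of `data`.
#' @param sampling_rate Sampling frequency, Hz.
#' @param events Data frame with columns `onset_sample` (1-based
#'   sample index of each cue) and `label` (`"left"`/`"right"`).
#' @return An object of class `"raw_recording"`.
#' @export
raw_recording <- function(data, channel_names, sampling_rate,
                          events = data.frame(onset_sample = integer(),
                                              label = character())) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names))
    stop("channel_names length must equal the number of data rows")
  events <- as.data.frame(events)
  if (!all(c("onset_sample", "label") %in% names(events)))
    stop("events must have columns onset_sample and label")
  if (nrow(events)) {
    if (is.unsorted(events$onset_sample, strictly = TRUE))
      stop("event onsets must be strictly increasing")
    if (any(events$onset_sample < 1L) ||
        any(events$onset_sample > ncol(data)))
      stop("event onsets must lie within the recording")
  }
  structure(list(data = data,
                 channel_names = as.character(channel_names),
                 sampling_rate = sampling_rate,
                 events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels (%s), %d samples @ %g Hz, %d events\n",
              nrow(x$data), paste(x$channel_names, collapse = ", "),
              ncol(x$data), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Subset the channels of a recording
#'
#' Returns a copy of `rec` containing only the requested channels, in
#' the requested order.  Events are unchanged.
#'
#' @param rec A [raw_recording()].
#' @param names Channel names to keep (typically `c("C3", "C4")`).
#' @return A [raw_recording()] with `length(names)` channels.
#' @export
select_channels <- function(rec, names) {
  idx <- match(names, rec$channel_names)
  if (anyNA(idx))
    stop(sprintf("channel(s) %s not found; available: %s",
                 paste(names[is.na(idx)], collapse = ", "),
                 paste(rec$channel_names, collapse = ", ")))
  raw_recording(rec$data[idx, , drop = FALSE], rec$channel_names[idx],
                rec$sampling_rate, rec$events)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the net phase response is zero and cue
#' alignment is preserved.  The motor-imagery pipeline uses 8-30 Hz,
#' covering the mu and beta rhythms.
#'
#' @param rec A [raw_recording()].
#' @param low,high Band edges in Hz; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param order Butterworth order of the one-pass prototype.
#' @return The filtered [raw_recording()], same length and events.
#' @export
bandpass_filter <- function(rec, low = 8, high = 30, order = 4) {
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filt <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  raw_recording(filt, rec$channel_names, rec$sampling_rate, rec$events)
}

#' Extract cue-locked epochs from a recording
#'
#' Cuts one fixed-length segment per event, spanning `window` seconds
#' relative to the cue.  The default window, -3 s to +4 s, keeps a
#' 3-s pre-cue baseline and the full 4-s motor-imagery period.
#'
#' @param rec A two-channel (C3, C4) [raw_recording()] with events.
#' @param window Two-element numeric, seconds relative to the cue.
#' @return A list of [mi_trial()] objects (class `"mi_dataset"`).
#' @export
epoch_trials <- function(rec, window = c(-3, 4)) {
  if (nrow(rec$data) != 2L)
    stop("epoch_trials expects a two-channel (C3, C4) recording; ",
         "use select_channels() first")
  fs <- rec$sampling_rate
  i0 <- round(window[1] * fs)
  i1 <- round(window[2] * fs) - 1L
  trials <- vector("list", nrow(rec$events))
  for (k in seq_len(nrow(rec$events))) {
    on <- rec$events$onset_sample[k]
    lo <- on + i0
    hi <- on + i1
    if (lo < 1L || hi > ncol(rec$data))
      stop(sprintf("event %d (onset sample %d) window exceeds the recording",
                   k, on))
    trials[[k]] <- mi_trial(rec$data[, lo:hi, drop = FALSE], fs,
                            cue_onset = -window[1],
                            label = rec$events$label[k])
  }
  attr(trials, "labels") <- rec$events$label
  class(trials) <- "mi_dataset"
  trials
}

#' Baseline-correct a trial
#'
#' Subtracts from each channel its mean over the baseline window, so
#' slow drifts do not offset the epoch.  The default window is the
#' whole pre-cue segment.
#'
#' @param trial An [mi_trial()].
#' @param baseline_window Two-element numeric, seconds relative to the
#'   segment start; defaults to `c(0, cue_onset)`.
#' @return The corrected [mi_trial()].
#' @export
baseline_correct <- function(trial, baseline_window = NULL) {
  if (is.null(baseline_window))
    baseline_window <- c(0, trial$cue_onset)
  fs <- trial$sampling_rate
  lo <- max(1L, round(baseline_window[1] * fs) + 1L)
  hi <- min(ncol(trial$data), round(baseline_window[2] * fs))
  if (hi < lo) stop("empty baseline window")
  mu <- rowMeans(trial$data[, lo:hi, drop = FALSE])
  mi_trial(trial$data - mu, fs, trial$cue_onset, trial$label)
}

#' Full preprocessing pipeline
#'
#' select C3/C4 -> 8-30 Hz zero-phase band-pass -> epoch -> baseline
#' correction, the standard order for this pipeline.
#'
#' @param rec A [raw_recording()] containing channels C3 and C4.
#' @param low,high Band-pass edges, Hz.
#' @param window Epoch window in seconds relative to the cue.
#' @return A list of preprocessed [mi_trial()] objects.
#' @export
preprocess_recording <- function(rec, low = 8, high = 30,
                                 window = c(-3, 4)) {
  rec <- select_channels(rec, c("C3", "C4"))
  rec <- bandpass_filter(rec, low, high)
  trials <- epoch_trials(rec, window)
  out <- lapply(trials, baseline_correct)
  attributes(out) <- attributes(trials)
  out
}

#' Read a raw recording from the package CSV format
#'
#' The signal file is a CSV with a header row of channel names and one
#' sample per row; the events sidecar has columns
#' `onset_sample,label`.
#'
#' @param signal_path Path to the signal CSV.
#' @param events_path Path to the events CSV (optional).
#' @param sampling_rate Sampling frequency of the stored signal, Hz.
#' @return A [raw_recording()].
#' @export
read_recording_csv <- function(signal_path, events_path = NULL,
                               sampling_rate = 250) {
  df <- utils::read.csv(signal_path, check.names = FALSE)
  events <- if (is.null(events_path))
    data.frame(onset_sample = integer(), label = character())
  else utils::read.csv(events_path, stringsAsFactors = FALSE)
  raw_recording(t(as.matrix(df)), names(df), sampling_rate, events)
}

#' Write a raw recording to the package CSV format
#' @param rec A [raw_recording()].
#' @param signal_path,events_path Output paths.
#' @return Invisibly, `signal_path`.
#' @export
write_recording_csv <- function(rec, signal_path, events_path = NULL) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.csv(df, signal_path, row.names = FALSE)
  if (!is.null(events_path))
    utils::write.csv(rec$events, events_path, row.names = FALSE)
  invisible(signal_path)
}
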