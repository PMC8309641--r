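#' Image subtraction of the C3 and C4 time-frequency maps
#'
#' The feature-enhancement step at the core of the pipeline: because
#' C3 and C4 sit mirror-symmetrically over the two sensorimotor
#' cortices, left- and right-hand motor imagery modulate their
#' band power in opposite directions.  Subtracting the C4 power map
#' from the C3 map pixel by pixel cancels shared background energy
#' and doubles the lateralized ERD/ERS contrast, so the two classes
#' differ in the *sign* of the difference map.
#'
#' The raw difference `D = power_C3 - power_C4` is computed on the
#' power maps (before any quantization), rescaled symmetrically to
#' `[0, 1]` by `v -> 0.5 + v / (2 * max(abs(D)))` — 0.5 encodes zero
#' difference and the sign survives — and bilinearly resized to
#' `out_size` x `out_size`.
#'
#' Channel order is part of the contract: a silent C4-minus-C3 flip
#' would invert the class encoding, so the maps' `channel` fields are
#' checked.
#'
#' @param map_c3,map_c4 [tf_power()] maps with `channel` `"C3"` and
#'   `"C4"` respectively, on identical freq/time axes.
#' @param out_size Output side length.
#' @return A [classifier_image()] of kind `"subtracted"`.
#' @export
image_subtract <- function(map_c3, map_c4, out_size = 64) {
  check_same_axes(map_c3, map_c4)
  if (!identical(map_c3$channel, "C3") || !identical(map_c4$channel, "C4"))
    stop("image_subtract(map_c3, map_c4) requires channel order C3, C4; ",
         "got ", map_c3$channel, ", ", map_c4$channel)
  d <- map_c3$power - map_c4$power
  m <- max(abs(d))
  scaled <- if (m == 0) matrix(0.5, nrow(d), ncol(d)) else 0.5 + d / (2 * m)
  classifier_image(resize_bilinear(scaled, out_size, out_size), "subtracted")
}

#' Vertically stacked C3/C4 image (the UD baseline)
#'
#' The baseline input representation: each channel's power map is
#' min-max normalized independently, the C3 map is placed above the
#' C4 map, and the stack is resized to `out_size` x `out_size`.
#' Unlike [image_subtract()], no cross-channel cancellation happens,
#' so shared background energy stays in the image.
#'
#' @param map_c3,map_c4 [tf_power()] maps on identical axes.
#' @param out_size Output side length.
#' @return A [classifier_image()] of kind `"stacked"`.
#' @export
stack_ud <- function(map_c3, map_c4, out_size = 64) {
  check_same_axes(map_c3, map_c4)
  norm01 <- function(p) {
    rng <- range(p)
    if (diff(rng) == 0) matrix(0.5, nrow(p), ncol(p))
    else (p - rng[1]) / diff(rng)
  }
  stacked <- rbind(norm01(map_c3$power), norm01(map_c4$power))
  classifier_image(resize_bilinear(stacked, out_size, out_size), "stacked")
}

check_same_axes <- function(a, b) {
  if (!isTRUE(all.equal(a$freqs, b$freqs)) ||
      !isTRUE(all.equal(a$times, b$times)))
    stop("the two maps must share identical frequency and time axes")
  invisible(TRUE)
}

#' Convert trials to classifier images
#'
#' Runs the time-frequency transform on each trial and combines the
#' C3/C4 maps with [image_subtract()] (`representation = "subtract"`)
#' or [stack_ud()] (`"stack"`).  All normalization is per-trial, so
#' images may be computed once and reused across cross-validation
#' folds without information leakage.
#'
#' @param trials A list of [mi_trial()] objects.
#' @param representation `"subtract"` or `"stack"`.
#' @param config A [cwt_config()].
#' @param out_size Image side length.
#' @return A `out_size` x `out_size` x `n_trials` array with a
#'   `labels` attribute.
#' @export
trials_to_images <- function(trials,
                             representation = c("subtract", "stack"),
                             config = cwt_config(), out_size = 64) {
  representation <- match.arg(representation)
  imgs <- array(0, c(out_size, out_size, length(trials)))
  for (i in seq_along(trials)) {
    maps <- trial_tf_maps(trials[[i]], config)
    imgs[, , i] <- if (representation == "subtract")
      image_subtract(maps$C3, maps$C4, out_size)
    else stack_ud(maps$C3, maps$C4, out_size)
  }
  attr(imgs, "labels") <- trial_labels(trials)
  imgs
}
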