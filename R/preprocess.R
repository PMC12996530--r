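#' Raw frame stack
#'
#' A raw microscope intensity recording: time x position, or
#' time x position x transverse rows before collapsing the (few) pixel rows
#' across the channel. The per-position time mean must be strictly positive,
#' as it is the denominator of the normalization step.
#'
#' @param values 2-D or 3-D numeric array of intensities.
#' @param dt Frame interval, s.
#' @param pixel_size_nm Pixel size, nm.
#' @return An object of class `nsm_raw_stack`.
#' @export
raw_frame_stack <- function(values, dt = 0.005, pixel_size_nm = 27.4) {
  if (!is.array(values) || !(length(dim(values)) %in% c(2L, 3L))) {
    rlang::abort("`values` must be a 2-D or 3-D array.",
                 class = "nanokymo_invalid_argument")
  }
  assert_positive_scalar(dt, "dt")
  assert_positive_scalar(pixel_size_nm, "pixel_size_nm")
  structure(list(values = values, dt = dt, pixel_size_nm = pixel_size_nm),
            class = "nsm_raw_stack")
}

stack_values <- function(x) {
  if (inherits(x, "nsm_raw_stack")) x$values
  else if (inherits(x, "nsm_kymograph")) x$values
  else x
}

#' Collapse the transverse axis of a 3-D frame stack
#'
#' Experimental regions of interest span a handful of pixel rows across the
#' channel; the kymograph representation is one-dimensional per frame, so
#' 3-D stacks are averaged over the transverse (third) axis. 2-D inputs pass
#' through unchanged.
#'
#' @param stack A matrix, 3-D array, or [raw_frame_stack()].
#' @return A matrix (time x position), or the input stack object with
#'   collapsed values.
#' @export
collapse_transverse <- function(stack) {
  v <- stack_values(stack)
  out <- if (length(dim(v)) == 3L) rowMeans(v, dims = 2L) else v
  if (inherits(stack, "nsm_raw_stack")) {
    stack$values <- out
    stack
  } else {
    out
  }
}

#' Normalize an intensity stack to relative contrast
#'
#' Computes `I_bar(x, t) = (I(x, t) - <I(x, .)>) / <I(x, .)>`, where
#' `<I(x, .)>` is the per-position time average over the full stack. The
#' result has zero time mean at every position and is invariant under
#' rescaling of the raw intensities (`normalize(c I) = normalize(I)`).
#'
#' @param stack Matrix (time x position), 3-D array (collapsed first), or
#'   [raw_frame_stack()].
#' @return Matrix of relative contrast, time x position.
#' @export
normalize_stack <- function(stack) {
  v <- collapse_transverse(stack_values(stack))
  m <- colMeans(v)
  if (any(!is.finite(m)) || any(m <= 0)) {
    rlang::abort("Per-position time mean must be strictly positive.",
                 class = "nanokymo_invalid_argument")
  }
  sweep(sweep(v, 2L, m, "-"), 2L, m, "/")
}

#' Subtract a separable low-pass filtered version of a kymograph
#'
#' Computes the low-pass field by sliding a normalized (unit-sum) moving
#' average of `window_time` frames along the time axis, then `window_space`
#' pixels along the position axis, and subtracts it. At the edges the
#' windows are truncated and renormalized, preserving the unit-sum property
#' without inventing padding values. Constants (and, approximately, slow
#' drifts with periods much longer than the windows) are removed; the
#' molecule's localized contrast dip survives.
#'
#' @param values Matrix of normalized relative contrast (time x position).
#' @param window_time Window length along time, frames (default 200).
#' @param window_space Window length along position, pixels (default 200).
#' @return Matrix of the same shape: `values - lowpass(values)`.
#' @export
lowpass_subtract <- function(values, window_time = 200L, window_space = 200L) {
  if (!is.matrix(values)) {
    rlang::abort("`values` must be a matrix.", class = "nanokymo_invalid_argument")
  }
  if (nrow(values) < 2L) {
    rlang::abort("Need at least 2 frames.", class = "nanokymo_invalid_argument")
  }
  smooth_t <- apply(values, 2L, running_mean, width = window_time)
  low <- t(apply(smooth_t, 1L, running_mean, width = window_space))
  values - low
}

#' Preprocess a raw stack into a normalized, background-suppressed kymograph
#'
#' The full preprocessing pipeline: collapse the transverse axis (3-D
#' inputs), normalize to relative contrast by the per-position time average,
#' and subtract the separable low-pass field. The output is invariant under
#' scaling of the raw intensities.
#'
#' @param x A raw [kymograph()], [raw_frame_stack()], matrix, or 3-D array.
#' @param window_time,window_space Low-pass window sizes, see
#'   [lowpass_subtract()].
#' @param geometry Channel geometry; taken from `x` when it is a kymograph.
#' @param dt Frame interval; taken from `x` when available.
#' @return A preprocessed [kymograph()] whose `preprocessing` field records
#'   the window sizes.
#' @export
preprocess_kymograph <- function(x, window_time = 200L, window_space = 200L,
                                 geometry = NULL, dt = NULL) {
  if (inherits(x, "nsm_kymograph")) {
    geometry <- geometry %||% x$geometry
    dt <- dt %||% x$dt
  } else if (inherits(x, "nsm_raw_stack")) {
    dt <- dt %||% x$dt
  }
  v <- normalize_stack(x)
  out <- lowpass_subtract(v, window_time, window_space)
  if (is.null(geometry)) {
    ps <- if (inherits(x, "nsm_raw_stack")) x$pixel_size_nm else 27.4
    geometry <- channel_geometry(63, 30, pixel_size_nm = ps,
                                 n_pixels = ncol(out))
  }
  kymograph(out, geometry, dt %||% 0.005,
            provenance = if (inherits(x, "nsm_kymograph")) x$provenance else "measured",
            ground_truth = if (inherits(x, "nsm_kymograph")) x$ground_truth else NULL,
            preprocessing = list(normalized = TRUE, window_time = window_time,
                                 window_space = window_space))
}
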