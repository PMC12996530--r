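#' Kymograph container
#'
#' The central exchange format: a 2-D array of relative optical contrast with
#' rows indexing time frames and columns indexing pixels along the channel
#' axis, together with the channel geometry, the frame interval, provenance
#' (`"simulated"` or `"measured"`) and, for simulated data, the ground-truth
#' trajectories and optical parameters that generated it.
#'
#' @param values Numeric matrix, frames x pixels; all values finite.
#' @param geometry A [channel_geometry()]; `ncol(values)` must equal
#'   `geometry$n_pixels`.
#' @param dt Frame interval in seconds.
#' @param provenance `"simulated"` or `"measured"`.
#' @param ground_truth Optional list of per-molecule records, each a list
#'   with elements `trajectory` and `optics` (and optionally `mw_kDa`,
#'   `rs_nm`, `d_um2_s`, `ioc`).
#' @param preprocessing `NULL` for raw stacks, otherwise a list recording
#'   the preprocessing applied (window sizes, normalization).
#' @return An object of class `nsm_kymograph`.
#' @export
kymograph <- function(values, geometry, dt = 0.005,
                      provenance = c("simulated", "measured"),
                      ground_truth = NULL, preprocessing = NULL) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (frames x pixels).",
                 class = "nanokymo_invalid_argument")
  }
  if (!all(is.finite(values))) {
    rlang::abort("Kymograph values must all be finite.",
                 class = "nanokymo_invalid_argument")
  }
  stopifnot(inherits(geometry, "channel_geometry"))
  if (ncol(values) != geometry$n_pixels) {
    rlang::abort(sprintf(
      "Kymograph has %d columns but geometry declares %d pixels.",
      ncol(values), geometry$n_pixels), class = "nanokymo_shape_error")
  }
  assert_positive_scalar(dt, "dt")
  structure(
    list(values = values, geometry = geometry, dt = dt,
         provenance = provenance, ground_truth = ground_truth,
         preprocessing = preprocessing),
    class = "nsm_kymograph"
  )
}

#' @export
dim.nsm_kymograph <- function(x) dim(x$values)

#' @export
print.nsm_kymograph <- function(x, ...) {
  cat(sprintf(
    "<nsm_kymograph> %d frames x %d px (%.2f s x %.2f um), %s%s, %s\n",
    nrow(x$values), ncol(x$values), nrow(x$values) * x$dt,
    view_length_nm(x$geometry) / 1e3, x$provenance,
    if (is.null(x$preprocessing)) " (raw)" else " (preprocessed)",
    if (is.null(x$ground_truth)) "no ground truth"
    else sprintf("%d ground-truth molecule(s)", length(x$ground_truth))))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble nsm_kymograph
#' @export
as_tibble.nsm_kymograph <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    frame = rep(seq_len(nrow(v)), times = ncol(v)),
    pixel = rep(seq_len(ncol(v)), each = nrow(v)),
    time_s = (rep(seq_len(nrow(v)), times = ncol(v)) - 1) * x$dt,
    position_um = (rep(seq_len(ncol(v)), each = nrow(v)) - 0.5) *
      x$geometry$pixel_size_nm / 1e3,
    contrast = as.vector(v)
  )
}
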