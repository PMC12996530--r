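#' Nanochannel geometry
#'
#' Describes the imaged segment of a nanofluidic channel: its cross-section
#' (width and depth at the widest/deepest points), the camera pixel size
#' projected on the sample, and the number of pixels along the channel axis
#' in the field of view. The cross-section area defaults to the rectangular
#' product `width_nm * depth_nm`; pass `area_nm2` to use an externally
#' measured value instead (e.g. a trapezoid fit to a cross-section SEM
#' image), which is what the optical-contrast-to-mass conversion consumes.
#'
#' @param width_nm Channel width in nm.
#' @param depth_nm Channel depth in nm.
#' @param pixel_size_nm Size of one camera pixel on the sample, nm.
#' @param n_pixels Number of pixels of the imaged channel segment.
#' @param area_nm2 Cross-section area in nm^2; defaults to
#'   `width_nm * depth_nm`.
#' @return An object of class `channel_geometry`.
#' @examples
#' channel_geometry(63, 30)           # ultrasmall channel, area 1890 nm^2
#' channel_geometry(122, 97)          # DNA-ladder channel
#' @export
channel_geometry <- function(width_nm, depth_nm, pixel_size_nm = 27.4,
                             n_pixels = 512L, area_nm2 = NULL) {
  assert_positive_scalar(width_nm, "width_nm")
  assert_positive_scalar(depth_nm, "depth_nm")
  assert_positive_scalar(pixel_size_nm, "pixel_size_nm")
  n_pixels <- assert_count(n_pixels, "n_pixels")
  if (is.null(area_nm2)) {
    area_nm2 <- width_nm * depth_nm
  } else {
    assert_positive_scalar(area_nm2, "area_nm2")
  }
  structure(
    list(width_nm = width_nm, depth_nm = depth_nm,
         pixel_size_nm = pixel_size_nm, n_pixels = n_pixels,
         area_nm2 = area_nm2),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> %g x %g nm (area %g nm^2), %d px @ %g nm/px (view %.2f um)\n",
    x$width_nm, x$depth_nm, x$area_nm2, x$n_pixels, x$pixel_size_nm,
    view_length_nm(x) / 1e3))
  invisible(x)
}

#' Length of the imaged channel segment in nm
#' @param geometry A [channel_geometry()].
#' @return Length of the field of view along the channel axis, nm.
#' @export
view_length_nm <- function(geometry) {
  stopifnot(inherits(geometry, "channel_geometry"))
  geometry$n_pixels * geometry$pixel_size_nm
}

#' Optical response of a point scatterer
#'
#' A molecule inside the channel appears as a Gaussian contrast dip of width
#' `s_nm` whose integral along the channel axis is the integrated optical
#' contrast (iOC, units of contrast x nm). iOC is proportional to the
#' molecular polarizability and inversely proportional to the channel
#' cross-section area.
#'
#' @param ioc Integrated optical contrast (contrast x nm), `>= 0`.
#' @param s_nm Gaussian response width (standard deviation), nm.
#' @return An object of class `optical_params`.
#' @export
optical_params <- function(ioc, s_nm) {
  assert_nonneg_scalar(ioc, "ioc")
  assert_positive_scalar(s_nm, "s_nm")
  structure(list(ioc = ioc, s_nm = s_nm), class = "optical_params")
}

#' Brownian trajectory parameters
#'
#' Parameters of the discrete-time Brownian recursion
#' `x_i = x_{i-1} + v dt + N(0,1) sqrt(2 D dt)` used to simulate molecule
#' motion along the channel axis. Positions are unbounded: molecules may
#' diffuse out of the field of view, and only in-view frames count toward
#' the trajectory-point number N.
#'
#' @param D Diffusivity in um^2/s (`>= 0`).
#' @param v Drift velocity in um/s.
#' @param dt Frame interval in seconds (default 0.005, i.e. 200 fps).
#' @param x0 Initial position in nm, or `"uniform"` to draw uniformly over
#'   the field of view.
#' @param k Number of frames (positions) to generate.
#' @param seed Optional integer seed.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(D, v = 0, dt = 0.005, x0 = "uniform", k,
                              seed = NULL) {
  assert_nonneg_scalar(D, "D")
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    rlang::abort("`v` must be a single finite number.",
                 class = "nanokymo_invalid_argument")
  }
  assert_positive_scalar(dt, "dt")
  k <- assert_count(k, "k")
  if (!(identical(x0, "uniform") ||
        (is.numeric(x0) && length(x0) == 1L && is.finite(x0)))) {
    rlang::abort("`x0` must be a finite position in nm or \"uniform\".",
                 class = "nanokymo_invalid_argument")
  }
  structure(list(D = D, v = v, dt = dt, x0 = x0, k = k, seed = seed),
            class = "trajectory_params")
}

#' Background-noise model parameters
#'
#' Parametric model of the empty-channel background: a (vibrating) Gaussian
#' illumination envelope, a static "dirt" field obtained by convolving white
#' noise with a PSF-like kernel, a per-frame scalar intensity jitter, and
#' per-pixel shot noise. Each parameter can be fixed to a number or left
#' `NULL`, in which case it is drawn from `sampling_ranges` independently for
#' every generated background (the regime used to train the estimator, so
#' that it interpolates over realistic noise variation).
#'
#' Length-like parameters (`x0_bg`, `lambda_bg`, `d_x`, `C`) are expressed in
#' nm; their sampling ranges are expressed as fractions of the view length so
#' they adapt to the imaged segment. `amp_A` and `n_theta` are dimensionless.
#'
#' @param x0_bg Center of the background envelope, nm.
#' @param lambda_bg Width of the background envelope, nm.
#' @param amp_A Per-frame scalar intensity jitter amplitude.
#' @param d_x Channel vibration amplitude scale, nm.
#' @param C Dirt-kernel width, nm.
#' @param n_theta Overall noise level (relative contrast units).
#' @param dirt_amp Multiplier on the dirt field; 1 reproduces the model as
#'   stated, 0 switches the dirt term off (useful for deterministic checks).
#' @param sampling_ranges Named list of per-parameter distributions, see
#'   [default_noise_ranges()].
#' @param seed Optional integer seed.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(x0_bg = NULL, lambda_bg = NULL, amp_A = NULL,
                         d_x = NULL, C = NULL, n_theta = NULL, dirt_amp = 1,
                         sampling_ranges = default_noise_ranges(),
                         seed = NULL) {
  for (nm in c("x0_bg", "lambda_bg", "amp_A", "d_x", "C", "n_theta")) {
    val <- get(nm)
    if (!is.null(val)) {
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
        rlang::abort(sprintf("`%s` must be NULL or a single finite number.", nm),
                     class = "nanokymo_invalid_argument")
      }
    }
  }
  if (!is.null(lambda_bg)) assert_positive_scalar(lambda_bg, "lambda_bg")
  if (!is.null(C)) assert_positive_scalar(C, "C")
  if (!is.null(n_theta)) assert_nonneg_scalar(n_theta, "n_theta")
  assert_nonneg_scalar(dirt_amp, "dirt_amp")
  validate_noise_ranges(sampling_ranges)
  structure(
    list(x0_bg = x0_bg, lambda_bg = lambda_bg, amp_A = amp_A, d_x = d_x,
         C = C, n_theta = n_theta, dirt_amp = dirt_amp,
         sampling_ranges = sampling_ranges, seed = seed),
    class = "noise_params"
  )
}

#' Default sampling ranges for the background-noise parameters
#'
#' Calibrated so that, in the default 63 x 30 nm channel, a molecule with a
#' 100 kDa-equivalent integrated optical contrast produces a per-frame peak
#' signal-to-noise ratio of roughly 2-5, while a 5 kDa-equivalent contrast is
#' buried below the per-pixel noise floor. Length-like entries are fractions
#' of the view length (`*_frac`); `amp_A` and `n_theta` are absolute.
#'
#' @return Named list of distribution specifications.
#' @export
default_noise_ranges <- function() {
  list(
    x0_bg     = list(dist = "normal",  mean_frac = 0.5,  sd_frac = 0.05),
    lambda_bg = list(dist = "uniform", lo_frac = 0.60,   hi_frac = 1.20),
    amp_A     = list(dist = "uniform", lo = 0,           hi = 0.01),
    d_x       = list(dist = "uniform", lo_frac = 0.002,  hi_frac = 0.010),
    C         = list(dist = "uniform", lo_frac = 0.010,  hi_frac = 0.050),
    n_theta   = list(dist = "uniform", lo = 1e-5,        hi = 4e-5)
  )
}

validate_noise_ranges <- function(r) {
  needed <- c("x0_bg", "lambda_bg", "amp_A", "d_x", "C", "n_theta")
  if (!is.list(r) || !all(needed %in% names(r))) {
    rlang::abort("`sampling_ranges` must name all of x0_bg, lambda_bg, amp_A, d_x, C, n_theta.",
                 class = "nanokymo_invalid_argument")
  }
  for (nm in needed) {
    spec <- r[[nm]]
    if (identical(spec[["dist"]], "uniform")) {
      lo <- spec[["lo"]] %||% spec[["lo_frac"]]
      hi <- spec[["hi"]] %||% spec[["hi_frac"]]
      if (is.null(lo) || is.null(hi) || lo > hi) {
        rlang::abort(sprintf("Uniform range for `%s` must satisfy lo <= hi.", nm),
                     class = "nanokymo_invalid_argument")
      }
    } else if (identical(spec[["dist"]], "normal")) {
      sd <- spec[["sd"]] %||% spec[["sd_frac"]]
      if (is.null(sd) || sd < 0) {
        rlang::abort(sprintf("Normal range for `%s` needs sd >= 0.", nm),
                     class = "nanokymo_invalid_argument")
      }
    } else {
      rlang::abort(sprintf("Unknown distribution for `%s`.", nm),
                   class = "nanokymo_invalid_argument")
    }
  }
  invisible(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
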