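#' Differential optical contrast of a molecule in a nanochannel
#'
#' The total intensity scattered by a channel segment containing a molecule
#' is approximately `I_t = I_c + I_m - sqrt(2 I_c I_m)`: the channel term,
#' the molecule term, and their interference. Subtracting the empty-channel
#' image leaves `I_m - sqrt(2 I_c I_m)`, which is negative (a contrast dip)
#' whenever `0 < I_m < 2 I_c`. Because the molecule scatters orders of
#' magnitude less than the channel, the interference term dominates and the
#' dip scales with the molecular polarizability.
#'
#' @param i_c Empty-channel scattering intensity (`> 0`).
#' @param i_m Molecule scattering intensity (`>= 0`). Vectorized.
#' @return The differential signal `I_t - I_c`.
#' @examples
#' differential_contrast(1, 0)     # no molecule, no signal
#' differential_contrast(1, 0.5)   # -0.5
#' @export
differential_contrast <- function(i_c, i_m) {
  if (any(!is.finite(i_c)) || any(i_c <= 0)) {
    rlang::abort("`i_c` must be positive.", class = "nanokymo_invalid_argument")
  }
  if (any(!is.finite(i_m)) || any(i_m < 0)) {
    rlang::abort("`i_m` must be non-negative.", class = "nanokymo_invalid_argument")
  }
  i_m - sqrt(2 * i_c * i_m)
}

#' Sample a Brownian trajectory along the channel axis
#'
#' Generates `k` positions by the recursion
#' `x_i = x_{i-1} + v dt + N(0,1) sqrt(2 D dt)` (diffusivity converted to
#' nm^2/s internally). Positions are neither reflected nor clipped: the
#' physical channel is much longer than the imaged segment, so molecules
#' may leave the field of view. `n_in_view` counts the frames whose position
#' lies inside `[0, n_pixels * pixel_size_nm]`.
#'
#' @param params A [trajectory_params()].
#' @param geometry A [channel_geometry()].
#' @return An object of class `nsm_trajectory` with elements `positions`
#'   (nm), `params`, and `n_in_view`.
#' @export
sample_trajectory <- function(params, geometry) {
  stopifnot(inherits(params, "trajectory_params"),
            inherits(geometry, "channel_geometry"))
  L <- view_length_nm(geometry)
  positions <- with_seed(params$seed, {
    x0 <- if (identical(params$x0, "uniform")) stats::runif(1, 0, L) else params$x0
    d_nm2 <- params$D * 1e6          # um^2/s -> nm^2/s
    v_nm <- params$v * 1e3           # um/s   -> nm/s
    if (params$k == 1L) {
      x0
    } else {
      inc <- v_nm * params$dt +
        stats::rnorm(params$k - 1L) * sqrt(2 * d_nm2 * params$dt)
      c(x0, x0 + cumsum(inc))
    }
  })
  structure(
    list(positions = positions, params = params,
         n_in_view = sum(positions >= 0 & positions <= L)),
    class = "nsm_trajectory"
  )
}

#' @export
print.nsm_trajectory <- function(x, ...) {
  cat(sprintf("<nsm_trajectory> k = %d frames, %d in view, D = %g um^2/s, v = %g um/s\n",
              x$params$k, x$n_in_view, x$params$D, x$params$v))
  invisible(x)
}

#' Render the optical response field of one molecule
#'
#' Evaluates `I_r(x, t_i) = 1 - ioc * g(x - x_i; s)` on the pixel grid,
#' where `g` is a unit-integral Gaussian of width `s`. For a molecule fully
#' in view, the per-frame integrated contrast deficit
#' `pixel_size * sum(1 - I_r)` equals the iOC (to Riemann-sum accuracy).
#' Response fields of multiple molecules combine multiplicatively, each
#' being a relative transmission-like factor near one.
#'
#' @param trajectory An [sample_trajectory()] result.
#' @param optics An [optical_params()].
#' @param geometry A [channel_geometry()].
#' @return Numeric matrix (frames x pixels).
#' @export
render_molecule_response <- function(trajectory, optics, geometry) {
  stopifnot(inherits(trajectory, "nsm_trajectory"),
            inherits(optics, "optical_params"),
            inherits(geometry, "channel_geometry"))
  x_grid <- (seq_len(geometry$n_pixels) - 0.5) * geometry$pixel_size_nm
  # frames x pixels matrix of distances molecule -> pixel center
  g <- stats::dnorm(outer(trajectory$positions, x_grid, "-"), sd = optics$s_nm)
  1 - optics$ioc * g
}

#' Simulate an empty-channel background field
#'
#' Implements the parametric noise model: per frame `t`, a Gaussian
#' illumination envelope `exp(-(x - (x0 + x_lambda))^2 / lambda^2)` whose
#' center vibrates as `x_lambda = (2 N(0,1) + sin((pi - 0.05) t)) d_x`,
#' multiplied by `(1 + dirt)` where the dirt field is white noise convolved
#' with the normalized kernel `(exp(-x^2/C^2) + x_lambda) / sum(...)`, and by
#' a per-frame scalar jitter `(1 + A N(0,1))`. The final field adds shot
#' noise per pixel: `b_f = b_0 (1 + n_theta N(0,1)) + 0.4 n_theta N(0,1)`,
#' with a fresh normal draw for every pixel and frame.
#'
#' The white-noise field underlying the dirt term is drawn once per
#' background (channel imperfections are static in time); only the kernel
#' offset `x_lambda` varies across frames. Convolution is circular along the
#' channel axis.
#'
#' @param noise A [noise_params()]; `NULL` fields are drawn from its
#'   `sampling_ranges`.
#' @param shape Integer vector `c(frames, pixels)`.
#' @param pixel_size_nm Pixel size used to express length-like parameters.
#' @param seed Optional seed (defaults to `noise$seed`).
#' @return Matrix (frames x pixels) with attribute `"noise_resolved"` giving
#'   the concrete parameter values used.
#' @export
sample_background <- function(noise, shape, pixel_size_nm = 27.4,
                              seed = noise$seed) {
  stopifnot(inherits(noise, "noise_params"))
  if (length(shape) != 2L || any(shape < 1)) {
    rlang::abort("`shape` must be c(frames, pixels), both >= 1.",
                 class = "nanokymo_invalid_argument")
  }
  frames <- as.integer(shape[1]); px <- as.integer(shape[2])
  L <- px * pixel_size_nm

  with_seed(seed, {
    p <- resolve_noise_params(noise, L)
    x <- (seq_len(px) - 0.5) * pixel_size_nm

    # static dirt white noise, convolved (circularly) with the PSF-like kernel
    w <- stats::rnorm(px)
    d_wrap <- ((seq_len(px) - 1 + px / 2) %% px - px / 2) * pixel_size_nm
    k0 <- exp(-d_wrap^2 / p$C^2)
    conv0 <- Re(stats::fft(stats::fft(w) * stats::fft(k0), inverse = TRUE)) / px
    s_w <- sum(w); s_k0 <- sum(k0)

    z_vib <- stats::rnorm(frames)
    x_lambda <- (2 * z_vib + sin((pi - 0.05) * seq_len(frames))) * p$d_x
    jitter <- 1 + p$amp_A * stats::rnorm(frames)

    b0 <- matrix(0, frames, px)
    for (t in seq_len(frames)) {
      env <- exp(-(x - (p$x0_bg + x_lambda[t]))^2 / p$lambda_bg^2)
      dirt <- (conv0 + x_lambda[t] * s_w) / (s_k0 + px * x_lambda[t])
      # intensities are physical: the imperfection factor is floored at 5%
      # of the envelope so rare deep noise draws cannot turn the channel
      # response negative
      b0[t, ] <- env * pmax(1 + noise$dirt_amp * dirt, 0.05) * jitter[t]
    }
    z1 <- matrix(stats::rnorm(frames * px), frames, px)
    z2 <- matrix(stats::rnorm(frames * px), frames, px)
    bf <- b0 * (1 + p$n_theta * z1) + 0.4 * p$n_theta * z2
    attr(bf, "noise_resolved") <- p
    bf
  })
}

# Draw concrete values for NULL noise parameters from their sampling ranges.
# Length-like ranges are specified as fractions of the view length L.
resolve_noise_params <- function(noise, L) {
  r <- noise$sampling_ranges
  draw <- function(nm, frac_scale) {
    fixed <- noise[[nm]]
    if (!is.null(fixed)) return(fixed)
    spec <- r[[nm]]
    if (identical(spec[["dist"]], "normal")) {
      mean <- (spec[["mean"]] %||% (spec[["mean_frac"]] * frac_scale))
      sd <- (spec[["sd"]] %||% (spec[["sd_frac"]] * frac_scale))
      stats::rnorm(1, mean, sd)
    } else {
      lo <- spec[["lo"]] %||% (spec[["lo_frac"]] * frac_scale)
      hi <- spec[["hi"]] %||% (spec[["hi_frac"]] * frac_scale)
      stats::runif(1, lo, hi)
    }
  }
  list(
    x0_bg = draw("x0_bg", L),
    lambda_bg = draw("lambda_bg", L),
    amp_A = draw("amp_A", 1),
    d_x = draw("d_x", L),
    C = draw("C", L),
    n_theta = draw("n_theta", 1)
  )
}

#' Compose molecule responses and background into a raw kymograph
#'
#' The recorded intensity is the product `I = I0 * prod(I_r)`: the empty
#' channel response times the (multiplicative) response factor of each
#' molecule. The output is a raw, pre-normalization stack intended for
#' [preprocess_kymograph()].
#'
#' @param responses List of response matrices from
#'   [render_molecule_response()] (may be empty).
#' @param background Background matrix from [sample_background()] or a
#'   measured recording.
#' @param geometry A [channel_geometry()].
#' @param dt Frame interval, s.
#' @param ground_truth Optional list of per-molecule truth records.
#' @return An [kymograph()] with `provenance = "simulated"`.
#' @export
synthesize_kymograph <- function(responses, background, geometry, dt = 0.005,
                                 ground_truth = NULL) {
  if (inherits(responses, "matrix")) responses <- list(responses)
  for (r in responses) {
    if (!identical(dim(r), dim(background))) {
      rlang::abort("Response and background shapes disagree.",
                   class = "nanokymo_shape_error")
    }
  }
  values <- Reduce(`*`, responses, init = background)
  kymograph(values, geometry, dt, provenance = "simulated",
            ground_truth = ground_truth)
}

#' Superimpose simulated molecules on a measured empty-channel recording
#'
#' Takes the background from a randomly positioned crop of an experimentally
#' measured empty-channel kymograph instead of the parametric noise model,
#' and composes it with the molecule response fields as `I = I0 * prod(I_r)`.
#'
#' @param responses List of response matrices (may be empty; then the crop is
#'   returned unchanged). All must share one shape.
#' @param empty_recording An [kymograph()] of an empty channel, at least as
#'   large as the requested shape.
#' @param shape Target `c(frames, pixels)`; defaults to the shape of the
#'   first response, or the full recording if `responses` is empty.
#' @param seed Optional seed for the crop position.
#' @param ground_truth Optional list of per-molecule truth records.
#' @return An [kymograph()] with `provenance = "measured"`.
#' @export
embed_in_measured_background <- function(responses, empty_recording,
                                         shape = NULL, seed = NULL,
                                         ground_truth = NULL) {
  stopifnot(inherits(empty_recording, "nsm_kymograph"))
  if (inherits(responses, "matrix")) responses <- list(responses)
  if (is.null(shape)) {
    shape <- if (length(responses)) dim(responses[[1]]) else dim(empty_recording$values)
  }
  rec <- empty_recording$values
  if (nrow(rec) < shape[1] || ncol(rec) < shape[2]) {
    rlang::abort("Empty-channel recording is smaller than the requested shape.",
                 class = "nanokymo_shape_error")
  }
  crop <- with_seed(seed, {
    r0 <- if (nrow(rec) == shape[1]) 1L else sample.int(nrow(rec) - shape[1] + 1L, 1L)
    c0 <- if (ncol(rec) == shape[2]) 1L else sample.int(ncol(rec) - shape[2] + 1L, 1L)
    rec[r0:(r0 + shape[1] - 1L), c0:(c0 + shape[2] - 1L), drop = FALSE]
  })
  geom <- empty_recording$geometry
  geom$n_pixels <- as.integer(shape[2])
  values <- Reduce(`*`, responses, init = crop)
  kymograph(values, geom, empty_recording$dt, provenance = "measured",
            ground_truth = ground_truth)
}

#' Simulate a complete ground-truthed kymograph
#'
#' Front door of the simulator: converts molecular properties to optical
#' observables (MW -> iOC through the channel area, Rs -> D through
#' Stokes-Einstein with optional hindrance), samples trajectories, renders
#' responses, draws a background, and composes the raw kymograph. Either the
#' molecular properties or the observables can be given; whichever side is
#' missing is derived.
#'
#' @param mw_kDa Molecular weight(s) in kDa, one per molecule (or scalar,
#'   recycled to `n_molecules`). Ignored if `ioc` is given.
#' @param rs_nm Hydrodynamic radius/radii in nm. Ignored if `d_um2_s` given.
#' @param ioc Integrated optical contrast(s); derived from `mw_kDa` if `NULL`.
#' @param d_um2_s Diffusivity/ies in um^2/s; derived from `rs_nm` if `NULL`.
#' @param n_molecules Number of molecules (0 gives a pure-noise control).
#' @param n_frames Number of frames.
#' @param s_nm Gaussian response width, nm (diffraction-limited PSF scale).
#' @param v_um_s Drift velocity, um/s.
#' @param geometry A [channel_geometry()].
#' @param noise A [noise_params()].
#' @param constants A [conversion_constants()].
#' @param hindrance A [hindrance_model()].
#' @param dt Frame interval, s.
#' @param x0 Initial position(s), nm or `"uniform"`.
#' @param empty_recording Optional measured empty-channel [kymograph()]; when
#'   given, the background is a random crop of it instead of the parametric
#'   model.
#' @param seed Optional integer seed controlling all randomness.
#' @return A raw [kymograph()] whose `ground_truth` records, per molecule,
#'   the trajectory, optics, and the property values used.
#' @export
simulate_kymograph <- function(mw_kDa = NULL, rs_nm = NULL, ioc = NULL,
                               d_um2_s = NULL, n_molecules = 1L,
                               n_frames = 512L, s_nm = 100, v_um_s = 0,
                               geometry = channel_geometry(63, 30),
                               noise = noise_params(),
                               constants = conversion_constants(),
                               hindrance = hindrance_model("none"),
                               dt = 0.005, x0 = "uniform",
                               empty_recording = NULL, seed = NULL) {
  n_molecules <- assert_count(n_molecules, "n_molecules", min = 0L)
  n_frames <- assert_count(n_frames, "n_frames")
  with_seed(seed, {
    truth <- list()
    responses <- list()
    if (n_molecules > 0L) {
      if (is.null(ioc)) {
        if (is.null(mw_kDa)) {
          rlang::abort("Give either `mw_kDa` or `ioc`.",
                       class = "nanokymo_invalid_argument")
        }
        ioc <- mw_to_ioc(mw_kDa, geometry$area_nm2, constants)
      }
      if (is.null(d_um2_s)) {
        if (is.null(rs_nm)) {
          rlang::abort("Give either `rs_nm` or `d_um2_s`.",
                       class = "nanokymo_invalid_argument")
        }
        d_um2_s <- rs_to_d(rs_nm, constants, hindrance)
      }
      ioc <- rep_len(ioc, n_molecules)
      d_um2_s <- rep_len(d_um2_s, n_molecules)
      mw_rec <- rep_len(mw_kDa %||% ioc_to_mw(ioc, geometry$area_nm2, constants),
                        n_molecules)
      rs_rec <- rep_len(rs_nm %||% d_to_rs(d_um2_s, constants, hindrance),
                        n_molecules)
      x0 <- if (identical(x0, "uniform")) rep_len(list("uniform"), n_molecules)
            else as.list(rep_len(x0, n_molecules))
      for (m in seq_len(n_molecules)) {
        tp <- trajectory_params(D = d_um2_s[m], v = v_um_s, dt = dt,
                                x0 = x0[[m]], k = n_frames)
        tr <- sample_trajectory(tp, geometry)
        op <- optical_params(ioc = ioc[m], s_nm = s_nm)
        responses[[m]] <- render_molecule_response(tr, op, geometry)
        truth[[m]] <- list(trajectory = tr, optics = op, mw_kDa = mw_rec[m],
                           rs_nm = rs_rec[m], d_um2_s = d_um2_s[m],
                           ioc = ioc[m])
      }
    }
    if (is.null(empty_recording)) {
      bg <- sample_background(noise, c(n_frames, geometry$n_pixels),
                              pixel_size_nm = geometry$pixel_size_nm,
                              seed = NULL)
      synthesize_kymograph(responses, bg, geometry, dt,
                           ground_truth = if (length(truth)) truth else NULL)
    } else {
      embed_in_measured_background(responses, empty_recording,
                                   shape = c(n_frames, geometry$n_pixels),
                                   ground_truth = if (length(truth)) truth else NULL)
    }
  })
}
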