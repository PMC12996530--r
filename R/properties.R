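#' Physical conversion constants
#'
#' Constants of the optical-mass and diffusivity conversions. `a` maps
#' molecular mass to polarizability volume (0.46 Angstrom^3 per Dalton, used
#' for all analytes; the ~8% bias this introduces for dsDNA, whose dn/dc of
#' about 0.172 mL/g differs slightly from the protein value, is accepted and
#' not corrected). `kappa` is the optical calibration constant mapping
#' iOC x area to polarizability volume; with the unit conventions used here
#' (iOC in contrast x nm, area in nm^2, MW in kDa) the Angstrom/nm and
#' Da/kDa factors cancel and `MW_kDa = kappa * iOC * area_nm2 / a`. The
#' default `kappa = 0.003` is calibrated against the simulated background
#' model: it places a 100 kDa molecule in the default 63 x 30 nm channel at
#' a per-frame peak SNR of roughly 2-5 relative to the preprocessed
#' background fluctuation floor, with a 5 kDa molecule well below it. An
#' instrument-specific calibration replaces it when converting measured
#' contrasts.
#'
#' @param a Polarizability-to-mass constant, Angstrom^3/Da.
#' @param kappa Optical calibration constant (dimensionless here).
#' @param temperature_K Temperature, K.
#' @param viscosity_Pa_s Solvent dynamic viscosity, Pa s (water at 25 C).
#' @return An object of class `conversion_constants`.
#' @export
conversion_constants <- function(a = 0.46, kappa = 0.003,
                                 temperature_K = 298.15,
                                 viscosity_Pa_s = 8.9e-4) {
  assert_positive_scalar(a, "a")
  assert_positive_scalar(kappa, "kappa")
  assert_positive_scalar(temperature_K, "temperature_K")
  assert_positive_scalar(viscosity_Pa_s, "viscosity_Pa_s")
  structure(list(a = a, kappa = kappa, temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s),
            class = "conversion_constants")
}

kB <- 1.380649e-23  # J/K

#' Convert integrated optical contrast to molecular weight (and back)
#'
#' The optical contrast dip integrates to an iOC proportional to the
#' molecular polarizability volume and inversely proportional to the channel
#' cross-section area, so `MW = kappa * iOC * area / a`. The map is strictly
#' linear in both iOC and area.
#'
#' @param ioc Integrated optical contrast (contrast x nm). Vectorized.
#' @param area_nm2 Channel cross-section area, nm^2.
#' @param constants A [conversion_constants()].
#' @return Molecular weight in kDa (or iOC for the inverse).
#' @export
ioc_to_mw <- function(ioc, area_nm2, constants = conversion_constants()) {
  if (any(!is.finite(ioc)) || any(ioc <= 0)) {
    rlang::abort("`ioc` must be positive.", class = "nanokymo_invalid_argument")
  }
  assert_positive_scalar(area_nm2, "area_nm2")
  constants$kappa * ioc * area_nm2 / constants$a
}

#' @rdname ioc_to_mw
#' @param mw_kDa Molecular weight in kDa. Vectorized.
#' @export
mw_to_ioc <- function(mw_kDa, area_nm2, constants = conversion_constants()) {
  if (any(!is.finite(mw_kDa)) || any(mw_kDa <= 0)) {
    rlang::abort("`mw_kDa` must be positive.", class = "nanokymo_invalid_argument")
  }
  assert_positive_scalar(area_nm2, "area_nm2")
  mw_kDa * constants$a / (constants$kappa * area_nm2)
}

#' Hindered-diffusion model
#'
#' In a nanochannel whose cross-section approaches the molecule size,
#' hydrodynamic interaction with the walls reduces the measured diffusivity
#' below its free-solution value: `D_measured = H(Rs) * D_free` with
#' `H in (0, 1]`, non-increasing in Rs. Three modes are supported:
#' `"none"` (identity, free solution), `"parametric"` (a Renkin-style
#' centerline hindrance factor for an effective pore radius), and
#' `"lookup"` (a channel-specific calibration table of Rs vs H).
#'
#' @param mode One of `"none"`, `"parametric"`, `"lookup"`.
#' @param r_pore_nm Effective pore radius for the parametric mode, nm.
#' @param lookup Data frame with columns `rs_nm` and `H` (monotone
#'   non-increasing in `rs_nm`) for the lookup mode.
#' @return An object of class `hindrance_model`.
#' @export
hindrance_model <- function(mode = c("none", "parametric", "lookup"),
                            r_pore_nm = NULL, lookup = NULL) {
  mode <- match.arg(mode)
  if (mode == "parametric") {
    assert_positive_scalar(r_pore_nm, "r_pore_nm")
  }
  if (mode == "lookup") {
    if (!is.data.frame(lookup) || !all(c("rs_nm", "H") %in% names(lookup))) {
      rlang::abort("`lookup` must be a data frame with columns rs_nm and H.",
                   class = "nanokymo_invalid_argument")
    }
    lookup <- lookup[order(lookup$rs_nm), ]
    if (any(lookup$H <= 0) || any(lookup$H > 1)) {
      rlang::abort("Hindrance factors must lie in (0, 1].",
                   class = "nanokymo_invalid_argument")
    }
    if (is.unsorted(rev(lookup$H), strictly = FALSE)) {
      rlang::abort("`lookup$H` must be non-increasing in rs_nm.",
                   class = "nanokymo_invalid_argument")
    }
  }
  structure(list(mode = mode, r_pore_nm = r_pore_nm, lookup = lookup),
            class = "hindrance_model")
}

#' Evaluate the hindrance factor H(Rs)
#' @param model A [hindrance_model()].
#' @param rs_nm Hydrodynamic radius, nm. Vectorized.
#' @return Hindrance factor in (0, 1].
#' @export
hindrance_factor <- function(model, rs_nm) {
  stopifnot(inherits(model, "hindrance_model"))
  switch(model$mode,
    none = rep(1, length(rs_nm)),
    parametric = {
      lam <- pmin(rs_nm / model$r_pore_nm, 0.999)
      h <- (1 - lam)^2 * (1 - 2.104 * lam + 2.09 * lam^3 - 0.95 * lam^5)
      pmin(pmax(h, 1e-12), 1)
    },
    lookup = {
      h <- stats::approx(model$lookup$rs_nm, model$lookup$H, xout = rs_nm,
                         rule = 2)$y
      pmin(pmax(h, 1e-12), 1)
    }
  )
}

#' Convert diffusivity to hydrodynamic radius (and back)
#'
#' Free-solution conversion is Stokes-Einstein,
#' `Rs = kB T / (6 pi eta D)`. With a hindrance model the measured
#' diffusivity satisfies `D = H(Rs) * kB T / (6 pi eta Rs)`, solved for Rs
#' by bracketed root finding on `[0.1, 100]` nm.
#'
#' @param d_um2_s Measured diffusivity, um^2/s. Vectorized.
#' @param constants A [conversion_constants()].
#' @param hindrance A [hindrance_model()].
#' @return Hydrodynamic radius in nm (or diffusivity for the inverse).
#' @examples
#' d_to_rs(160)  # ~1.53 nm at 298.15 K in water
#' @export
d_to_rs <- function(d_um2_s, constants = conversion_constants(),
                    hindrance = hindrance_model("none")) {
  if (any(!is.finite(d_um2_s)) || any(d_um2_s <= 0)) {
    rlang::abort("`d_um2_s` must be positive.", class = "nanokymo_invalid_argument")
  }
  # free-solution Rs in nm for D in um^2/s: kB T / (6 pi eta D) with unit juggling
  free_rs <- function(d) {
    kB * constants$temperature_K /
      (6 * pi * constants$viscosity_Pa_s * d * 1e-12) * 1e9
  }
  if (hindrance$mode == "none") {
    return(free_rs(d_um2_s))
  }
  vapply(d_um2_s, function(d) {
    f <- function(rs) hindrance_factor(hindrance, rs) * kB *
      constants$temperature_K /
      (6 * pi * constants$viscosity_Pa_s * rs * 1e-9) * 1e12 - d
    lo <- 0.1; hi <- 100
    if (f(lo) < 0 || f(hi) > 0) {
      rlang::abort(sprintf("No hydrodynamic radius in [0.1, 100] nm matches D = %g um^2/s.", d),
                   class = "nanokymo_no_root")
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' @rdname d_to_rs
#' @param rs_nm Hydrodynamic radius, nm. Vectorized.
#' @export
rs_to_d <- function(rs_nm, constants = conversion_constants(),
                    hindrance = hindrance_model("none")) {
  if (any(!is.finite(rs_nm)) || any(rs_nm <= 0)) {
    rlang::abort("`rs_nm` must be positive.", class = "nanokymo_invalid_argument")
  }
  hindrance_factor(hindrance, rs_nm) * kB * constants$temperature_K /
    (6 * pi * constants$viscosity_Pa_s * rs_nm * 1e-9) * 1e12
}

#' dsDNA contour length from base-pair count
#'
#' B-form double-stranded DNA contributes about 0.34 nm of contour length
#' per base pair.
#'
#' @param bp Number of base pairs (`>= 0`). Vectorized.
#' @return Contour length in nm.
#' @examples
#' dsdna_length(c(50, 100, 200))  # 17, 34, 68 nm
#' @export
dsdna_length <- function(bp) {
  if (any(!is.finite(bp)) || any(bp < 0)) {
    rlang::abort("`bp` must be non-negative.", class = "nanokymo_invalid_argument")
  }
  0.34 * bp
}

#' dsDNA molecular weight from base-pair count
#'
#' Uses the standard approximation of 660 g/mol per base pair (average over
#' the four nucleotides plus backbone); exact values vary slightly with base
#' composition.
#'
#' @param bp Number of base pairs (`>= 0`). Vectorized.
#' @param per_bp_g_mol Average mass per base pair, g/mol.
#' @return Molecular weight in kDa.
#' @examples
#' dsdna_mw(200)  # 132 kDa
#' @export
dsdna_mw <- function(bp, per_bp_g_mol = 660) {
  if (any(!is.finite(bp)) || any(bp < 0)) {
    rlang::abort("`bp` must be non-negative.", class = "nanokymo_invalid_argument")
  }
  bp * per_bp_g_mol / 1000
}

#' Cramer-Rao lower bound for diffusivity estimation
#'
#' For `n` independent Gaussian position increments with variance `2 D dt`,
#' the Fisher information for `D` gives `var(D_hat) >= 2 D^2 / n`, so the
#' relative standard deviation of any unbiased estimator is bounded below by
#' `sqrt(2/n)`, independent of `D` itself.
#'
#' @param n Number of increments (`>= 2`). Vectorized.
#' @param d_um2_s Diffusivity (unused; the relative bound does not depend
#'   on it, kept for interface symmetry).
#' @return Relative standard-deviation lower bound.
#' @examples
#' crlb_diffusivity(200)  # 0.1
#' @export
crlb_diffusivity <- function(n, d_um2_s = NULL) {
  if (any(!is.finite(n)) || any(n < 2)) {
    rlang::abort("`n` must be >= 2.", class = "nanokymo_invalid_argument")
  }
  sqrt(2 / n)
}

#' Cramer-Rao lower bound for contrast-amplitude estimation
#'
#' For a known-shape response observed over `n` frames in additive white
#' Gaussian noise, the amplitude (hence iOC, hence MW) obeys
#' `sigma_rel >= 1 / (snr_eff * sqrt(n))`, where the effective per-frame SNR
#' is `snr_eff = a * sqrt(sum(g^2)) / sigma` for a response template `g`,
#' amplitude `a` and per-pixel noise standard deviation `sigma`. The
#' matched-filter estimator attains this bound.
#'
#' @param n Number of frames (`>= 1`). Vectorized.
#' @param per_frame_snr Effective per-frame SNR (`> 0`).
#' @return Relative standard-deviation lower bound.
#' @examples
#' crlb_amplitude(1e4, 1)  # 0.01
#' @export
crlb_amplitude <- function(n, per_frame_snr) {
  if (any(!is.finite(n)) || any(n < 1)) {
    rlang::abort("`n` must be >= 1.", class = "nanokymo_invalid_argument")
  }
  if (any(!is.finite(per_frame_snr)) || any(per_frame_snr <= 0)) {
    rlang::abort("`per_frame_snr` must be positive.",
                 class = "nanokymo_invalid_argument")
  }
  1 / (per_frame_snr * sqrt(n))
}

#' Theoretical precision bounds as a function of trajectory length
#'
#' Tabulates the Cramer-Rao relative standard-deviation bounds for MW
#' (amplitude estimation at effective per-frame SNR `per_frame_snr`) and Rs
#' (diffusivity estimation; since Rs is inversely proportional to D, its
#' relative bound coincides with the diffusivity bound to first order) over
#' a grid of trajectory-point numbers N. Both bounds scale as `1/sqrt(N)`.
#'
#' @param n_values Integer vector of trajectory lengths N.
#' @param per_frame_snr Effective per-frame SNR for the amplitude bound.
#' @return A tibble of class `nsm_crlb_curve` with columns `n`,
#'   `sigma_rel_mw`, `sigma_rel_rs`.
#' @export
crlb_curve <- function(n_values, per_frame_snr) {
  out <- tibble::tibble(
    n = as.numeric(n_values),
    sigma_rel_mw = crlb_amplitude(n_values, per_frame_snr),
    sigma_rel_rs = crlb_diffusivity(pmax(n_values, 2))
  )
  class(out) <- c("nsm_crlb_curve", class(out))
  attr(out, "per_frame_snr") <- per_frame_snr
  out
}

#' Maximum-likelihood diffusivity estimate from a trajectory
#'
#' The increment-based estimator
#' `D_hat = sum((dx - v dt)^2) / (2 n dt)` over the `n = k - 1` position
#' increments; with unknown drift, `v dt` is replaced by the mean increment.
#' This estimator attains the Cramer-Rao bound `sqrt(2/n)` on relative
#' standard deviation and serves as the reference estimator in precision
#' benchmarks.
#'
#' @param positions_nm Numeric vector of positions, nm (or an
#'   `nsm_trajectory`).
#' @param dt Frame interval, s.
#' @param v_um_s Known drift velocity, um/s, or `NULL` to estimate it from
#'   the mean increment.
#' @return Diffusivity estimate in um^2/s.
#' @export
estimate_diffusivity <- function(positions_nm, dt = 0.005, v_um_s = 0) {
  if (inherits(positions_nm, "nsm_trajectory")) {
    dt <- positions_nm$params$dt
    positions_nm <- positions_nm$positions
  }
  if (length(positions_nm) < 2L) {
    rlang::abort("Need at least two positions.", class = "nanokymo_invalid_argument")
  }
  inc <- diff(positions_nm)
  drift_nm <- if (is.null(v_um_s)) mean(inc) else v_um_s * 1e3 * dt
  sum((inc - drift_nm)^2) / (2 * length(inc) * dt) / 1e6
}

#' Matched-filter amplitude estimate
#'
#' Least-squares estimate of the amplitude `a` of a known template `g`
#' observed over `n` frames in additive noise: frames are projected onto the
#' template, `a_hat = sum(y_t . g) / (n * sum(g^2))`. Unbiased, and
#' efficient for white Gaussian noise.
#'
#' @param frames Matrix (frames x pixels) of observations, or a vector for a
#'   single frame.
#' @param template Numeric vector, the per-frame response shape.
#' @return Amplitude estimate.
#' @export
matched_filter_amplitude <- function(frames, template) {
  if (is.vector(frames)) frames <- matrix(frames, nrow = 1L)
  if (ncol(frames) != length(template)) {
    rlang::abort("Template length must match the number of pixels.",
                 class = "nanokymo_shape_error")
  }
  sum(frames %*% template) / (nrow(frames) * sum(template^2))
}

#' Empirical precision versus trajectory length, with its theoretical bound
#'
#' For each N in `n_grid`, simulates `n_replicates` independent realizations
#' with `simulate_fn(n)`, applies `estimate_fn` to each, and computes the
#' relative standard deviation of the estimates about their mean (the mean
#' is the measure of center). Each empirical point is paired with the
#' theoretical lower bound `bound_fn(n)`.
#'
#' @param simulate_fn Function of `n` returning one simulated realization.
#' @param estimate_fn Function mapping a realization to a scalar estimate.
#' @param n_grid Integer vector of trajectory lengths N.
#' @param n_replicates Replicates per N (`>= 2`).
#' @param bound_fn Function of `n` returning the relative-sigma bound.
#' @param seed Optional seed.
#' @return A tibble of class `nsm_precision_curve` with columns `n`,
#'   `sigma_rel`, `sigma_rel_bound`, `n_replicates`. A zero-variance
#'   (degenerate, e.g. constant) estimator yields `sigma_rel = 0` and is
#'   flagged in the `degenerate` column.
#' @export
precision_vs_n <- function(simulate_fn, estimate_fn, n_grid,
                           n_replicates = 500L,
                           bound_fn = crlb_diffusivity, seed = NULL) {
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2L)
  rows <- with_seed(seed, {
    purrr::map(n_grid, function(n) {
      est <- vapply(seq_len(n_replicates),
                    function(i) estimate_fn(simulate_fn(n)), numeric(1))
      s <- stats::sd(est); m <- mean(est)
      tibble::tibble(n = as.numeric(n),
                     sigma_rel = if (s == 0) 0 else s / m,
                     sigma_rel_bound = bound_fn(n),
                     n_replicates = n_replicates,
                     degenerate = s == 0)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nsm_precision_curve", class(out))
  out
}
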