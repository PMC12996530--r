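#' Generate a deterministic packaged test dataset
#'
#' Stands in for experimental recordings: a desk-scale emulation of a
#' dsDNA-ladder experiment with three MW classes (nominal 132, 66 and
#' 33 kDa) plus a buffer-only control, `n_per_class` kymographs each, and a
#' small high-SNR debugging set with clearly visible trajectories. All
#' kymographs are written as TIFF + JSON sidecars along with a
#' `manifest.csv` recording the per-kymograph ground truth (condition, MW,
#' Rs, iOC, D, N). Identical seeds produce byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling everything.
#' @param n_per_class Kymographs per condition.
#' @param n_frames,n_pixels Kymograph shape.
#' @param mw_classes Nominal MW classes, kDa.
#' @param geometry Channel geometry (default: the DNA-ladder channel,
#'   122 x 97 nm).
#' @return Invisibly, the manifest tibble.
#' @export
nsm_fixtures <- function(dir, seed = 1L, n_per_class = 24L,
                         n_frames = 64L, n_pixels = 128L,
                         mw_classes = c(132, 66, 33),
                         geometry = channel_geometry(122, 97,
                                                     n_pixels = n_pixels)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(geometry$n_pixels == n_pixels)
  conditions <- c(paste0("mw", mw_classes), "control")
  rows <- list()
  with_seed(seed, {
    idx <- 0L
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      mw <- if (cond == "control") NA_real_ else mw_classes[ci]
      for (r in seq_len(n_per_class)) {
        idx <- idx + 1L
        kym <- if (cond == "control") {
          simulate_kymograph(n_molecules = 0L, n_frames = n_frames,
                             geometry = geometry)
        } else {
          simulate_kymograph(mw_kDa = mw, rs_nm = 2 + (mw / 132),
                             n_molecules = 1L, n_frames = n_frames,
                             geometry = geometry)
        }
        file <- sprintf("kymo_%03d_%s.tif", idx, cond)
        write_kymograph(kym, file.path(dir, file))
        gt <- kym$ground_truth
        rows[[idx]] <- tibble::tibble(
          file = file, condition = cond,
          mw_kDa = mw,
          rs_nm = if (is.null(gt)) NA_real_ else gt[[1]]$rs_nm,
          ioc = if (is.null(gt)) NA_real_ else gt[[1]]$ioc,
          d_um2_s = if (is.null(gt)) NA_real_ else gt[[1]]$d_um2_s,
          n_points = if (is.null(gt)) 0 else gt[[1]]$trajectory$n_in_view
        )
      }
    }
    # high-SNR debugging set: slow, bright, always visible
    quiet <- noise_params(n_theta = 1e-7, dirt_amp = 0,
                          d_x = 0, amp_A = 0)
    for (r in seq_len(4L)) {
      idx <- idx + 1L
      kym <- simulate_kymograph(mw_kDa = 500, rs_nm = 2, d_um2_s = 1,
                                n_molecules = 1L, n_frames = n_frames,
                                geometry = geometry, noise = quiet,
                                x0 = view_length_nm(geometry) / 2)
      file <- sprintf("kymo_%03d_debug.tif", idx)
      write_kymograph(kym, file.path(dir, file))
      gt <- kym$ground_truth
      rows[[idx]] <- tibble::tibble(
        file = file, condition = "debug", mw_kDa = 500,
        rs_nm = gt[[1]]$rs_nm, ioc = gt[[1]]$ioc,
        d_um2_s = gt[[1]]$d_um2_s,
        n_points = gt[[1]]$trajectory$n_in_view
      )
    }
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
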