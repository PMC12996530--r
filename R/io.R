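#' Read and write kymographs
#'
#' Kymographs are stored as 32-bit float TIFF images (frames x pixels) with
#' a JSON sidecar (`<stem>.json`) carrying the frame interval, channel
#' geometry, provenance, preprocessing record and ground truth. Because the
#' TIFF floating-point range is `[0, 1]`, values are affinely mapped into
#' that range on write and restored on read using the `value_range` stored
#' in the sidecar; the round trip is lossless at 32-bit float precision.
#' When the sidecar is missing, defaults (pixel size 27.4 nm, dt 0.005 s)
#' are applied with a warning.
#'
#' @param kymo An [kymograph()].
#' @param path Output path ending in `.tif` or `.tiff`.
#' @return `write_kymograph` invisibly returns `path`; `read_kymograph`
#'   returns an [kymograph()].
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "nsm_kymograph"))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rlang::abort("Unsupported format: use a .tif/.tiff path.",
                 class = "nanokymo_io_error")
  }
  v <- kymo$values
  lo <- min(v); hi <- max(v)
  scaled <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  meta <- list(
    dt = kymo$dt,
    provenance = kymo$provenance,
    value_range = c(lo, hi),
    geometry = unclass(kymo$geometry),
    preprocessing = kymo$preprocessing,
    ground_truth = serialize_ground_truth(kymo$ground_truth)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".json")
}

serialize_ground_truth <- function(gt) {
  if (is.null(gt)) return(NULL)
  purrr::map(gt, function(rec) {
    list(
      positions_nm = rec$trajectory$positions,
      n_in_view = rec$trajectory$n_in_view,
      params = rec$trajectory$params[c("D", "v", "dt", "k")],
      ioc = rec$optics$ioc, s_nm = rec$optics$s_nm,
      mw_kDa = rec$mw_kDa %||% NULL, rs_nm = rec$rs_nm %||% NULL,
      d_um2_s = rec$d_um2_s %||% NULL
    )
  })
}

deserialize_ground_truth <- function(gt) {
  if (is.null(gt) || length(gt) == 0L) return(NULL)
  purrr::map(gt, function(rec) {
    pos <- unlist(rec$positions_nm)
    tp <- trajectory_params(D = rec$params$D, v = rec$params$v,
                            dt = rec$params$dt, x0 = pos[1],
                            k = rec$params$k)
    tr <- structure(list(positions = pos, params = tp,
                         n_in_view = rec$n_in_view),
                    class = "nsm_trajectory")
    list(trajectory = tr, optics = optical_params(rec$ioc, rec$s_nm),
         mw_kDa = rec$mw_kDa, rs_nm = rec$rs_nm, d_um2_s = rec$d_um2_s,
         ioc = rec$ioc)
  })
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "nanokymo_io_error")
  }
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rlang::abort("Unsupported format: use a .tif/.tiff path.",
                 class = "nanokymo_io_error")
  }
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    vr <- meta$value_range
    values <- v * (vr[2] - vr[1]) + vr[1]
    g <- meta$geometry
    geometry <- channel_geometry(g$width_nm, g$depth_nm, g$pixel_size_nm,
                                 g$n_pixels, g$area_nm2)
    gt <- if (is.null(meta$ground_truth)) NULL else {
      raw <- jsonlite::read_json(sc, simplifyVector = FALSE)$ground_truth
      deserialize_ground_truth(raw)
    }
    pre <- meta$preprocessing
    if (!is.null(pre)) pre <- as.list(pre)
    kymograph(values, geometry, dt = meta$dt, provenance = meta$provenance,
              ground_truth = gt, preprocessing = pre)
  } else {
    rlang::warn(sprintf(
      "No metadata sidecar for %s; applying defaults (pixel 27.4 nm, dt 0.005 s).",
      path))
    geometry <- channel_geometry(63, 30, pixel_size_nm = 27.4,
                                 n_pixels = ncol(v))
    kymograph(v, geometry, dt = 0.005, provenance = "measured")
  }
}

#' Read and write molecule-estimate tables
#'
#' Estimate tables are plain CSV with columns `id`, `mw_kDa`, `rs_nm`,
#' `n_points`, `p_total` and (optionally) `accepted`.
#'
#' @param estimates A data frame of estimates.
#' @param path CSV path.
#' @return `write_estimates` invisibly returns `path`; `read_estimates`
#'   returns a tibble.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
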