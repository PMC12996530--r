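#' Total probability mass of a probability map
#'
#' `P_total = sum over all bins of P(x, t)`; the per-kymograph confidence
#' score used for thresholding against buffer-only controls.
#'
#' @param p A probability-map matrix (values in `[0, 1]`) or an
#'   `nsm_prediction`.
#' @return Scalar sum of all bin probabilities.
#' @export
probability_total <- function(p) {
  if (inherits(p, "nsm_prediction")) p <- p$probability_map
  sum(p)
}

#' Probability threshold from buffer-only controls
#'
#' The detection threshold is half the average probability mass of the
#' control (buffer-only) kymographs: `P_thresh = mean(P_control) / 2`.
#'
#' @param control_totals Numeric vector of control `P_total` values
#'   (non-empty).
#' @return The threshold (scalar).
#' @examples
#' compute_threshold(c(10, 20, 30))  # 10
#' @export
compute_threshold <- function(control_totals) {
  if (length(control_totals) == 0L || any(!is.finite(control_totals))) {
    rlang::abort("`control_totals` must be a non-empty finite vector.",
                 class = "nanokymo_invalid_argument")
  }
  0.5 * mean(control_totals)
}

#' Flag estimates by the probability-sum threshold
#'
#' Keeps exactly the kymographs with `p_total >= thresh` (raising the
#' threshold never increases the accepted count). The input table is
#' returned with its `accepted` column set; filter on it to obtain the
#' retained set.
#'
#' @param estimates A data frame with a `p_total` column (one row per
#'   kymograph), e.g. from [predict_population()].
#' @param thresh Threshold, `>= 0`.
#' @return The input as a tibble with `accepted` set, and the threshold in
#'   attribute `"threshold"`.
#' @export
apply_threshold <- function(estimates, thresh) {
  assert_nonneg_scalar(thresh, "thresh")
  if (!"p_total" %in% names(estimates)) {
    rlang::abort("`estimates` must have a `p_total` column.",
                 class = "nanokymo_invalid_argument")
  }
  out <- tibble::as_tibble(estimates)
  out$accepted <- out$p_total >= thresh
  attr(out, "threshold") <- thresh
  out
}

#' Gaussian 3-sigma outlier pruning
#'
#' Fits a Gaussian to the values by moment matching (sample mean and sample
#' standard deviation, `n - 1` denominator) in a single pass, and removes
#' values falling strictly outside three standard deviations of the mean.
#' Points exactly at `mu +/- 3 sigma` are kept; there is no re-fit after
#' removal.
#'
#' @param values Numeric vector (`length >= 2`).
#' @return A list with `values` (kept), `mu`, `sigma`, and `removed`
#'   (indices into the input).
#' @export
prune_outliers <- function(values) {
  if (length(values) < 2L || any(!is.finite(values))) {
    rlang::abort("`values` must be a finite vector of length >= 2.",
                 class = "nanokymo_invalid_argument")
  }
  mu <- mean(values)
  sigma <- stats::sd(values)
  removed <- which(abs(values - mu) > 3 * sigma)
  list(values = if (length(removed)) values[-removed] else values,
       mu = mu, sigma = sigma, removed = removed)
}

#' Population summary of thresholded, pruned molecule estimates
#'
#' Applies the probability-sum threshold, then prunes MW and Rs outliers
#' independently (a kymograph removed in either dimension is excluded from
#' the joint population), and summarizes the surviving estimates.
#'
#' @param estimates Data frame with columns `mw_kDa`, `rs_nm`, `p_total`.
#' @param thresh Probability-sum threshold (e.g. from
#'   [compute_threshold()]); 0 keeps everything.
#' @param prune Logical; apply the 3-sigma pruning after thresholding.
#' @return A one-row tibble of class `nsm_population_summary` with columns
#'   `n_input`, `n_accepted`, `mw_mean`, `mw_median`, `mw_sd`, `rs_mean`,
#'   `rs_median`, `rs_sd`, `threshold_used`.
#' @export
summarize_population <- function(estimates, thresh = 0, prune = TRUE) {
  flagged <- apply_threshold(estimates, thresh)
  kept <- dplyr::filter(flagged, .data$accepted)
  if (nrow(kept) == 0L) {
    rlang::abort("No estimates pass the threshold.",
                 class = "nanokymo_empty_population")
  }
  if (prune && nrow(kept) >= 2L) {
    pm <- prune_outliers(kept$mw_kDa)
    pr <- prune_outliers(kept$rs_nm)
    drop <- union(pm$removed, pr$removed)
    if (length(drop)) kept <- kept[-drop, ]
  }
  out <- tibble::tibble(
    n_input = nrow(flagged),
    n_accepted = nrow(kept),
    mw_mean = mean(kept$mw_kDa), mw_median = stats::median(kept$mw_kDa),
    mw_sd = if (nrow(kept) > 1L) stats::sd(kept$mw_kDa) else 0,
    rs_mean = mean(kept$rs_nm), rs_median = stats::median(kept$rs_nm),
    rs_sd = if (nrow(kept) > 1L) stats::sd(kept$rs_nm) else 0,
    threshold_used = thresh
  )
  class(out) <- c("nsm_population_summary", class(out))
  out
}
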