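# broom-style accessors

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted model
#' @param x An `nsm_hvit_fit`.
#' @param ... Unused.
#' @return The per-step history tibble (step, stage, loss, bce, val_loss).
#' @method tidy nsm_hvit_fit
#' @export
tidy.nsm_hvit_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#' @param x An `nsm_hvit_fit`.
#' @param ... Unused.
#' @return Tibble with steps, stages, first/final loss, best validation
#'   loss, and parameter count.
#' @method glance nsm_hvit_fit
#' @export
glance.nsm_hvit_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_steps = nrow(h),
    n_stages = max(h$stage),
    initial_loss = h$loss[1],
    final_loss = h$loss[nrow(h)],
    best_val_loss = x$best_val_loss,
    n_parameters = sum(vapply(x$model$params, length, integer(1)))
  )
}

#' Tidy a single-kymograph prediction
#' @param x An `nsm_prediction`.
#' @param ... Unused.
#' @return The one-row estimate tibble (mw_kDa, rs_nm, n_points, p_total).
#' @method tidy nsm_prediction
#' @export
tidy.nsm_prediction <- function(x, ...) x$estimate

#' Tidy a population summary into one row per statistic
#' @param x An `nsm_population_summary`.
#' @param ... Unused.
#' @return A long tibble with columns `property`, `statistic`, `value`.
#' @method tidy nsm_population_summary
#' @export
tidy.nsm_population_summary <- function(x, ...) {
  wide <- tibble::as_tibble(unclass(x))
  long <- tidyr::pivot_longer(
    wide[c("mw_mean", "mw_median", "mw_sd", "rs_mean", "rs_median", "rs_sd")],
    dplyr::everything(), names_to = "key", values_to = "value")
  tidyr::separate(long, "key", into = c("property", "statistic"), sep = "_")
}
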