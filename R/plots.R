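# ggplot2 autoplot methods for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kymograph as a contrast heat map
#'
#' @param object An [kymograph()].
#' @param ... Unused.
#' @return A ggplot: position (um) vs time (s), filled by relative contrast.
#' @method autoplot nsm_kymograph
#' @export
autoplot.nsm_kymograph <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$position_um, .data$time_s,
                                   fill = .data$contrast)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey90",
                                  high = "white", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Position (µm)", y = "Time (s)",
                  fill = "Contrast") +
    ggplot2::theme_minimal()
}

#' Plot a probability map
#'
#' @param object An `nsm_probability_map` (from [predict_hvit()]).
#' @param ... Unused.
#' @return A ggplot of per-bin molecule-presence probability.
#' @method autoplot nsm_probability_map
#' @export
autoplot.nsm_probability_map <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    time_bin = rep(seq_len(nrow(m)), times = ncol(m)),
    space_bin = rep(seq_len(ncol(m)), each = nrow(m)),
    probability = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$space_bin, .data$time_bin,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Channel bin", y = "Time bin", fill = "P") +
    ggplot2::theme_minimal()
}

#' Plot an empirical precision curve against its theoretical bound
#'
#' @param object An `nsm_precision_curve` from [precision_vs_n()].
#' @param ... Unused.
#' @return A log-log ggplot of relative sigma vs N with the bound as a line.
#' @method autoplot nsm_precision_curve
#' @export
autoplot.nsm_precision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sigma_rel_bound),
                       linewidth = 0.8, colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$sigma_rel),
                        colour = "#2171b5", size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Trajectory points N",
                  y = expression(sigma[rel]),
                  title = "Empirical precision vs theoretical bound") +
    ggplot2::theme_minimal()
}

#' Plot a theoretical precision-bound curve
#'
#' @param object An `nsm_crlb_curve` from [crlb_curve()].
#' @param ... Unused.
#' @return A log-log ggplot of the MW and Rs relative-sigma bounds vs N.
#' @method autoplot nsm_crlb_curve
#' @export
autoplot.nsm_crlb_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("sigma_rel_mw", "sigma_rel_rs"),
                            names_to = "property", values_to = "bound")
  df$property <- ifelse(df$property == "sigma_rel_mw", "MW", "Rs")
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$bound,
                                   colour = .data$property)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Trajectory points N", y = expression(sigma[rel]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object An `nsm_hvit_fit` from [train_hvit()].
#' @param ... Unused.
#' @return A ggplot of training (and validation) loss vs step.
#' @method autoplot nsm_hvit_fit
#' @export
autoplot.nsm_hvit_fit <- function(object, ...) {
  h <- object$history
  g <- ggplot2::ggplot(h, ggplot2::aes(.data$step, .data$loss)) +
    ggplot2::geom_line(colour = "#2171b5") +
    ggplot2::labs(x = "Step", y = "Loss") +
    ggplot2::theme_minimal()
  hv <- h[!is.na(h$val_loss), ]
  if (nrow(hv)) {
    g <- g + ggplot2::geom_point(data = hv,
                                 ggplot2::aes(y = .data$val_loss),
                                 colour = "#cb181d", size = 2)
  }
  g
}
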