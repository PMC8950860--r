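#' Plot a compartmental volume series
#'
#' @param object A `resp_volumes` tibble.
#' @param demean Subtract each compartment's mean before plotting.
#' @param ... Unused.
#' @return A ggplot: volume (L) vs time, one facet per compartment.
#' @method autoplot resp_volumes
#' @export
autoplot.resp_volumes <- function(object, demean = TRUE, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("V_CW", "V_RC", "V_AB"),
                            names_to = "compartment", values_to = "volume")
  if (demean) {
    df <- df %>%
      group_by(.data$compartment) %>%
      mutate(volume = .data$volume - mean(.data$volume)) %>%
      ungroup()
  }
  df$compartment <- factor(df$compartment, levels = c("V_CW", "V_RC", "V_AB"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$volume)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~compartment, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "volume (L)") +
    ggplot2::theme_minimal()
}

#' Plot LOOCV relative-error distributions
#'
#' @param object A `resp_loocv`.
#' @param ... Unused.
#' @return A ggplot: per-metric relative errors (%) by compartment.
#' @method autoplot resp_loocv
#' @export
autoplot.resp_loocv <- function(object, ...) {
  metrics <- paste0("d", c("RR", "DI", "DE", "VI", "VE"))
  df <- tidyr::pivot_longer(object$errors, all_of(metrics),
                            names_to = "metric", values_to = "error")
  df$metric <- factor(df$metric, levels = metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compartment, y = .data$error)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative error (%)",
                  title = sprintf("Model %d LOOCV", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot mean absolute PC loadings per IMU
#'
#' @param object A `resp_selection`.
#' @param families Signal families to show (default the acceleration
#'   families).
#' @param ... Unused.
#' @return A ggplot: mean |loading| by IMU, faceted by family x target,
#'   with the selection threshold drawn.
#' @method autoplot resp_selection
#' @export
autoplot.resp_selection <- function(object,
                                    families = c("A_ToT", "A_X", "A_Y"), ...) {
  thr <- attr(object, "threshold") %||% 0.32
  df <- dplyr::filter(as_tibble(unclass(object)), .data$family %in% families)
  df$imu <- factor(df$imu, levels = paste0("imu", 1:9))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$imu, y = .data$mean_abs_loading,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::facet_grid(target ~ family) +
    ggplot2::labs(x = NULL, y = "mean |loading|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
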