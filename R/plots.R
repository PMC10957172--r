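# ggplot2 methods for the main result types.

#' @export
autoplot.rate_map <- function(object, units = NULL, smooth = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(units)) df <- df[df$unit_id %in% units, ]
  df$value <- if (smooth) df$rate_smooth else df$rate
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value,
                                   colour = .data$trajectory)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~unit_id, scales = "free_y") +
    ggplot2::labs(x = "position bin", y = "firing rate (Hz)",
                  colour = "trajectory") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.heatmap_set <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("preferred", "nonpreferred"),
                            names_to = "which", values_to = "norm_rate")
  df$which <- factor(df$which, c("preferred", "nonpreferred"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$row,
                                   fill = .data$norm_rate)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~which) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), oob = scales_squish) +
    ggplot2::labs(x = "position bin", y = "unit (ordered by peak)",
                  fill = "normalized rate") +
    ggplot2::theme_minimal()
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @export
autoplot.perm_test <- function(object, units = NULL, ...) {
  df <- object$points
  if (!is.null(units)) df <- df[df$unit_id %in% units, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$d0)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$sig, ], colour = "red", size = 0.8) +
    ggplot2::facet_wrap(~unit_id, scales = "free_y") +
    ggplot2::labs(x = "position bin",
                  y = "left - right rate difference (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reward_psth <- function(object, units = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(units)) df <- df[df$unit_id %in% units, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$rate_smooth,
                                   colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit_id, scales = "free_y") +
    ggplot2::labs(x = "time from first lick (s)", y = "rate (Hz)",
                  colour = "reward side") +
    ggplot2::theme_minimal()
}

#' Plot a light PSTH against its baseline limit
#'
#' @param psth Tibble from [build_light_psth()].
#' @param limit Baseline confidence limit (Hz), drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_light_psth <- function(psth, limit = NULL) {
  p <- ggplot2::ggplot(psth, ggplot2::aes(x = .data$t_ms + 0.5,
                                          y = .data$rate,
                                          fill = .data$artifact)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "grey70")) +
    ggplot2::labs(x = "time from pulse onset (ms)", y = "rate (Hz)",
                  fill = "artifact bin") +
    ggplot2::theme_minimal()
  if (!is.null(limit)) {
    p <- p + ggplot2::geom_hline(yintercept = limit, linetype = 2)
  }
  p
}
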