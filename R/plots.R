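#' Plot a FLIM fit
#'
#' Pixel/fraction fits draw the fitted-parameter map as a raster; binned
#' fits draw the pooled decay with the model curve on a log count scale.
#'
#' @param object a `flim_fit`.
#' @param value column to map for pixel fits (default lifetime or beta).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flim_fit <- function(object, value = NULL, ...) {
  if (!is.null(object$pixels) && nrow(object$pixels) > 0 &&
      object$type != "binned") {
    px <- object$pixels
    if (is.null(value))
      value <- intersect(c("tau_ps", "beta"), names(px))[1]
    return(
      ggplot2::ggplot(px, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data[[value]])) +
        ggplot2::geom_raster() +
        ggplot2::scale_y_reverse() +
        ggplot2::scale_fill_viridis_c(name = value) +
        ggplot2::coord_fixed() +
        ggplot2::facet_grid(rows = ggplot2::vars(.data$well),
                            cols = ggplot2::vars(.data$fov)) +
        ggplot2::theme_minimal()
    )
  }
  f <- object$fitted
  ggplot2::ggplot(f, ggplot2::aes(x = .data$delay_ps)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gate delay (ps)", y = "counts") +
    ggplot2::theme_minimal()
}

#' Plate heat map of well summaries
#'
#' @param summaries well-level output of [aggregate_plate()].
#' @param value column to display (default the first `mean_*` column).
#' @param limits display range, e.g. `c(2200, 3100)` ps; `NULL` for data
#'   range.
#' @return a ggplot.
#' @export
plot_plate_map <- function(summaries, value = NULL, limits = NULL) {
  if (is.null(value))
    value <- grep("^mean_", names(summaries), value = TRUE)[1]
  pos <- well_position(summaries$well)
  d <- dplyr::mutate(summaries, plate_row = pos$row, plate_col = pos$col)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$plate_col, y = .data$plate_row,
                                  fill = .data[[value]])) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_y_reverse(breaks = seq_len(8), labels = LETTERS[1:8]) +
    ggplot2::scale_x_continuous(breaks = seq_len(12)) +
    ggplot2::scale_fill_viridis_c(name = value, limits = limits) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.flim_fit
#' @export
autoplot.dose_response <- function(object, ...) {
  curve <- attr(object, "curve")
  pts <- attr(object, "data")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$concentration,
                                      y = .data$response)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = pts) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "response") +
    ggplot2::theme_minimal()
}

#' Time-course plot of mean lifetime and FRETing fraction
#' @param tc output of [time_course()].
#' @return a ggplot.
#' @export
plot_time_course <- function(tc) {
  long <- tidyr::pivot_longer(
    dplyr::select(tc, "time_s", "mean_tau_ps", "mean_beta"),
    cols = c("mean_tau_ps", "mean_beta"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "time (s)") +
    ggplot2::theme_minimal()
}
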