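# ggplot2 visualisations of the drift tracks, per-pixel models and the
# evaluation summary.

#' Plot a reference's drift track with spline and GAM overlays
#'
#' Matched peaks are drawn as the difference between observed and theoretical
#' m/z over pixel order, inliers and outliers distinguished, with the ridge
#' spline and (when available) the GAM trend overlaid.
#'
#' @param track One element of the `track_details` list of an `msi_recal`
#'   result (from [model_reference_track()]).
#' @return A ggplot object.
#' @export
plot_drift_track <- function(track) {
  d <- track$diagnostics
  if (is.null(d)) stop("track has no diagnostics to plot", call. = FALSE)
  m0 <- track$reference_mz
  df <- tibble::tibble(
    pixel = d$pixel_index, dmz = d$mz_obs - m0,
    status = ifelse(d$inlier, "inlier", "outlier")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pixel, y = .data$dmz)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(
      data = tibble::tibble(pixel = d$pixel_index, dmz = d$spline_mz - m0),
      colour = "orange"
    ) +
    ggplot2::scale_colour_manual(values = c(inlier = "grey30", outlier = "red")) +
    ggplot2::labs(
      x = "pixel order", y = expression(Delta * " m/z (observed - theoretical)"),
      title = sprintf("Reference %.4f m/z", m0),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(track$trend)) {
    tr <- track$trend$predictions
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(pixel = tr$pixel_index, dmz = tr$mz_pred - m0),
      colour = "forestgreen"
    )
  }
  p
}

#' Ion image of a matched reference
#'
#' Intensities of the matched peaks on the pixel grid (the smallest-residual
#' match when a pixel has several), for visual validation of the assignment's
#' spatial consistency.
#'
#' @param track One element of `track_details` (must carry diagnostics).
#' @param dataset The [msi_dataset()] searched (for the coordinates).
#' @return A ggplot object.
#' @export
plot_match_image <- function(track, dataset) {
  d <- track$diagnostics
  if (is.null(d)) stop("track has no diagnostics to plot", call. = FALSE)
  best <- d |>
    dplyr::group_by(.data$pixel_index) |>
    dplyr::slice_min(.data$residual, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  xy <- dataset$coords[match(best$pixel_index, dataset$coords$pixel_index), ]
  df <- tibble::tibble(x = xy$x, y = xy$y, intensity = best$intensity)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Matched intensities, %.4f m/z",
                                  track$reference_mz)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_drift_track autoplot method dispatching on the full
#'   recalibration result: drift tracks of the first accepted references.
#' @param object An `msi_recal` object.
#' @param n Number of accepted reference tracks to draw.
#' @param ... Unused.
#' @export
autoplot.msi_recal <- function(object, n = 1, ...) {
  acc <- Filter(function(t) t$accepted, object$track_details)
  if (length(acc) == 0) stop("no accepted references to plot", call. = FALSE)
  plot_drift_track(acc[[min(n, length(acc))]])
}

#' Evaluation scatter: improvement vs significance
#'
#' One point per evaluated dataset: Delta-tilde against -log10 of the
#' bootstrap p-value.
#'
#' @param reports A list of `recal_evaluation` objects (or a single one).
#' @return A ggplot object.
#' @export
plot_evaluation <- function(reports) {
  if (inherits(reports, "recal_evaluation")) reports <- list(reports)
  df <- dplyr::bind_rows(lapply(reports, glance))
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_ppm,
                                   -log10(.data$p_value))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      x = expression(tilde(Delta) * " (ppm)"),
      y = expression(-log[10] ~ "bootstrap p")
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_evaluation autoplot method for a single evaluation:
#'   per-pixel improvement distribution.
#' @param object A `recal_evaluation` object.
#' @param ... Unused.
#' @export
autoplot.recal_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$per_pixel, ggplot2::aes(.data$diff_ppm)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$delta, colour = "red") +
    ggplot2::labs(
      x = "per-pixel median |error before| - |error after| (ppm)",
      y = "pixels",
      title = sprintf("Delta-tilde = %.2f ppm, p = %.3g",
                      object$delta, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
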