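#' Plot a p-value calibration curve
#'
#' Expected (-log p) versus observed (-log empirical survival fraction); a
#' well-calibrated score follows the y = x diagonal, a conservative score
#' sits above it.
#'
#' @param curve A tibble from [calibration_curve()] (an optional `model`
#'   column separates multiple curves).
#' @return A ggplot object.
#' @export
plot_calibration <- function(curve) {
  aes_pts <- if ("model" %in% names(curve)) {
    ggplot2::aes(.data$neg_log_p, .data$neg_log_sf, colour = .data$model)
  } else {
    ggplot2::aes(.data$neg_log_p, .data$neg_log_sf)
  }
  ggplot2::ggplot(curve, aes_pts) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(-log ~ "p-value (expected)"),
      y = expression(-log ~ "survival fraction (observed)")
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn scan_thresholds Yield versus call threshold, one line per
#'   library-pooling level.
#' @param object A `threshold_scan` tibble.
#' @param ... Unused.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$call_threshold, .data$mean_yield,
    colour = factor(.data$pool_factor),
    group = .data$pool_factor
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mutation call threshold (reads)",
                  y = "mean target genes discovered",
                  colour = "pooling P") +
    ggplot2::theme_minimal()
}

#' Plot discovery yield against experiment cost
#'
#' @param subset_yields A tibble from [subset_yield_analysis()] (columns
#'   `cost`, `mean_found`, `se_found`) or any tibble with `total_cost` and
#'   `mean_yield` (e.g. [optimize_design()] output).
#' @return A ggplot object.
#' @export
plot_yield_cost <- function(subset_yields) {
  if (all(c("cost", "mean_found") %in% names(subset_yields))) {
    ggplot2::ggplot(subset_yields,
                    ggplot2::aes(.data$cost, .data$mean_found)) +
      ggplot2::geom_line() +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$mean_found - .data$se_found,
        ymax = .data$mean_found + .data$se_found
      )) +
      ggplot2::labs(x = "experiment cost ($)",
                    y = "validated targets in report list") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(subset_yields,
                    ggplot2::aes(.data$total_cost, .data$mean_yield)) +
      ggplot2::geom_point() +
      ggplot2::geom_line() +
      ggplot2::labs(x = "experiment cost ($)", y = "mean yield") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
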