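# ggplot2 autoplot methods for the package's result objects.

#' Plot posterior probability curves and cut points
#'
#' Draws the per-class posterior probability curves of the discriminant
#' model over a count grid, with the derived boundaries as vertical
#' lines — the standard picture of how the intensity cut points arise as
#' curve intersections.
#'
#' @param object A [derive_cutpoints()] object.
#' @param grid Optional count grid; defaults to a 1-cpm grid spanning the
#'   class means plus three pooled SDs.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cutpoint_set <- function(object, grid = NULL, ...) {
  model <- object$model
  if (is.null(grid)) {
    grid <- seq(max(0, min(model$class_means) - 3 * model$pooled_sd),
                max(model$class_means) + 3 * model$pooled_sd, by = 10)
  }
  curves <- posterior_curves(model, grid)
  cuts <- tibble(
    boundary = c("light_max", "moderate_max"),
    cpm = c(object$raw$light_max, object$raw$moderate_max)
  )
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$cpm, y = .data$posterior,
                               colour = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = cuts,
                        ggplot2::aes(xintercept = .data$cpm),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "counts per minute", y = "posterior probability",
      title = "Discriminant posterior curves and derived cut points"
    ) +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param object An [evaluate_cutpoints()] object.
#' @param ... Unused.
#' @return A ggplot object, one panel per intensity.
#' @exportS3Method ggplot2::autoplot
autoplot.cutpoint_evaluation <- function(object, ...) {
  pts <- purrr::imap(object$roc, function(r, lev) {
    mutate(r$roc_points, intensity = lev)
  }) |> bind_rows() |>
    mutate(intensity = factor(.data$intensity, intensity_levels()))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~intensity) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = "One-vs-rest ROC curves by intensity") +
    ggplot2::theme_minimal()
}

#' Plot energy expenditure against counts
#'
#' Scatter of per-child activity summaries: mean counts per minute
#' against METs, coloured by activity — the calibration picture relating
#' movement counts to metabolic cost.
#'
#' @param summaries Output of [reduce_study()].
#' @return A ggplot object.
#' @export
plot_counts_vs_mets <- function(summaries) {
  check_columns(summaries, c("mean_cpm", "mets", "activity"), "summaries")
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$mean_cpm, y = .data$mets,
                               colour = .data$activity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "counts per minute", y = "METs (EE / predicted BMR)",
                  title = "Energy expenditure vs accelerometer counts") +
    ggplot2::theme_minimal()
}
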