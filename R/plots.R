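# ggplot2 displays for the fitted objects.

#' Plot a bootstrap distribution of community doubling times
#'
#' Histogram of the replicate predictions with the point prediction (solid)
#' and bootstrap mean (dashed) marked.
#'
#' @param object A `growth_bootstrap`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_bootstrap <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$d_hours)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$point$d_hours, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$mean_d, linetype = "dashed") +
    ggplot2::labs(
      x = "predicted minimal generation time (h)", y = "replicates",
      title = object$name,
      subtitle = sprintf("B = %d bootstraps, sd = %.2f h", object$B,
                         object$sd_d)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a refit growth model (transformed d versus F)
#'
#' Scatter of the training data on the Box-Cox scale with the fitted line,
#' in the style of the minimal-generation-time-versus-F regression display.
#'
#' @param object A `growth_model` with provenance `"refit"` (the published
#'   model carries no training data).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_model <- function(object, ...) {
  if (is.null(object$training)) {
    abort("no training data stored; only refit models can be plotted")
  }
  ggplot2::ggplot(object$training, ggplot2::aes(x = .data$f, y = .data$phi)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope_F, colour = "red") +
    ggplot2::labs(
      x = "F (composite codon-usage bias)",
      y = sprintf("Box-Cox(d), lambda = %s", format(object$lambda)),
      subtitle = sprintf("Phi(d) = %.4f %+.4f F   (R^2 = %.2f, n = %d)",
                         object$intercept, object$slope_F, object$r_squared,
                         object$training_n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot subsampling accuracy of the composite index
#'
#' Per-size scatter of the recomputed index (F when available, otherwise
#' ΔENC′) with the per-size mean and mean ± sd envelopes, showing how the
#' estimate tightens with sample size.
#'
#' @param tbl Output of [subsample_accuracy()].
#' @param full_value Optional horizontal reference: the full-data value.
#' @return A ggplot.
#' @export
plot_subsample_accuracy <- function(tbl, full_value = NULL) {
  ycol <- if ("f" %in% names(tbl)) "f" else "delta_enc"
  summ <- tbl |>
    group_by(.data$size) |>
    summarise(mean = mean(.data[[ycol]]), sd = sd(.data[[ycol]]),
              .groups = "drop")
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$size, y = .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.25, colour = "grey50") +
    ggplot2::geom_line(data = summ, ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_line(data = summ, ggplot2::aes(y = .data$mean + .data$sd),
                       linetype = "dashed") +
    ggplot2::geom_line(data = summ, ggplot2::aes(y = .data$mean - .data$sd),
                       linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genes sampled", y = ycol) +
    ggplot2::theme_minimal()
  if (!is.null(full_value)) {
    p <- p + ggplot2::geom_hline(yintercept = full_value, colour = "red",
                                 linetype = "dotted")
  }
  p
}
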