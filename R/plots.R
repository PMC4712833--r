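# ggplot2 views of the main result types.

#' Bar plot of chromatin-state composition
#'
#' @param classified Output of [classify_peaks()], or a composition tibble
#'   from [class_composition()].
#' @param mode Passed to [class_composition()] when `classified` is a
#'   classified peak set.
#' @return A ggplot object.
#' @export
plot_composition <- function(classified, mode = "label") {
  comp <- if (inherits(classified, "classified_peaks")) {
    class_composition(classified, mode = mode)
  } else {
    classified
  }
  comp <- comp[comp$n > 0, , drop = FALSE]
  ggplot2::ggplot(comp, ggplot2::aes(
    x = stats::reorder(.data$category, -.data$n), y = .data$frac_total,
    fill = .data$locality)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of all peaks",
                  title = "Chromatin-state composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean coverage profile around peak centers
#'
#' Column means of a [peak_signal_matrix()], one line per supplied matrix.
#'
#' @param ... Named signal matrices from [peak_signal_matrix()].
#' @return A ggplot object.
#' @export
plot_signal_profile <- function(...) {
  mats <- list(...)
  if (is.null(names(mats)) || any(!nzchar(names(mats)))) {
    names(mats) <- paste0("track_", seq_along(mats))
  }
  df <- bind_rows(lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    tibble(track = nm, offset = attr(m, "bin_mids"),
           mean_signal = colMeans(m, na.rm = TRUE))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_signal,
                                   colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from peak center (bp)", y = "mean signal",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Paired spacing distributions for a nucleosome comparison
#'
#' @param object A `spacing_comparison` from [compare_spacing()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spacing_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$pairs, c("distance_a", "distance_b"),
    names_to = "condition", values_to = "spacing")
  df$condition <- ifelse(df$condition == "distance_a", object$label_a,
                         object$label_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spacing,
                                   fill = .data$condition)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = c(object$median_a, object$median_b),
                        linetype = "dashed") +
    ggplot2::labs(x = "+1/-1 nucleosome spacing (bp)", y = "density",
                  fill = NULL,
                  title = sprintf("Spacing medians %g vs %g bp (p = %.3g)",
                                  object$median_a, object$median_b,
                                  object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Histogram of per-sample signature scores by group
#'
#' @param object A `signature_score` from [signature_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_score <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$score,
                                               fill = .data$group)) +
    ggplot2::geom_histogram(bins = 15, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "signature score (baseline z units)", y = "samples",
                  fill = NULL,
                  title = sprintf("Signature '%s'", object$signature)) +
    ggplot2::theme_minimal()
}
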