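#' Plot the objective-function trajectory of a fuzzy c-means fit
#'
#' The objective is non-increasing by construction; a flat tail indicates
#' convergence.
#'
#' @param object An `fcm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcm_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective), objective = object$objective)
  ggplot2::ggplot(df, ggplot2::aes(iteration, objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Iteration", y = "FCM objective",
      title = sprintf("Fuzzy c-means convergence (%d clusters)", ncol(object$membership))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the index comparison of an experiment
#'
#' One panel per validity index, one bar per feature method. Accuracy is
#' better high; partition entropy and the scatter-trace ratio are better
#' low.
#'
#' @param object A `cs_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cs_experiment <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("method", "accuracy", "etp", "ratio")],
    -method, names_to = "index", values_to = "value"
  )
  df$index <- factor(df$index, levels = c("accuracy", "etp", "ratio"),
                     labels = c("Accuracy", "Partition entropy", "tr(Sw)/tr(Sb)"))
  ggplot2::ggplot(df, ggplot2::aes(method, value, fill = method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Feature-set comparison") +
    ggplot2::theme_minimal()
}

#' Scatter plot of two feature dimensions
#'
#' Quick look at a feature matrix: two chosen feature columns against each
#' other, colored by label when given.
#'
#' @param features A feature tibble from [extract_features()].
#' @param labels Optional class labels, one per row.
#' @param dims Which two feature columns (by position, excluding `id`) to
#'   plot.
#' @return A ggplot.
#' @export
plot_features <- function(features, labels = NULL, dims = c(1L, 2L)) {
  x <- as_feature_matrix(features)
  if (length(dims) != 2L || any(dims < 1L) || any(dims > ncol(x))) {
    abort("`dims` must select two feature columns.", class = "trisense_parameter_error")
  }
  df <- tibble(
    f1 = x[, dims[1]],
    f2 = x[, dims[2]],
    label = if (is.null(labels)) "all" else as.character(labels)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = colnames(x)[dims[1]], y = colnames(x)[dims[2]],
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::guides(colour = "none") else p
}
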