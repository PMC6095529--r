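#' Heatmap of a confusion matrix
#'
#' Actual categories on the y axis (first row on top) against response
#' categories on the x axis, tile fill and printed value giving the cell
#' statistic in the matrix's semantics.
#'
#' @param object A [confusion_matrix()].
#' @param digits Digits printed in the tiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, digits = 2, ...) {
  df <- tidy.confusion_matrix(object)
  df$actual <- factor(df$actual, levels = rev(rownames(object$values)))
  df$response <- factor(df$response, levels = colnames(object$values))
  lab <- switch(object$semantics,
                percent_of_responses = "% of responses",
                mean_rating = "mean rating",
                choice_proportion = "choice proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$actual,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$value, digits)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = lab) +
    ggplot2::labs(x = "perceived", y = "actual") +
    ggplot2::theme_minimal()
}

#' Scree and scatter views of a profile embedding
#'
#' `autoplot()` draws the points in the first two components, colored by
#' a label column; `plot_scree()` shows the explained-variance fractions
#' per component.
#'
#' @param object A `profile_embedding` from [pca_profiles()].
#' @param label Name of a label column of the scores to color by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_embedding <- function(object,
                                       label = names(object$scores)[1],
                                       ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data[[label]])) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.profile_embedding
#' @param embedding A `profile_embedding`.
#' @export
plot_scree <- function(embedding) {
  df <- tibble::tibble(
    component = seq_along(embedding$explained_variance),
    explained = embedding$explained_variance
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = df$component) +
    ggplot2::labs(x = "component", y = "explained variance fraction") +
    ggplot2::theme_minimal()
}
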