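#' Elbow plot
#'
#' Distortion against cluster number, with the automatically chosen elbow
#' marked by a dashed line. Set `unsquared = TRUE` to plot the summed
#' (unsquared) Euclidean distances instead of the k-means inertia.
#'
#' @param object An [elbow_scan()].
#' @param unsquared Plot the unsquared distance curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.elbow_scan <- function(object, unsquared = FALSE, ...) {
  df <- object$scan
  df$y <- if (unsquared) df$distortion_unsquared else df$distortion
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of clusters (k)",
                  y = if (unsquared) "distortion (summed distance)" else "distortion (inertia)",
                  title = sprintf("Elbow scan (chosen k = %d)", object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Cluster-center profile plot
#'
#' Bar chart of the per-cluster mean of each summary variable (in the units
#' of the clustered data, i.e. z-scores in the standard workflow), the
#' standard visual check that the clusters are distinct in magnitude and/or
#' direction.
#'
#' @param centers A [cluster_centers_table()] tibble.
#' @return A ggplot object.
#' @export
plot_centers <- function(centers) {
  long <- tidyr::pivot_longer(centers, -c("cluster", "size"),
                              names_to = "variable", values_to = "mean")
  long$variable <- factor(long$variable, levels = unique(long$variable))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variable, y = .data$mean,
                                     fill = factor(.data$cluster))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "cluster center (standardized units)",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' 2-D projection scatter
#'
#' Principal-component projection of the sub-transcripts, optionally colored
#' by cluster membership and annotated with the C/T session labels.
#'
#' @param object A [pca_project()] result.
#' @param solution Optional [kmeans_fit()] solution supplying cluster colors.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_projection <- function(object, solution = NULL, ...) {
  df <- as_tibble(object)
  ve <- attr(object, "var_explained")
  if (!is.null(solution)) df$cluster <- factor(solution$assignments[df$label])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2))
  p <- if (!is.null(solution)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$cluster), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.7, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' Synchrony timeline
#'
#' One tile per session across the treatment span, colored by
#' synchronized/asynchronized status — the at-a-glance distribution view.
#'
#' @param object A [session_synchrony()] outcome.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synchrony_outcome <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = 1,
                                   fill = .data$synchronized)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828")) +
    ggplot2::scale_x_continuous(breaks = df$session) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "session", y = NULL, fill = "synchronized",
                  title = if (!is.null(object$dyad_id)) paste("Dyad", object$dyad_id) else NULL) +
    ggplot2::theme_minimal()
}
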