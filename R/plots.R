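# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_line
#'   scale_color_viridis_c scale_fill_gradient2 labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Map view of a t-SNE embedding
#'
#' @param object A `tsne_embedding`.
#' @param colour_by Optional data frame `compound_id`, `label` colouring
#'   the points (e.g. superclass labels or cluster assignments).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tsne_embedding
#' @export
autoplot.tsne_embedding <- function(object, colour_by = NULL, ...) {
  d <- object$coords
  if (!is.null(colour_by)) {
    colour_by <- tibble::as_tibble(colour_by)
    names(colour_by)[2] <- "label"
    d <- dplyr::left_join(d, colour_by, by = "compound_id")
    p <- ggplot(d, aes(x = .data$y1, y = .data$y2,
                       colour = factor(.data$label))) +
      labs(colour = "label")
  } else {
    p <- ggplot(d, aes(x = .data$y1, y = .data$y2))
  }
  p + geom_point(size = 1, alpha = 0.8) + coord_equal() + theme_minimal() +
    labs(x = "t-SNE 1", y = "t-SNE 2",
         subtitle = paste0("final KL loss ",
                           format(object$final_loss, digits = 4)))
}

#' Loss trace of a t-SNE run
#' @param embedding A `tsne_embedding`.
#' @return A ggplot of KL loss against iteration.
#' @export
plot_loss_trace <- function(embedding) {
  d <- tibble::tibble(iteration = seq_along(embedding$loss_trace),
                      loss = embedding$loss_trace)
  ggplot(d, aes(x = .data$iteration, y = .data$loss)) +
    geom_line() + theme_minimal() +
    labs(x = "iteration", y = "KL loss")
}

#' Heatmap of within/between-cluster cosine similarity
#'
#' @param object A `similarity_summary`.
#' @param ... Unused.
#' @return A ggplot; within-cluster means on the diagonal.
#' @method autoplot similarity_summary
#' @export
autoplot.similarity_summary <- function(object, ...) {
  d <- tidy(object)
  d2 <- d[d$cluster_a != d$cluster_b, ]
  d2[, c("cluster_a", "cluster_b")] <- d2[, c("cluster_b", "cluster_a")]
  ggplot(dplyr::bind_rows(d, d2),
         aes(x = factor(.data$cluster_a), y = factor(.data$cluster_b),
             fill = .data$mean_cosine)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0) +
    theme_minimal() +
    labs(x = "cluster", y = "cluster", fill = "mean cosine")
}

#' Prediction-error overlay map
#'
#' Embedding coordinates coloured by the absolute prediction error of an
#' evaluated model, the view used to look for regions of chemical space a
#' model handles poorly.
#'
#' @param overlay Output of [error_overlay()].
#' @return A ggplot.
#' @export
plot_error_overlay <- function(overlay) {
  ggplot(overlay, aes(x = .data$y1, y = .data$y2,
                      colour = .data$abs_error)) +
    geom_point(size = 1.2) + coord_equal() +
    scale_color_viridis_c() + theme_minimal() +
    labs(x = "t-SNE 1", y = "t-SNE 2", colour = "|error|")
}
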