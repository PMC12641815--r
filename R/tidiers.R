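# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tsne_tidiers
#' @param x A `tsne_embedding`.
#' @param ... Unused.
#' @method tidy tsne_embedding
#' @export
tidy.tsne_embedding <- function(x, ...) x$coords

#' Tidiers for t-SNE embeddings
#'
#' `tidy()` returns the coordinate tibble; `glance()` a one-row summary.
#' @name tsne_tidiers
#' @method glance tsne_embedding
#' @export
glance.tsne_embedding <- function(x, ...) {
  tibble::tibble(n = nrow(x$coords), iterations = x$iterations,
                 final_loss = x$final_loss,
                 perplexity = x$config$perplexity)
}

#' @rdname qsar_tidiers
#' @param x A `qsar_report` or `ols_report`.
#' @param ... Unused.
#' @method tidy qsar_report
#' @export
tidy.qsar_report <- function(x, ...) x$per_compound

#' Tidiers for model performance reports
#'
#' `tidy()` returns per-compound truth/prediction/absolute-error rows;
#' `glance()` the RMSE/MAE summary.
#' @name qsar_tidiers
#' @method glance qsar_report
#' @export
glance.qsar_report <- function(x, ...) {
  tibble::tibble(property = x$property, descriptor_kind = x$descriptor_kind,
                 rmse = x$rmse, mae = x$mae, r_squared = x$r_squared,
                 n_train = x$n_train, n_eval = x$n_eval)
}

#' @rdname qsar_tidiers
#' @method tidy ols_report
#' @export
tidy.ols_report <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname qsar_tidiers
#' @method glance ols_report
#' @export
glance.ols_report <- function(x, ...) {
  tibble::tibble(variables = paste(x$variables, collapse = "+"),
                 rmse = x$rmse, mae = x$mae, r_squared = x$r_squared,
                 n_train = x$n_train, n_eval = x$n_eval)
}

#' @rdname similarity_tidiers
#' @param x A `similarity_summary`.
#' @param ... Unused.
#' @method tidy similarity_summary
#' @export
tidy.similarity_summary <- function(x, ...) {
  b <- x$between
  idx <- which(upper.tri(b, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    cluster_a = as.integer(rownames(b)[idx[, 1]]),
    cluster_b = as.integer(colnames(b)[idx[, 2]]),
    type = ifelse(idx[, 1] == idx[, 2], "within", "between"),
    mean_cosine = b[idx]
  )
}

#' Tidiers for cluster-similarity summaries
#'
#' `tidy()` returns the within/between pairs in long form; `glance()` the
#' overall within vs between means.
#' @name similarity_tidiers
#' @method glance similarity_summary
#' @export
glance.similarity_summary <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$within),
    mean_within = mean(x$within$mean_cosine, na.rm = TRUE),
    mean_between = mean(x$between[upper.tri(x$between)], na.rm = TRUE)
  )
}
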