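#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length and nonzero norm.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity undefined for zero-norm vector")
  sum(u * v) / (nu * nv)
}

#' Assign map clusters
#'
#' Either runs k-means on the 2-D embedding coordinates (10 restarts,
#' lowest within-cluster sum of squares kept, deterministic given `seed`)
#' or passes through a label table. Cluster ids are integers from 1.
#'
#' @param embedding A `tsne_embedding` or a data frame with `compound_id`
#'   and coordinate columns.
#' @param mode `"kmeans"` or `"file"`.
#' @param k Number of clusters for k-means.
#' @param labels Data frame (or CSV path) with `compound_id`, `cluster_id`
#'   for `mode = "file"`.
#' @param seed Integer seed for k-means.
#' @return Tibble `compound_id`, `cluster_id` with attributes `source`,
#'   `k`, `seed`.
#' @export
assign_clusters <- function(embedding, mode = c("kmeans", "file"), k = NULL,
                            labels = NULL, seed = 1L) {
  mode <- rlang::arg_match(mode)
  coords <- if (inherits(embedding, "tsne_embedding")) embedding$coords
            else tibble::as_tibble(embedding)
  if (mode == "file") {
    if (is.character(labels)) {
      labels <- readr::read_csv(labels, show_col_types = FALSE)
    }
    if (is.null(labels)) abort("mode = 'file' needs a label table")
    out <- tibble::as_tibble(labels)[, c("compound_id", "cluster_id")]
    out$cluster_id <- as.integer(out$cluster_id)
    return(structure(out, source = "file", k = length(unique(out$cluster_id)),
                     seed = NULL))
  }
  if (is.null(k) || k < 2) abort("kmeans mode needs k >= 2")
  ycols <- grep("^y[0-9]+$", names(coords), value = TRUE)
  m <- as.matrix(coords[, ycols])
  if (k > nrow(m)) abort("k exceeds the number of points")
  km <- withr::with_seed(as.integer(seed),
                         kmeans(m, centers = k, nstart = 10, iter.max = 100))
  structure(tibble::tibble(compound_id = coords$compound_id,
                           cluster_id = as.integer(km$cluster)),
            source = "kmeans", k = as.integer(k), seed = as.integer(seed))
}

#' Within- and between-cluster cosine-similarity summary
#'
#' Mean pairwise cosine similarity of standardized spectra inside each
#' cluster, across every cluster pair, and (optionally) inside each
#' chemical class. The retention-index column, if present, is excluded:
#' similarity is computed on the spectrum only. Values for standardized
#' vectors can be negative. Singleton clusters have no pairs and report
#' `NA`.
#'
#' @param dm A standardized `descriptor_matrix` covering all assigned ids.
#' @param assignment Output of [assign_clusters()].
#' @param classes Optional data frame `compound_id`, `label` (e.g. the
#'   superclass) for the per-class summary.
#' @return Object of class `similarity_summary`: `within` tibble
#'   (`cluster_id`, `n`, `mean_cosine`), `between` symmetric matrix with
#'   within values on the diagonal, `per_class_within` tibble.
#' @export
similarity_summary <- function(dm, assignment, classes = NULL) {
  feats <- attr(dm, "feature_names", exact = TRUE)
  feats <- setdiff(feats, "ri")
  m <- as.matrix(dm[, feats, drop = FALSE])
  rownames(m) <- dm$compound_id
  missing_ids <- setdiff(assignment$compound_id, dm$compound_id)
  if (length(missing_ids) > 0) {
    abort(paste0("matrix rows missing for ", length(missing_ids),
                 " assigned compounds"))
  }
  m <- m[assignment$compound_id, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) abort("zero-norm spectrum row")
  S <- tcrossprod(m / norms)  # full cosine matrix

  cl <- assignment$cluster_id
  ids <- sort(unique(cl))
  k <- length(ids)
  between <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  within <- tibble::tibble(cluster_id = ids, n = NA_integer_,
                           mean_cosine = NA_real_)
  for (a in seq_len(k)) {
    ia <- which(cl == ids[a])
    within$n[a] <- length(ia)
    if (length(ia) > 1) {
      sub <- S[ia, ia]
      within$mean_cosine[a] <- mean(sub[upper.tri(sub)])
    }
    between[a, a] <- within$mean_cosine[a]
    if (a < k) {
      for (b in seq((a + 1), k)) {
        ib <- which(cl == ids[b])
        between[a, b] <- between[b, a] <- mean(S[ia, ib, drop = FALSE])
      }
    }
  }

  per_class <- NULL
  if (!is.null(classes)) {
    classes <- tibble::as_tibble(classes)
    lab <- classes$label[match(assignment$compound_id, classes$compound_id)]
    lv <- sort(unique(stats::na.omit(lab)))
    per_class <- tibble::tibble(label = lv, n = NA_integer_,
                                mean_cosine = NA_real_)
    for (j in seq_along(lv)) {
      ij <- which(!is.na(lab) & lab == lv[j])
      per_class$n[j] <- length(ij)
      if (length(ij) > 1) {
        sub <- S[ij, ij]
        per_class$mean_cosine[j] <- mean(sub[upper.tri(sub)])
      }
    }
  }
  structure(list(within = within, between = between,
                 per_class_within = per_class),
            class = "similarity_summary")
}

#' Class composition of clusters
#'
#' Fraction of each class label within every cluster, over labeled
#' members; the dominant label is flagged. Clusters with no labeled member
#' are omitted with a message.
#'
#' @param assignment Output of [assign_clusters()].
#' @param classes Data frame `compound_id`, `label`.
#' @return Tibble `cluster_id`, `label`, `n`, `fraction`, `dominant`.
#' @export
class_composition <- function(assignment, classes) {
  classes <- tibble::as_tibble(classes)
  joined <- dplyr::left_join(assignment, classes, by = "compound_id")
  labeled <- joined[!is.na(joined$label), ]
  empty <- setdiff(unique(joined$cluster_id), unique(labeled$cluster_id))
  if (length(empty) > 0) {
    inform(paste0("clusters without labeled members omitted: ",
                  paste(empty, collapse = ", ")))
  }
  labeled %>%
    dplyr::count(.data$cluster_id, .data$label, name = "n") %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  dominant = .data$fraction == max(.data$fraction)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$cluster_id, dplyr::desc(.data$fraction))
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat("# similarity_summary:", nrow(x$within), "clusters; mean within",
      format(mean(x$within$mean_cosine, na.rm = TRUE), digits = 4),
      "; mean between",
      format(mean(x$between[upper.tri(x$between)], na.rm = TRUE), digits = 4),
      "\n")
  invisible(x)
}
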