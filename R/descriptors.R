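#' Bin a peak list onto the unit-mass grid
#'
#' Each peak is assigned to its nominal (round-half-up) mass bin; peaks
#' colliding in a bin are summed. Optionally the vector is rescaled so the
#' base peak equals 999 (the NIST convention).
#'
#' @param peaks Tibble or data frame with `mz` and `intensity`.
#' @param mz_min,mz_max Inclusive integer bin range.
#' @param base_peak_normalize Rescale so the maximum is 999.
#' @param compound_id Used in the error message when a peak falls outside
#'   the range.
#' @return Numeric vector of length `mz_max - mz_min + 1`, names `mz_<m>`.
#' @export
bin_spectrum <- function(peaks, mz_min = 35L, mz_max = 600L,
                         base_peak_normalize = TRUE,
                         compound_id = "<unnamed>") {
  nom <- nominal_mass(peaks$mz)
  if (any(nom < mz_min) || any(nom > mz_max)) {
    bad <- nom[nom < mz_min | nom > mz_max][1]
    abort(paste0("compound ", compound_id, ": nominal mass ", bad,
                 " outside bin range [", mz_min, ", ", mz_max, "]"))
  }
  v <- numeric(mz_max - mz_min + 1L)
  idx <- nom - mz_min + 1L
  for (j in seq_along(idx)) v[idx[j]] <- v[idx[j]] + peaks$intensity[j]
  if (base_peak_normalize && max(v) > 0) v <- v / max(v) * 999
  names(v) <- paste0("mz_", mz_min:mz_max)
  v
}

#' Build the analytical descriptor matrix
#'
#' One row per compound; columns are the unit-mass intensity bins over the
#' dataset's global m/z frame, plus a final `ri` column unless
#' `include_ri = FALSE` (the "without RI" variant). When RI is included,
#' records lacking one are dropped with a message. With
#' `standardize = TRUE` every column is z-scored for embedding; the
#' unstandardized form is the one fed to the boosted models, where
#' monotone-invariant tree splits make scaling irrelevant.
#'
#' @param data A [spectra_dataset()].
#' @param include_ri Append the retention index as the last feature.
#' @param standardize Z-score all columns (constant columns become all-zero
#'   and are recorded in the `constant_columns` attribute).
#' @param base_peak_normalize Passed to [bin_spectrum()].
#' @param range Optional `c(mz_min, mz_max)` override of the dataset frame.
#' @return A `descriptor_matrix` tibble: `compound_id` plus feature
#'   columns, with attributes `descriptor_kind`, `standardized`,
#'   `feature_names`, and when standardized `column_means`/`column_sds`.
#' @export
build_analytical_matrix <- function(data, include_ri = TRUE,
                                    standardize = FALSE,
                                    base_peak_normalize = TRUE,
                                    range = NULL) {
  if (nrow(data) == 0) abort("empty dataset")
  rng <- if (is.null(range)) mz_range(data) else as.integer(range)
  keep <- rep(TRUE, nrow(data))
  if (include_ri) {
    keep <- !is.na(data$ri)
    if (any(!keep)) {
      inform(paste0("dropped ", sum(!keep), " records lacking RI"))
    }
    if (!any(keep)) abort("no records with RI available")
  }
  d <- data[keep, ]
  m <- t(vapply(seq_len(nrow(d)), function(i) {
    bin_spectrum(d$peaks[[i]], rng[1], rng[2], base_peak_normalize,
                 d$compound_id[i])
  }, numeric(rng[2] - rng[1] + 1L)))
  if (include_ri) m <- cbind(m, ri = d$ri)
  rownames(m) <- d$compound_id
  dm <- new_descriptor_matrix(m, d$compound_id,
                              kind = if (include_ri) "analytical" else "analytical_no_ri")
  if (standardize) standardize_descriptors(dm) else dm
}

new_descriptor_matrix <- function(m, ids, kind, standardized = FALSE,
                                  means = NULL, sds = NULL,
                                  extra_attrs = list()) {
  out <- tibble::as_tibble(as.data.frame(m, optional = TRUE))
  out <- tibble::add_column(out, compound_id = ids, .before = 1)
  out <- structure(out, class = c("descriptor_matrix", class(tibble::tibble())),
                   descriptor_kind = kind, standardized = standardized,
                   feature_names = colnames(m),
                   column_means = means, column_sds = sds)
  for (a in names(extra_attrs)) attr(out, a) <- extra_attrs[[a]]
  out
}

#' Feature columns of a descriptor matrix as a plain matrix
#' @param dm A `descriptor_matrix`.
#' @return Numeric matrix with compound ids as row names.
#' @export
descriptor_features <- function(dm) {
  fn <- attr(dm, "feature_names", exact = TRUE)
  m <- as.matrix(dm[, fn, drop = FALSE])
  rownames(m) <- dm$compound_id
  m
}

#' Z-score the columns of a descriptor matrix
#'
#' Non-constant columns get sample mean 0 and sd 1; constant columns are
#' set to all-zero (not dropped, so feature indices stay stable) and listed
#' in the `constant_columns` attribute. Applying the operation to an
#' already-standardized matrix changes nothing beyond rounding.
#'
#' @param dm A `descriptor_matrix`.
#' @return The standardized matrix.
#' @export
standardize_descriptors <- function(dm) {
  m <- descriptor_features(dm)
  mu <- colMeans(m)
  sds <- apply(m, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  ms <- sweep(m, 2, mu, "-")
  ms[, !const] <- sweep(ms[, !const, drop = FALSE], 2, sds[!const], "/")
  ms[, const] <- 0
  new_descriptor_matrix(ms, dm$compound_id,
                        kind = attr(dm, "descriptor_kind"),
                        standardized = TRUE, means = mu, sds = sds,
                        extra_attrs = list(constant_columns = colnames(m)[const]))
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("# descriptor_matrix:", attr(x, "descriptor_kind"), "-", nrow(x),
      "compounds x", length(attr(x, "feature_names")), "features",
      if (isTRUE(attr(x, "standardized"))) "(standardized)" else "", "\n")
  NextMethod()
}
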