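#' Six spectral summary indicators
#'
#' From each binned unit-mass spectrum: the intensity-weighted mean m/z
#' (`center_mz`), the m/z of the most intense bin (`maxint_mz`; ties go to
#' the lowest m/z), the highest occupied m/z (`max_mz`), the
#' intensity-weighted standard deviation of m/z (`sd_mz`), the count of
#' nonzero bins (`bin_num`), and the retention index carried through.
#' With `weighted = FALSE` the mean and standard deviation are computed
#' over the occupied bin positions without intensity weights. All six
#' values are invariant to uniform intensity rescaling.
#'
#' @param data A [spectra_dataset()], or a single binned spectrum vector
#'   from [bin_spectrum()].
#' @param weighted Intensity-weight `center_mz` and `sd_mz` (default).
#' @param base_peak_normalize Passed to [bin_spectrum()] (does not affect
#'   the indicators).
#' @return For a dataset: tibble `compound_id`, `center_mz`, `maxint_mz`,
#'   `max_mz`, `sd_mz`, `bin_num`, `ri`. For a vector: a one-row tibble
#'   without `compound_id`.
#' @export
compute_indicators <- function(data, weighted = TRUE,
                               base_peak_normalize = TRUE) {
  if (is.numeric(data)) {
    return(indicator_row(data, ri = NA_real_, weighted = weighted))
  }
  stopifnot(inherits(data, "spectra_dataset"))
  rng <- mz_range(data)
  rows <- lapply(seq_len(nrow(data)), function(i) {
    v <- bin_spectrum(data$peaks[[i]], rng[1], rng[2], base_peak_normalize,
                      data$compound_id[i])
    out <- indicator_row(v, ri = data$ri[i], weighted = weighted)
    tibble::add_column(out, compound_id = data$compound_id[i], .before = 1)
  })
  dplyr::bind_rows(rows)
}

indicator_row <- function(v, ri, weighted = TRUE) {
  mzs <- if (is.null(names(v))) as.numeric(seq_along(v))
         else as.numeric(sub("mz_", "", names(v)))
  nz <- v > 0
  if (!any(nz)) abort("all-zero spectrum vector")
  if (weighted) {
    w <- v[nz] / sum(v[nz])
    center <- sum(w * mzs[nz])
    sdv <- sqrt(sum(w * (mzs[nz] - center)^2))
  } else {
    center <- mean(mzs[nz])
    sdv <- sqrt(mean((mzs[nz] - center)^2))
  }
  imax <- which(v == max(v))[1]  # tie -> lowest m/z
  tibble::tibble(center_mz = center, maxint_mz = mzs[imax],
                 max_mz = max(mzs[nz]), sd_mz = sdv,
                 bin_num = sum(nz), ri = ri)
}

INDICATOR_VARS <- c("center_mz", "maxint_mz", "max_mz", "sd_mz", "bin_num", "ri")

#' Ordinary least squares on spectral indicators
#'
#' Fits `property ~ selected indicators` on the training compounds via the
#' QR decomposition and reports RMSE/MAE on the evaluation pool. Rows
#' lacking RI are dropped (with a message) when RI is among the
#' regressors. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param indicators Indicator tibble from [compute_indicators()].
#' @param labels Named numeric vector or data frame of true values.
#' @param variables Subset of
#'   `c("center_mz", "maxint_mz", "max_mz", "sd_mz", "bin_num", "ri")`.
#' @param train_ids,eval_ids Disjoint compound id sets.
#' @return Object of class `ols_report`: `coefficients` (intercept first),
#'   `variables`, `rmse`, `mae`, `per_compound`, `n_train`, `n_eval`.
#' @export
fit_ols <- function(indicators, labels, variables, train_ids, eval_ids) {
  stopifnot(all(variables %in% INDICATOR_VARS))
  labels <- labels_vector(labels)
  tab <- tibble::as_tibble(indicators)
  if ("ri" %in% variables) {
    drop <- tab$compound_id[is.na(tab$ri)]
    if (length(drop) > 0) {
      inform(paste0("dropped ", length(drop), " rows lacking RI"))
      train_ids <- setdiff(train_ids, drop)
      eval_ids <- setdiff(eval_ids, drop)
    }
  }
  if (length(intersect(train_ids, eval_ids)) > 0) {
    abort("train and eval ids overlap")
  }
  X <- as.matrix(tab[match(train_ids, tab$compound_id), variables,
                     drop = FALSE])
  y <- unname(labels[train_ids])
  if (nrow(X) <= length(variables) + 1) abort("too few training rows")
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("rank-deficient design; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qrd, y)
  Xe <- cbind(1, as.matrix(tab[match(eval_ids, tab$compound_id), variables,
                               drop = FALSE]))
  preds <- drop(Xe %*% beta)
  truth <- unname(labels[eval_ids])
  resid <- truth - preds
  structure(list(
    variables = variables, coefficients = beta,
    rmse = sqrt(mean(resid^2)), mae = mean(abs(resid)),
    r_squared = 1 - sum(resid^2) / sum((truth - mean(truth))^2),
    per_compound = tibble::tibble(compound_id = eval_ids, truth = truth,
                                  predicted = preds, abs_error = abs(resid)),
    n_train = length(train_ids), n_eval = length(eval_ids)
  ), class = "ols_report")
}

#' @export
print.ols_report <- function(x, ...) {
  cat("# ols_report: ~", paste(x$variables, collapse = " + "),
      "- RMSE", format(x$rmse, digits = 4),
      "MAE", format(x$mae, digits = 4), "\n")
  invisible(x)
}

#' Indicator-model comparison table
#'
#' For each property, fits the full-spectrum boosted model (with and
#' without RI), the all-six-variable linear model, and one single-variable
#' linear model per indicator, all on a shared split, and tabulates
#' RMSE/MAE on the pooled validation + test compounds.
#'
#' @param data A [spectra_dataset()].
#' @param properties Property columns to model.
#' @param fractions,seed Split specification.
#' @param params Boosting hyperparameters for the full-spectrum models.
#' @param include_boosted Also fit the boosted analytical models.
#' @param single_variables Which single-variable linear models to include.
#' @return Tibble `property`, `model`, `rmse`, `mae`, `n_train`, `n_eval`.
#' @export
indicator_comparison <- function(data, properties = property_names(),
                                 fractions = c(0.7, 0.15, 0.15), seed = 1L,
                                 params = qsar_params(),
                                 include_boosted = TRUE,
                                 single_variables = INDICATOR_VARS) {
  ind <- compute_indicators(data)
  dm_ri <- if (include_boosted) build_analytical_matrix(data, include_ri = TRUE)
  dm_nori <- if (include_boosted) build_analytical_matrix(data, include_ri = FALSE)
  rows <- list()
  add <- function(property, model, rmse, mae, n_train, n_eval) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      property = property, model = model, rmse = rmse, mae = mae,
      n_train = n_train, n_eval = n_eval)
  }
  for (prop in properties) {
    sp <- split_dataset(data, property = prop, fractions = fractions,
                        seed = seed)
    labels <- stats::setNames(data[[prop]], data$compound_id)
    tr <- sp$compound_id[sp$split == "train"]
    ev <- sp$compound_id[sp$split %in% c("valid", "test")]
    if (include_boosted) {
      for (spec in list(list(dm = dm_ri, name = "boosted_analytical"),
                        list(dm = dm_nori, name = "boosted_analytical_no_ri"))) {
        tr2 <- intersect(tr, spec$dm$compound_id)
        ev2 <- intersect(ev, spec$dm$compound_id)
        mod <- train_qsar(spec$dm, labels, tr2, params = params,
                          property = prop)
        rep <- evaluate_qsar(mod, spec$dm, labels, ev2)
        add(prop, spec$name, rep$rmse, rep$mae, rep$n_train, rep$n_eval)
      }
    }
    all6 <- fit_ols(ind, labels, INDICATOR_VARS, tr, ev)
    add(prop, "ols_all_six", all6$rmse, all6$mae, all6$n_train, all6$n_eval)
    for (v in single_variables) {
      f <- fit_ols(ind, labels, v, tr, ev)
      add(prop, paste0("ols_", v), f$rmse, f$mae, f$n_train, f$n_eval)
    }
  }
  dplyr::bind_rows(rows)
}
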