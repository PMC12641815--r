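#' Train/validation/test split
#'
#' Records carrying a finite value of the target property are partitioned
#' by seeded uniform random draw into train/validation/test with
#' largest-remainder rounding of the fraction sizes. The evaluation pool
#' downstream is validation plus test unless requested otherwise.
#'
#' @param data A [spectra_dataset()] (or any tibble with `compound_id`).
#' @param property Optional property column restricting eligibility to
#'   rows with a finite value.
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed.
#' @return Tibble `compound_id`, `split` (factor train/valid/test).
#' @export
split_dataset <- function(data, property = NULL,
                          fractions = c(train = 0.7, valid = 0.15, test = 0.15),
                          seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  ids <- data$compound_id
  if (!is.null(property)) {
    ids <- ids[is.finite(data[[property]])]
  }
  n <- length(ids)
  if (n == 0) abort("no eligible records to split")
  # largest-remainder apportionment of n over the three fractions
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  if (any(sizes == 0)) abort("a split would be empty; adjust fractions or n")
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  split <- rep(c("train", "valid", "test"), times = sizes)
  tibble::tibble(compound_id = shuffled,
                 split = factor(split, levels = c("train", "valid", "test"))) %>%
    dplyr::arrange(match(.data$compound_id, ids))
}

#' Boosted-tree hyperparameters
#'
#' Defaults: 300 trees of depth 6, learning rate 0.1, row subsampling 0.8,
#' histogram tree construction, single thread (for reproducibility),
#' squared-error objective.
#'
#' @param nrounds,max_depth,eta,subsample,seed Usual gradient-boosting
#'   controls.
#' @return List of class `qsar_params`.
#' @export
qsar_params <- function(nrounds = 300L, max_depth = 6L, eta = 0.1,
                        subsample = 0.8, seed = 1L) {
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, subsample = subsample, seed = as.integer(seed)),
            class = "qsar_params")
}

labels_vector <- function(labels) {
  if (is.data.frame(labels)) {
    value_col <- setdiff(names(labels), "compound_id")[1]
    stats::setNames(labels[[value_col]], labels$compound_id)
  } else {
    labels
  }
}

#' Train a gradient-boosted QSAR model
#'
#' Fits an XGBoost regression ensemble of the given descriptor matrix rows
#' against a property. Analytical descriptors are used unstandardized:
#' tree splits are invariant to monotone feature rescaling, so
#' standardization would change nothing.
#'
#' @param dm A `descriptor_matrix`.
#' @param labels Named numeric vector (names = compound ids) or a data
#'   frame `compound_id`, value.
#' @param train_ids Compound ids to train on (>= 20).
#' @param params A [qsar_params()].
#' @param property Name recorded on the model.
#' @return Object of class `qsar_model`.
#' @export
train_qsar <- function(dm, labels, train_ids, params = qsar_params(),
                       property = "property") {
  labels <- labels_vector(labels)
  m <- descriptor_features(dm)
  missing <- setdiff(train_ids, rownames(m))
  if (length(missing) > 0) abort("training ids missing from matrix")
  y <- labels[train_ids]
  if (anyNA(y)) abort("labels missing for some training ids")
  if (length(train_ids) < 20) abort("need at least 20 training rows")
  X <- m[train_ids, , drop = FALSE]
  booster <- withr::with_seed(params$seed, xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  max_depth = params$max_depth, eta = params$eta,
                  subsample = params$subsample, nthread = 1,
                  tree_method = "hist", seed = params$seed),
    data = xgboost::xgb.DMatrix(X, label = unname(y)),
    nrounds = params$nrounds, verbose = 0))
  structure(list(booster = booster,
                 feature_names = attr(dm, "feature_names", exact = TRUE),
                 descriptor_kind = attr(dm, "descriptor_kind", exact = TRUE),
                 property = property, train_ids = train_ids, params = params),
            class = "qsar_model")
}

#' @export
predict.qsar_model <- function(object, dm, ...) {
  m <- descriptor_features(dm)[, object$feature_names, drop = FALSE]
  p <- predict(object$booster, xgboost::xgb.DMatrix(m))
  stats::setNames(p, rownames(m))
}

#' Evaluate a QSAR model on held-out compounds
#'
#' @param model A `qsar_model` (or `ols_model`).
#' @param dm The descriptor matrix (same feature schema as training).
#' @param labels Named numeric vector or data frame of true values.
#' @param eval_ids Evaluation compound ids; must be disjoint from the
#'   model's training ids.
#' @return Object of class `qsar_report` with `rmse`, `mae`, `r_squared`,
#'   `per_compound` tibble (`compound_id`, `truth`, `predicted`,
#'   `abs_error`), `n_train`, `n_eval`.
#' @export
evaluate_qsar <- function(model, dm, labels, eval_ids) {
  labels <- labels_vector(labels)
  if (length(eval_ids) == 0) abort("empty evaluation pool")
  if (length(intersect(eval_ids, model$train_ids)) > 0) {
    abort("evaluation ids overlap the training set")
  }
  preds <- predict(model, dm)[eval_ids]
  truth <- labels[eval_ids]
  if (anyNA(truth) || anyNA(preds)) abort("missing labels or predictions")
  resid <- truth - preds
  structure(list(
    property = model$property,
    descriptor_kind = model$descriptor_kind,
    rmse = sqrt(mean(resid^2)),
    mae = mean(abs(resid)),
    r_squared = 1 - sum(resid^2) / sum((truth - mean(truth))^2),
    per_compound = tibble::tibble(compound_id = eval_ids,
                                  truth = unname(truth),
                                  predicted = unname(preds),
                                  abs_error = unname(abs(resid))),
    n_train = length(model$train_ids),
    n_eval = length(eval_ids)
  ), class = "qsar_report")
}

#' @export
print.qsar_report <- function(x, ...) {
  cat("# qsar_report:", x$property, "/", x$descriptor_kind,
      "- RMSE", format(x$rmse, digits = 4),
      "MAE", format(x$mae, digits = 4),
      "(n_train", x$n_train, ", n_eval", paste0(x$n_eval, ")"), "\n")
  invisible(x)
}

#' Benchmark descriptor kinds across properties
#'
#' Trains one boosted model per (property, descriptor kind) with the split
#' shared across kinds for the same property, and evaluates on the pooled
#' validation + test compounds. Analytical matrices enter unstandardized.
#'
#' @param data A [spectra_dataset()].
#' @param properties Property columns to model.
#' @param kinds Descriptor kinds: any of `"analytical"`,
#'   `"analytical_no_ri"`, `"ecfp6"`, `"maccs"`, `"pubchem"`,
#'   `"topological"`.
#' @param fractions,seed Split specification (see [split_dataset()]).
#' @param params Boosting hyperparameters.
#' @param evaluation_pool `"valid_plus_test"` (default) or `"test_only"`.
#' @return Tibble `property`, `descriptor_kind`, `rmse`, `mae`,
#'   `r_squared`, `n_train`, `n_eval`, with the reports in the `report`
#'   list-column.
#' @export
compare_descriptors <- function(data, properties = property_names(),
                                kinds = c("analytical", "analytical_no_ri"),
                                fractions = c(0.7, 0.15, 0.15), seed = 1L,
                                params = qsar_params(),
                                evaluation_pool = c("valid_plus_test",
                                                    "test_only")) {
  evaluation_pool <- rlang::arg_match(evaluation_pool)
  matrices <- lapply(stats::setNames(kinds, kinds), function(kd) {
    switch(kd,
      analytical = build_analytical_matrix(data, include_ri = TRUE),
      analytical_no_ri = build_analytical_matrix(data, include_ri = FALSE),
      build_molecular_matrix(data, kind = kd))
  })
  rows <- list()
  for (prop in properties) {
    sp <- split_dataset(data, property = prop, fractions = fractions,
                        seed = seed)
    labels <- stats::setNames(data[[prop]], data$compound_id)
    train_ids <- sp$compound_id[sp$split == "train"]
    eval_ids <- if (evaluation_pool == "valid_plus_test") {
      sp$compound_id[sp$split %in% c("valid", "test")]
    } else {
      sp$compound_id[sp$split == "test"]
    }
    for (kd in kinds) {
      dm <- matrices[[kd]]
      tr <- intersect(train_ids, dm$compound_id)
      ev <- intersect(eval_ids, dm$compound_id)
      model <- train_qsar(dm, labels, tr, params = params, property = prop)
      rep <- evaluate_qsar(model, dm, labels, ev)
      rows[[length(rows) + 1]] <- tibble::tibble(
        property = prop, descriptor_kind = kd, rmse = rep$rmse,
        mae = rep$mae, r_squared = rep$r_squared,
        n_train = rep$n_train, n_eval = rep$n_eval, report = list(rep))
    }
  }
  dplyr::bind_rows(rows)
}

#' Join per-compound prediction errors onto map coordinates
#'
#' Produces the table behind error-overlay maps: embedding coordinates
#' with each evaluated compound's absolute prediction error. Report
#' compounds absent from the embedding are excluded with a message.
#'
#' @param embedding A `tsne_embedding` or coordinate data frame.
#' @param report A `qsar_report`.
#' @return Tibble `compound_id`, `y1`, `y2`, ..., `abs_error`.
#' @export
error_overlay <- function(embedding, report) {
  coords <- if (inherits(embedding, "tsne_embedding")) embedding$coords
            else tibble::as_tibble(embedding)
  pc <- report$per_compound
  missing <- setdiff(pc$compound_id, coords$compound_id)
  if (length(missing) > 0) {
    inform(paste0(length(missing),
                  " evaluated compounds missing from the embedding"))
  }
  dplyr::inner_join(coords, pc[, c("compound_id", "abs_error")],
                    by = "compound_id")
}
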