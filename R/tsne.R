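# Dense, exact t-SNE. Kept deliberately free of approximations
# (no Barnes-Hut) so every quantity can be checked against brute-force
# oracles at small n.

#' t-SNE configuration
#'
#' Perplexity and the PCA pre-reduction dimension default to 30. The
#' optimizer is plain momentum gradient descent on the Kullback--Leibler
#' loss: learning rate 200 (the loss is scale-free after the affinities are
#' normalized to a joint distribution), momentum 0.5 until iteration 250
#' and 0.8 after, 1000 iterations. Early exaggeration (multiply the input
#' affinities by a factor for an initial stretch) is available but off by
#' default so the recorded loss trace refers to the true loss throughout.
#'
#' @param perplexity Target perplexity (effective neighbor count).
#' @param initial_dims PCA pre-reduction dimensionality.
#' @param out_dims Output dimensionality.
#' @param n_iter Gradient-descent iterations.
#' @param eta Learning rate.
#' @param momentum_early,momentum_late,momentum_switch Momentum schedule:
#'   `momentum_early` before iteration `momentum_switch`, `momentum_late`
#'   after.
#' @param exaggeration_factor,exaggeration_iter Early-exaggeration factor
#'   and duration; factor 1 disables it.
#' @param seed Integer seed for the Gaussian initialization.
#' @return List of class `tsne_config`.
#' @export
tsne_config <- function(perplexity = 30, initial_dims = 30L, out_dims = 2L,
                        n_iter = 1000L, eta = 200,
                        momentum_early = 0.5, momentum_late = 0.8,
                        momentum_switch = 250L,
                        exaggeration_factor = 1, exaggeration_iter = 50L,
                        seed = 1L) {
  stopifnot(eta > 0, momentum_early >= 0, momentum_early < 1,
            momentum_late >= 0, momentum_late < 1, perplexity > 0)
  structure(list(perplexity = perplexity, initial_dims = initial_dims,
                 out_dims = out_dims, n_iter = n_iter, eta = eta,
                 momentum_early = momentum_early,
                 momentum_late = momentum_late,
                 momentum_switch = momentum_switch,
                 exaggeration_factor = exaggeration_factor,
                 exaggeration_iter = exaggeration_iter,
                 seed = as.integer(seed)),
            class = "tsne_config")
}

squared_distances <- function(X) {
  s <- rowSums(X^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Perplexity-calibrated conditional affinities
#'
#' For each point i the Gaussian bandwidth sigma_i is found by binary
#' search so that the Shannon entropy (bits) of the conditional
#' distribution p_(j|i) satisfies 2^H = target perplexity to within 1e-6
#' bits. Rows sum to one; the diagonal is zero.
#'
#' @param X Numeric matrix, one row per point.
#' @param perplexity Target perplexity; must be below n - 1.
#' @param tol Entropy tolerance (bits) of the binary search.
#' @param max_iter Binary-search iterations per point.
#' @return List with `P_cond` (n x n conditional matrix) and `sigmas`.
#' @export
conditional_affinities <- function(X, perplexity, tol = 1e-6,
                                   max_iter = 200L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) abort("need at least 3 points")
  if (!all(is.finite(X))) abort("non-finite values in input")
  if (perplexity >= n - 1) abort("perplexity must be below n - 1")
  d2 <- squared_distances(X)
  target_h <- log2(perplexity)
  P <- matrix(0, n, n)
  sigmas <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1            # beta = 1 / (2 sigma^2)
    beta_lo <- -Inf
    beta_hi <- Inf
    for (it in seq_len(max_iter)) {
      # shift by the smallest distance so the largest weight never
      # underflows; the shift cancels in the normalization
      w <- exp(-(di - min(di)) * beta)
      p <- w / sum(w)
      h <- -sum(ifelse(p > 0, p * log2(p), 0))
      if (abs(h - target_h) < tol) break
      if (h > target_h) {       # too flat: tighten the kernel
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
    sigmas[i] <- sqrt(1 / (2 * beta))
  }
  list(P_cond = P, sigmas = sigmas)
}

#' Symmetrized joint affinities
#'
#' `P = (P_cond + t(P_cond)) / (2n)`, turning the row-stochastic
#' conditional matrix into a single joint distribution over ordered pairs
#' (total mass one).
#'
#' @param P_cond Conditional affinity matrix with rows summing to 1.
#' @param sigmas,perplexity Optional calibration results carried along for
#'   inspection.
#' @return List of class `affinity_model` with `P`, and pass-through
#'   `sigmas`/`perplexity` when supplied.
#' @export
symmetrize_affinities <- function(P_cond, sigmas = NULL, perplexity = NULL) {
  n <- nrow(P_cond)
  P <- (P_cond + t(P_cond)) / (2 * n)
  structure(list(P = P, sigmas = sigmas, perplexity = perplexity),
            class = "affinity_model")
}

#' Low-dimensional Student-t affinities
#'
#' `q_ij` proportional to `(1 + ||y_i - y_j||^2)^-1`, normalized over all
#' ordered pairs to sum to one, with entries floored at 1e-12 so the loss
#' stays finite.
#'
#' @param Y Embedding coordinate matrix.
#' @return n x n matrix Q with zero diagonal.
#' @export
low_dim_affinities <- function(Y) {
  if (!all(is.finite(Y))) abort("non-finite embedding coordinates")
  num <- 1 / (1 + squared_distances(as.matrix(Y)))
  diag(num) <- 0
  Q <- num / sum(num)
  pmax(Q, 1e-12) * (num > 0)  # keep diagonal at zero
}

#' Kullback--Leibler embedding loss
#'
#' `sum over pairs of p * log(p / q)`; pairs with `p = 0` contribute
#' nothing. Non-negative by Gibbs' inequality.
#'
#' @param P,Q Joint affinity matrices of the same shape.
#' @return Scalar loss.
#' @export
kl_loss <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  pos <- P > 0
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Gradient of the KL loss with respect to the embedding
#'
#' Closed form `4 * sum_j (p_ij - q_ij) (y_i - y_j) / (1 + ||y_i - y_j||^2)`.
#' Rows sum to zero (the loss is translation invariant).
#'
#' @param P,Q Joint affinities.
#' @param Y Current embedding.
#' @return Matrix with the shape of `Y`.
#' @export
tsne_gradient <- function(P, Q, Y) {
  Y <- as.matrix(Y)
  num <- 1 / (1 + squared_distances(Y))
  diag(num) <- 0
  W <- 4 * (P - Q) * num
  diag(W) <- 0
  # grad_i = sum_j W_ij (y_i - y_j)
  sweep(Y, 1, rowSums(W), "*") - W %*% Y
}

#' Fit a t-SNE embedding
#'
#' The input is PCA-reduced to `initial_dims` components (skipped when it
#' already has fewer columns), pairwise affinities are calibrated to the
#' target perplexity, the map is initialized from a Gaussian with standard
#' deviation 1e-4 using `config$seed`, and plain momentum gradient descent
#' minimizes the KL loss. The loss is recorded every iteration.
#'
#' @param x A `descriptor_matrix`, data frame with a `compound_id` column,
#'   or plain numeric matrix.
#' @param config A [tsne_config()].
#' @param init `"gaussian"` (default) draws the initial map from a
#'   small-variance Gaussian with `config$seed`; `"pca"` scales the first
#'   principal components of the input to the same small variance, a
#'   deterministic initialization that preserves global structure (useful
#'   when the relative arrangement of well-separated groups matters, as in
#'   homologous-series analyses).
#' @param Y_init Optional explicit initial coordinates (overrides `init`;
#'   used e.g. for permutation-equivariance checks).
#' @param diagnostics Record the total mass of P and Q at every iteration.
#' @return Object of class `tsne_embedding`: `coords` tibble
#'   (`compound_id`, `y1`, `y2`, ...), `loss_trace`, `final_loss`,
#'   `iterations`, `sigmas`, `config`, and when requested `psum_trace` /
#'   `qsum_trace`.
#' @export
fit_tsne <- function(x, config = tsne_config(),
                     init = c("gaussian", "pca"), Y_init = NULL,
                     diagnostics = FALSE) {
  init <- rlang::arg_match(init)
  if (inherits(x, "descriptor_matrix")) {
    ids <- x$compound_id
    X <- descriptor_features(x)
  } else if (is.data.frame(x)) {
    ids <- if ("compound_id" %in% names(x)) x$compound_id
           else as.character(seq_len(nrow(x)))
    X <- as.matrix(x[, setdiff(names(x), "compound_id"), drop = FALSE])
  } else {
    X <- as.matrix(x)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  n <- nrow(X)
  if (n < config$out_dims + 1) abort("too few rows to embed")

  if (ncol(X) > config$initial_dims) {
    X <- prcomp(X, center = TRUE, scale. = FALSE,
                rank. = config$initial_dims)$x
  }
  aff <- conditional_affinities(X, config$perplexity)
  P <- symmetrize_affinities(aff$P_cond)$P

  Y <- if (!is.null(Y_init)) {
    as.matrix(Y_init)
  } else if (init == "pca") {
    pcs <- prcomp(X)$x[, seq_len(config$out_dims), drop = FALSE]
    sweep(pcs, 2, apply(pcs, 2, sd), "/") * 1e-4
  } else {
    withr::with_seed(config$seed,
                     matrix(rnorm(n * config$out_dims, sd = 1e-4), nrow = n))
  }
  Y_prev <- Y
  loss_trace <- numeric(config$n_iter)
  psum_trace <- if (diagnostics) numeric(config$n_iter) else NULL
  qsum_trace <- if (diagnostics) numeric(config$n_iter) else NULL

  for (t in seq_len(config$n_iter)) {
    P_eff <- if (t <= config$exaggeration_iter) {
      P * config$exaggeration_factor   # temporary attraction boost
    } else P
    Q <- low_dim_affinities(Y)
    grad <- tsne_gradient(P_eff, Q, Y)
    loss_trace[t] <- kl_loss(P, Q)
    if (!is.finite(loss_trace[t])) {
      abort(paste0("non-finite loss at iteration ", t))
    }
    if (diagnostics) {
      psum_trace[t] <- sum(P_eff)
      qsum_trace[t] <- sum(Q)
    }
    alpha <- if (t < config$momentum_switch) config$momentum_early
             else config$momentum_late
    Y_new <- Y - config$eta * grad + alpha * (Y - Y_prev)
    Y_prev <- Y
    Y <- Y_new
  }

  coords <- tibble::as_tibble(as.data.frame(Y))
  names(coords) <- paste0("y", seq_len(config$out_dims))
  coords <- tibble::add_column(coords, compound_id = ids, .before = 1)
  structure(list(coords = coords, loss_trace = loss_trace,
                 final_loss = kl_loss(P, low_dim_affinities(Y)),
                 iterations = config$n_iter, sigmas = aff$sigmas,
                 config = config, psum_trace = psum_trace,
                 qsum_trace = qsum_trace),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat("# tsne_embedding:", nrow(x$coords), "points,",
      x$iterations, "iterations, final KL loss",
      format(x$final_loss, digits = 5), "\n")
  invisible(x)
}
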