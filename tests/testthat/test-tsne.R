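# Brute-force oracles: every affinity quantity recomputed with explicit
# double loops, independent of the vectorized implementation.

brute_low_dim_q <- function(Y) {
  n <- nrow(Y)
  num <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) num[i, j] <- 1 / (1 + sum((Y[i, ] - Y[j, ])^2))
  }
  num / sum(num)
}

brute_kl <- function(P, Q) {
  out <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) out <- out + P[i, j] * log(P[i, j] / Q[i, j])
  }
  out
}

numeric_gradient <- function(P, Y, h = 1e-5) {
  g <- matrix(0, nrow(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) for (d in seq_len(ncol(Y))) {
    Yp <- Y; Yp[i, d] <- Yp[i, d] + h
    Ym <- Y; Ym[i, d] <- Ym[i, d] - h
    g[i, d] <- (kl_loss(P, low_dim_affinities(Yp)) -
                  kl_loss(P, low_dim_affinities(Ym))) / (2 * h)
  }
  g
}

test_that("conditional affinities are symmetric for equidistant points and row-stochastic", {
  X <- rbind(c(0, 0), c(1, 0), c(-1, 0))  # x2, x3 equidistant from x1
  ca <- conditional_affinities(X, perplexity = 1.9)
  expect_equal(ca$P_cond[1, 2], ca$P_cond[1, 3])
  expect_equal(ca$P_cond[1, 2], 0.5, tolerance = 1e-6)
  X2 <- withr::with_seed(1, matrix(rnorm(60), 12))
  ca2 <- conditional_affinities(X2, perplexity = 4)
  expect_lt(max(abs(rowSums(ca2$P_cond) - 1)), 1e-9)
  expect_true(all(diag(ca2$P_cond) == 0))
})

test_that("the bandwidth search hits the target perplexity", {
  X <- withr::with_seed(2, matrix(rnorm(20 * 5), 20))
  ca <- conditional_affinities(X, perplexity = 5)
  realized <- apply(ca$P_cond, 1, function(p) {
    p <- p[p > 0]
    2^(-sum(p * log2(p)))
  })
  expect_lt(max(abs(realized - 5)), 1e-3)
})

test_that("conditional affinities reject bad inputs", {
  X <- matrix(rnorm(20), 10)
  expect_error(conditional_affinities(X, perplexity = 9), "perplexity")
  X[1, 1] <- NA
  expect_error(conditional_affinities(X, 3), "non-finite")
})

test_that("symmetrization matches the elementwise formula and conserves mass", {
  pc <- random_conditional(10, seed = 3)
  P <- symmetrize_affinities(pc)$P
  n <- 10
  for (i in 1:n) for (j in 1:n) {
    expect_equal(P[i, j], (pc[i, j] + pc[j, i]) / (2 * n))
  }
  expect_equal(sum(P), 1, tolerance = 1e-9)
  # symmetric input: P equals input / n off-diagonal
  sym <- (pc + t(pc)); sym <- sym / rowSums(sym)
  if (isSymmetric(sym)) {
    expect_equal(symmetrize_affinities(sym)$P, sym / n)
  }
})

test_that("low-dimensional affinities follow the Student-t kernel", {
  Y2 <- rbind(c(0, 0), c(5, 5))
  Q2 <- low_dim_affinities(Y2)
  expect_equal(Q2[1, 2], 0.5)   # two points: normalization fixes q
  expect_equal(Q2[2, 1], 0.5)
  # three equidistant points -> all off-diagonal entries 1/6
  Y3 <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  Q3 <- low_dim_affinities(Y3)
  expect_equal(Q3[upper.tri(Q3)], rep(1 / 6, 3), tolerance = 1e-12)
  Y8 <- withr::with_seed(4, matrix(rnorm(16), 8))
  expect_equal(low_dim_affinities(Y8), brute_low_dim_q(Y8),
               tolerance = 1e-12)
})

test_that("the KL loss is zero at Q = P, non-negative, and matches brute force", {
  Y <- withr::with_seed(5, matrix(rnorm(12), 6))
  Q <- low_dim_affinities(Y)
  expect_equal(kl_loss(Q, Q), 0)
  pc <- random_conditional(6, seed = 6)
  P <- symmetrize_affinities(pc)$P
  expect_gte(kl_loss(P, Q), 0)
  expect_equal(kl_loss(P, Q), brute_kl(P, Q), tolerance = 1e-12)
})

test_that("the analytic gradient vanishes at a stationary point and is translation-free", {
  # n = 2: Q is (0.5, 0.5) for any map, so choosing P = Q makes L constant
  Y <- rbind(c(0, 0), c(1, 1))
  P <- matrix(c(0, 0.5, 0.5, 0), 2)
  g <- tsne_gradient(P, low_dim_affinities(Y), Y)
  expect_lt(max(abs(g)), 1e-12)
  pc <- random_conditional(10, seed = 7)
  P10 <- symmetrize_affinities(pc)$P
  Y10 <- withr::with_seed(8, matrix(rnorm(20), 10))
  g10 <- tsne_gradient(P10, low_dim_affinities(Y10), Y10)
  expect_lt(max(abs(colSums(g10))), 1e-10)
})

test_that("the analytic gradient matches central finite differences", {
  pc <- random_conditional(10, seed = 9)
  P <- symmetrize_affinities(pc)$P
  Y <- withr::with_seed(10, matrix(rnorm(20), 10))
  g <- tsne_gradient(P, low_dim_affinities(Y), Y)
  expect_lt(max(abs(g - numeric_gradient(P, Y))), 1e-4)
})

test_that("fit_tsne is seed-deterministic and permutation-equivariant", {
  X <- withr::with_seed(11, matrix(rnorm(30 * 5), 30))
  cfg <- tsne_config(perplexity = 8, n_iter = 100, seed = 4)
  e1 <- fit_tsne(X, cfg)
  e2 <- fit_tsne(X, cfg)
  expect_identical(e1$coords, e2$coords)

  perm <- withr::with_seed(12, sample(30))
  Y0 <- withr::with_seed(4, matrix(rnorm(30 * 2, sd = 1e-4), 30))
  ep <- fit_tsne(X[perm, ], cfg, Y_init = Y0[perm, ])
  eo <- fit_tsne(X, cfg, Y_init = Y0)
  expect_equal(as.matrix(ep$coords[, 2:3]),
               as.matrix(eo$coords[perm, 2:3]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("optimization reduces the loss on a Gaussian mixture", {
  X <- withr::with_seed(13, rbind(matrix(rnorm(25 * 4), 25),
                                  matrix(rnorm(25 * 4, mean = 6), 25)))
  emb <- fit_tsne(X, tsne_config(perplexity = 10, n_iter = 300, seed = 1))
  expect_lt(emb$final_loss, emb$loss_trace[1])
  expect_true(all(is.finite(emb$loss_trace)))
})

test_that("PCA initialization is deterministic without a seed draw", {
  X <- withr::with_seed(14, matrix(rnorm(24 * 6), 24))
  cfg <- tsne_config(perplexity = 6, n_iter = 50, seed = 1)
  expect_identical(fit_tsne(X, cfg, init = "pca")$coords,
                   fit_tsne(X, cfg, init = "pca")$coords)
})
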