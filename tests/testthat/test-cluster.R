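brute_similarity <- function(m, cl, classes = NULL) {
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ids <- sort(unique(cl))
  within <- sapply(ids, function(c0) {
    idx <- which(cl == c0)
    if (length(idx) < 2) return(NA_real_)
    vals <- c()
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) vals <- c(vals, cosine(m[idx[a], ], m[idx[b], ]))
    }
    mean(vals)
  })
  between <- matrix(NA_real_, length(ids), length(ids))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a < b) {
      ia <- which(cl == ids[a]); ib <- which(cl == ids[b])
      vals <- c()
      for (i in ia) for (j in ib) vals <- c(vals, cosine(m[i, ], m[j, ]))
      between[a, b] <- between[b, a] <- mean(vals)
    }
  }
  list(within = within, between = between)
}

test_that("cosine similarity matches analytic cases", {
  expect_equal(cosine_similarity(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("cluster assignment passes labels through and recovers separated clouds", {
  labels <- tibble::tibble(compound_id = c("A", "B", "C"),
                           cluster_id = c(1, 1, 2))
  asn <- assign_clusters(two_clouds(), mode = "file", labels = labels)
  expect_equal(asn$cluster_id, c(1L, 1L, 2L))

  clouds <- two_clouds(n_per = 10, gap = 100)
  km <- assign_clusters(clouds, "kmeans", k = 2, seed = 1)
  expect_equal(length(unique(km$cluster_id[1:10])), 1)
  expect_equal(length(unique(km$cluster_id[11:20])), 1)
  expect_false(km$cluster_id[1] == km$cluster_id[11])
  expect_identical(km, assign_clusters(clouds, "kmeans", k = 2, seed = 1))
  expect_error(assign_clusters(clouds, "kmeans", k = 50, seed = 1), "exceeds")
})

test_that("similarity summaries equal the brute-force oracle", {
  for (rep in 1:5) {
    n <- withr::with_seed(rep, sample(6:12, 1))
    m <- withr::with_seed(rep + 100, matrix(rnorm(n * 5), n))
    cl <- withr::with_seed(rep + 200, sample(1:3, n, replace = TRUE))
    dm <- new_descriptor_matrix(
      `colnames<-`(m, paste0("f", 1:5)),
      sprintf("c%02d", seq_len(n)), kind = "analytical", standardized = TRUE)
    asn <- tibble::tibble(compound_id = sprintf("c%02d", seq_len(n)),
                          cluster_id = cl)
    ss <- similarity_summary(dm, asn)
    oracle <- brute_similarity(m, cl)
    expect_equal(ss$within$mean_cosine, unname(oracle$within),
                 tolerance = 1e-12)
    expect_equal(ss$between[upper.tri(ss$between)],
                 oracle$between[upper.tri(oracle$between)],
                 tolerance = 1e-12)
    expect_true(isSymmetric(ss$between))
  }
})

test_that("summaries ignore the RI column and identical rows give within = 1", {
  m <- rbind(c(1, 2, 3, 1000), c(1, 2, 3, 2000), c(-1, 5, 0, 1500))
  colnames(m) <- c("mz_50", "mz_51", "mz_52", "ri")
  dm <- new_descriptor_matrix(m, c("a", "b", "c"), kind = "analytical")
  asn <- tibble::tibble(compound_id = c("a", "b", "c"),
                        cluster_id = c(1L, 1L, 2L))
  ss <- similarity_summary(dm, asn)
  expect_equal(ss$within$mean_cosine[1], 1)   # RI differences excluded
  expect_true(is.na(ss$within$mean_cosine[2]))  # singleton cluster
})

test_that("summaries are invariant to compound order", {
  d <- small_dataset(n = 30, seed = 21)
  dm <- standardize_descriptors(build_analytical_matrix(d))
  asn <- tibble::tibble(compound_id = d$compound_id,
                        cluster_id = rep(1:3, each = 10))
  ss1 <- similarity_summary(dm, asn)
  perm <- withr::with_seed(3, sample(30))
  ss2 <- similarity_summary(dm[perm, ], asn[perm, ])
  expect_equal(ss1$within, ss2$within, tolerance = 1e-12)
  expect_equal(ss1$between, ss2$between, tolerance = 1e-12)
})

test_that("class composition reports fractions and the dominant class", {
  asn <- tibble::tibble(compound_id = sprintf("c%d", 1:6),
                        cluster_id = c(1L, 1L, 1L, 1L, 2L, 2L))
  classes <- tibble::tibble(
    compound_id = sprintf("c%d", 1:4),
    label = c("Benzenoids", "Benzenoids", "Benzenoids", "Lipids"))
  expect_message(comp <- class_composition(asn, classes), "omitted: 2")
  c1 <- comp[comp$cluster_id == 1, ]
  expect_equal(c1$fraction[c1$label == "Benzenoids"], 0.75)
  expect_equal(c1$fraction[c1$label == "Lipids"], 0.25)
  expect_true(c1$dominant[c1$label == "Benzenoids"])
})

test_that("an all-aromatic dataset yields purely aromatic clusters", {
  d <- generate_dataset(generator_config(n_compounds = 24, seed = 3,
                                         scaffold_mix = c(pcb_like = 1)))
  asn <- tibble::tibble(compound_id = d$compound_id,
                        cluster_id = rep(1:2, 12))
  comp <- class_composition(asn, tibble::tibble(compound_id = d$compound_id,
                                                label = d$superclass))
  expect_true(all(comp$fraction == 1))
  expect_true(all(comp$label == "Benzenoids"))
})
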