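# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

# Small default-condition dataset for unit tests.
small_dataset <- function(n = 80, seed = 42) {
  key <- paste0("d", n, "_", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- suppressMessages(
      generate_dataset(generator_config(n_compounds = n, seed = seed)))
  }
  fixture_env[[key]]
}

# A well-separated pair of 2-D point clouds for clustering tests.
two_clouds <- function(n_per = 10, gap = 100, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      compound_id = sprintf("P%02d", seq_len(2 * n_per)),
      y1 = c(rnorm(n_per), rnorm(n_per) + gap),
      y2 = c(rnorm(n_per), rnorm(n_per))
    )
  })
}

# Random valid conditional-affinity matrix (rows sum to 1, zero diagonal).
random_conditional <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n), n)
    diag(m) <- 0
    m / rowSums(m)
  })
}

write_msp_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".msp",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
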