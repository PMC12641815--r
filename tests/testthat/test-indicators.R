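named_bins <- function(x) {
  v <- numeric(566)
  names(v) <- paste0("mz_", 35:600)
  v[paste0("mz_", names(x))] <- unname(x)
  v
}

test_that("indicators match hand-computed values on toy spectra", {
  # equal intensities at 50 and 150: centre midway, tie broken to lowest m/z
  i1 <- compute_indicators(named_bins(c(`50` = 100, `150` = 100)))
  expect_equal(i1$center_mz, 100)
  expect_equal(i1$maxint_mz, 50)
  expect_equal(i1$max_mz, 150)
  expect_equal(i1$sd_mz, 50)
  expect_equal(i1$bin_num, 2)

  i2 <- compute_indicators(named_bins(c(`77` = 999)))
  expect_equal(i2$center_mz, 77)
  expect_equal(i2$sd_mz, 0)
  expect_equal(i2$maxint_mz, 77)
  expect_equal(i2$max_mz, 77)
  expect_equal(i2$bin_num, 1)

  i3 <- compute_indicators(named_bins(c(`50` = 300, `150` = 100)))
  expect_equal(i3$center_mz, 75)  # (50*300 + 150*100) / 400
  expect_error(compute_indicators(named_bins(c(`50` = 0))), "all-zero")
})

test_that("indicators are invariant to uniform intensity rescaling", {
  for (trial in 1:200) {
    v <- withr::with_seed(trial, {
      v <- numeric(100)
      names(v) <- paste0("mz_", 35:134)
      nz <- sample(100, sample(3:20, 1))
      v[nz] <- runif(length(nz), 1, 999)
      v
    })
    c_scale <- withr::with_seed(trial + 1000, runif(1, 0.01, 100))
    expect_equal(compute_indicators(v), compute_indicators(v * c_scale),
                 tolerance = 1e-12)
  }
})

test_that("maxint_mz never exceeds max_mz on generated data", {
  ind <- compute_indicators(small_dataset(n = 60, seed = 40))
  expect_true(all(ind$maxint_mz <= ind$max_mz))
  expect_true(all(ind$sd_mz >= 0))
})

test_that("unweighted indicators use occupied bins only", {
  v <- named_bins(c(`50` = 300, `150` = 100))
  unw <- compute_indicators(v, weighted = FALSE)
  expect_equal(unw$center_mz, 100)
  expect_equal(unw$sd_mz, 50)
})

test_that("OLS coefficients match the normal-equations solution", {
  for (trial in 1:50) {
    dat <- withr::with_seed(trial, {
      n <- sample(20:40, 1)
      tab <- tibble::tibble(
        compound_id = sprintf("c%02d", 1:n),
        center_mz = runif(n, 50, 300), maxint_mz = runif(n, 50, 300),
        max_mz = runif(n, 100, 500), sd_mz = runif(n, 0, 80),
        bin_num = sample(3:30, n, replace = TRUE), ri = runif(n, 800, 3000))
      vars <- sample(c("center_mz", "maxint_mz", "sd_mz", "ri"),
                     sample(1:3, 1))
      beta <- rnorm(length(vars) + 1)
      y <- beta[1] + as.matrix(tab[, vars]) %*% beta[-1] + rnorm(n)
      list(tab = tab, vars = vars, y = stats::setNames(drop(y), tab$compound_id))
    })
    tr <- dat$tab$compound_id[1:15]
    ev <- setdiff(dat$tab$compound_id, tr)
    fit <- fit_ols(dat$tab, dat$y, dat$vars, tr, ev)
    X <- cbind(1, as.matrix(dat$tab[match(tr, dat$tab$compound_id),
                                    dat$vars]))
    beta_ne <- solve(t(X) %*% X, t(X) %*% dat$y[tr])  # normal equations
    expect_lt(max(abs(fit$coefficients - drop(beta_ne))), 1e-8)
  }
})

test_that("OLS handles exact fits, nesting, and rank deficiency", {
  tab <- tibble::tibble(compound_id = sprintf("c%d", 1:8),
                        center_mz = c(1:8) * 10, maxint_mz = c(1:8) * 10,
                        max_mz = 1:8, sd_mz = rep(1, 8),
                        bin_num = 1:8, ri = 1:8 * 100)
  y <- stats::setNames(3 + 2 * tab$center_mz, tab$compound_id)
  fit <- fit_ols(tab, y, "center_mz", tab$compound_id[1:5],
                 tab$compound_id[6:8])
  expect_lt(fit$rmse, 1e-9)   # collinear target: exact fit carries over

  # adding a variable cannot worsen the training fit
  tab2 <- withr::with_seed(60, dplyr::mutate(tab,
    center_mz = runif(8, 10, 100), sd_mz = runif(8, 1, 20)))
  y2 <- withr::with_seed(61,
    stats::setNames(rnorm(8, 50, 10), tab2$compound_id))
  rmse_of <- function(vars) {
    X <- cbind(1, as.matrix(tab2[, vars]))
    sqrt(mean(stats::lm.fit(X, unname(y2))$residuals^2))
  }
  expect_lte(rmse_of(c("center_mz", "sd_mz")), rmse_of("center_mz"))

  expect_error(fit_ols(tab, y, c("center_mz", "maxint_mz"),
                       tab$compound_id[1:6], tab$compound_id[7:8]),
               "collinear.*maxint_mz")
})

test_that("rows lacking RI are dropped only when RI is a regressor", {
  d <- small_dataset(n = 40, seed = 41)
  d$ri[1:6] <- NA
  ind <- compute_indicators(d)
  lab <- stats::setNames(d$bp, d$compound_id)
  tr <- d$compound_id[1:30]
  ev <- d$compound_id[31:40]
  expect_message(fit <- fit_ols(ind, lab, "ri", tr, ev), "dropped 6")
  expect_equal(fit$n_train, 24)
  expect_silent(fit2 <- fit_ols(ind, lab, "center_mz", tr, ev))
  expect_equal(fit2$n_train, 30)
})

test_that("the indicator comparison table has one row per fitted model", {
  d <- small_dataset(n = 250, seed = 42)
  tab <- suppressMessages(indicator_comparison(
    d, properties = "bp", include_boosted = FALSE,
    single_variables = c("ri", "center_mz")))
  expect_equal(tab$model, c("ols_all_six", "ols_ri", "ols_center_mz"))
  expect_true(all(tab$rmse > 0))
})
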