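test_that("fit_ols recovers exact linear structure", {
  set.seed(3)
  X <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 2 * X[, 1] - X[, 2] + 3
  tab <- descriptor_table(X, y)
  fit <- fit_ols(tab, c("x1", "x2"))
  expect_equal(unname(fit$coefficients), c(2, -1), tolerance = 1e-10)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("F equals t-squared for a single regressor", {
  set.seed(7)
  X <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x"))
  y <- rnorm(50)
  tab <- descriptor_table(X, y)
  fit <- fit_ols(tab, "x")
  t_stat <- coef(summary(lm(y ~ X)))["X", "t value"]
  expect_equal(fit$f_stat, t_stat^2, tolerance = 1e-8)
})

test_that("r2 is definitionally the squared fitted-observed correlation", {
  for (seed in 1:5) {
    tab <- random_table(30, 4, seed = seed)
    fit <- fit_ols(tab, descriptor_names(tab)[1:3])
    expect_equal(fit$r2, cor(fit$fitted, tab$activity)^2,
                 tolerance = 1e-12)
  }
})

test_that("rank-deficient designs are rejected with the column named", {
  set.seed(5)
  X <- matrix(rnorm(30), 30, 1)
  X <- cbind(a = X, b = 2 * X[, 1])
  colnames(X) <- c("a", "b")
  tab <- descriptor_table(X, rnorm(30))
  expect_error(fit_ols(tab, c("a", "b")), "collinear.*b")
})

test_that("closed-form LOO equals an explicit refit loop", {
  for (seed in 1:20) {
    tab <- random_table(30, 3, noise_sd = 1, seed = seed)
    subset <- descriptor_names(tab)
    got <- loo_r2(tab, subset)
    # brute-force oracle: refit n times with one row held out
    n <- n_compounds(tab)
    press <- 0
    for (i in seq_len(n)) {
      fit_i <- fit_ols(table_rows(tab, setdiff(seq_len(n), i)), subset)
      press <- press +
        (tab$activity[i] -
           as.numeric(predict(fit_i, table_rows(tab, i))))^2
    }
    sst <- sum((tab$activity - mean(tab$activity))^2)
    expect_equal(got, 1 - press / sst, tolerance = 1e-10)
  }
})

test_that("LOO R2 is 1 on noiseless data and shrinks on noise", {
  tab <- random_table(30, 3, noise_sd = 0, seed = 1)
  expect_equal(loo_r2(tab, descriptor_names(tab)), 1, tolerance = 1e-10)
  set.seed(8)
  noise <- descriptor_table(matrix(rnorm(50 * 2), 50, 2,
                                   dimnames = list(NULL, c("a", "b"))),
                            rnorm(50))
  fit <- fit_ols(noise, c("a", "b"))
  expect_lt(fit$r2_cv, fit$r2)
})

test_that("bmlr recovers planted informative descriptors", {
  set.seed(100)
  n <- 100L
  X <- matrix(rnorm(n * 53), n, 53,
              dimnames = list(NULL, c(paste0("inf", 1:3),
                                      paste0("nz", 1:50))))
  y <- 7 + 2 * X[, 1] - 1.5 * X[, 2] + X[, 3] + rnorm(n, sd = 0.3)
  tab <- descriptor_table(X, y)
  sel <- suppressWarnings(bmlr(tab, max_size = 5))
  expect_true(all(paste0("inf", 1:3) %in%
                    sel$chosen$descriptor_names))
})

test_that("with a wide beam the search equals exhaustive best subset", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- 6L; n <- 60L
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("d", 1:p)))
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    tab <- descriptor_table(X, y)
    sel <- suppressWarnings(
      bmlr(tab, max_size = 3, breakpoint = 0, pair_corr_max = 1,
           beam_width = choose(p, 2)))
    for (size in 1:3) {
      best_exh <- max(combn(p, size, function(ix)
        fit_ols(tab, paste0("d", ix))$r2))
      expect_equal(sel$trace$r2[size], best_exh, tolerance = 1e-10)
    }
  }
})

test_that("breakpoint of 1 stops at a single descriptor", {
  tab <- random_table(60, 6, seed = 4)
  sel <- bmlr(tab, max_size = 4, breakpoint = 1.0)
  expect_equal(sel$selected_size, 1L)
  expect_length(sel$chosen$descriptor_names, 1L)
})

test_that("per-size champion R2 never decreases and search is deterministic", {
  tab <- random_table(80, 12, k = 4, noise_sd = 0.5, seed = 6)
  sel1 <- suppressWarnings(bmlr(tab, max_size = 5, breakpoint = 0))
  expect_true(all(diff(sel1$trace$r2) >= -1e-12))
  sel2 <- suppressWarnings(bmlr(tab, max_size = 5, breakpoint = 0))
  expect_identical(sel1$trace, sel2$trace)
})

test_that("mutually collinear descriptor sets cannot seed a pair", {
  set.seed(12)
  base <- rnorm(40)
  X <- cbind(a = base + rnorm(40, sd = 0.01),
             b = base + rnorm(40, sd = 0.01),
             c = base + rnorm(40, sd = 0.01))
  tab <- descriptor_table(X, rnorm(40))
  expect_error(bmlr(tab, max_size = 2, pair_corr_max = 0.8),
               "no admissible")
})

test_that("the selection report writes the per-size table", {
  tab <- random_table(60, 6, seed = 9)
  sel <- suppressWarnings(bmlr(tab, max_size = 3, breakpoint = 0))
  path <- tempfile(fileext = ".tsv")
  bmlr_report(sel, path)
  rep <- read.delim(path)
  expect_equal(nrow(rep), 3L)
  expect_named(rep, c("size", "descriptors", "r2", "r2_cv", "s2",
                      "f_stat"))
})
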