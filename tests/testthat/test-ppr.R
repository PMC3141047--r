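test_that("smooth_ridge reproduces straight lines exactly", {
  set.seed(2)
  t <- sort(runif(40, -2, 2))
  r <- 1.5 * t - 0.3
  for (df in c(2, 4, 8)) {
    s <- smooth_ridge(t, r, df)
    expect_equal(eval_smoother(s, t), r, tolerance = 1e-6)
  }
})

test_that("fitted values approach the data as df approaches n", {
  set.seed(3)
  t <- sort(runif(20, 0, 1))
  r <- sin(4 * t) + rnorm(20, sd = 0.3)
  dev <- vapply(c(5, 12, 19), function(df)
    max(abs(eval_smoother(smooth_ridge(t, r, df), t) - r)), numeric(1))
  # maximum deviation from the data shrinks towards interpolation
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], dev[1] / 2)
})

test_that("the smoother matrix trace matches the requested df", {
  set.seed(11)
  t <- sort(runif(100, -1, 1))
  r <- t^2 + rnorm(100, sd = 0.1)
  for (df in c(3, 5, 8)) {
    s <- smooth_ridge(t, r, df)
    # explicit trace oracle: smooth each basis vector at the calibrated
    # penalty and sum the diagonal of the resulting smoother matrix
    tr <- sum(vapply(seq_along(t), function(j) {
      e <- numeric(length(t)); e[j] <- 1
      fit <- smooth.spline(t, e, lambda = s$lambda, all.knots = TRUE)
      predict(fit, t[j])$y
    }, numeric(1)))
    expect_equal(tr, df, tolerance = 0.05)
  }
})

test_that("degenerate projections are rejected", {
  expect_error(smooth_ridge(rep(1, 10), rnorm(10), 4), "degenerate")
  expect_error(smooth_ridge(1:10, rnorm(10), 11), "below")
})

test_that("a single planted square ridge is recovered", {
  set.seed(5)
  n <- 200L; p <- 5L
  X <- matrix(rnorm(n * p), n, p)
  a_true <- c(1, 0, 0, 0, 0)
  y <- drop(X %*% a_true)^2
  fit <- suppressWarnings(ppr_fit(X, y, nterms = 1, df = 10, seed = 1))
  a_hat <- fit$terms[[1]]$alpha
  expect_gte(abs(sum(a_hat * a_true)), 0.99)
  expect_gte(r2_score(y, fit$fitted), 0.999)
})

test_that("one-term PPR matches OLS on linear data", {
  set.seed(6)
  n <- 150L; p <- 4L
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("d", 1:p)))
  y <- 7 + drop(X %*% c(1, -2, 0.5, 0)) + rnorm(n, sd = 0.4)
  tab <- descriptor_table(X, y)
  ols <- fit_ols(tab, paste0("d", 1:p))
  fit <- ppr_fit(tab, nterms = 1, df = 2, seed = 1)
  expect_equal(r2_score(y, fit$fitted), ols$r2, tolerance = 1e-3)
})

test_that("nterms = max_terms keeps exactly that many terms", {
  tab <- random_table(80, 5, seed = 8)
  fit <- suppressWarnings(ppr_fit(tab, nterms = 3, max_terms = 3,
                                  df = 4))
  expect_length(fit$terms, 3L)
  expect_equal(fit$hyperparams$nterms, 3L)
})

test_that("directions are unit-norm and residuals orthogonal to terms", {
  syn <- generate_table(synthetic_spec(n_compounds = 100, n_noise = 4,
                                       form = "ridge", seed = 13))
  fit <- suppressWarnings(ppr_fit(syn$table, nterms = 2, max_terms = 4,
                                  df = 5))
  for (tm in fit$terms) {
    expect_equal(sqrt(sum(tm$alpha^2)), 1, tolerance = 1e-9)
    # least-squares scales make residuals orthogonal to term outputs
    Xs <- sweep(sweep(syn$table$values, 2, fit$center), 2, fit$scale,
                "/")
    g <- eval_smoother(tm$smoother, drop(Xs %*% tm$alpha))
    expect_lt(abs(sum(fit$residuals * g)) / sqrt(sum(g^2)), 1e-6)
  }
})

test_that("training RSS is non-increasing in the number of terms", {
  syn <- generate_table(synthetic_spec(n_compounds = 120, n_noise = 5,
                                       form = "ridge", seed = 17))
  rss <- vapply(1:4, function(m) {
    fit <- suppressWarnings(ppr_fit(syn$table, nterms = m,
                                    max_terms = m, df = 5, seed = 2))
    sum(fit$residuals^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("more thorough pruning refits never hurt the training fit", {
  syn <- generate_table(synthetic_spec(n_compounds = 120, n_noise = 6,
                                       form = "ridge", seed = 19))
  rss <- vapply(c(0L, 1L, 2L), function(lev) {
    fit <- suppressWarnings(ppr_fit(syn$table, nterms = 2,
                                    max_terms = 5, df = 5,
                                    optlevel = lev, seed = 3))
    sum(fit$residuals^2)
  }, numeric(1))
  expect_lte(rss[2], rss[1] + 1e-8)  # optlevel 1 vs 0
  expect_lte(rss[3], rss[1] + 1e-8)  # optlevel 2 vs 0
})

test_that("optlevel 3 is the single-response alias of level 2", {
  syn <- generate_table(synthetic_spec(n_compounds = 90, n_noise = 4,
                                       form = "ridge", seed = 23))
  f2 <- suppressWarnings(ppr_fit(syn$table, nterms = 2, max_terms = 4,
                                 df = 4, optlevel = 2, seed = 5))
  f3 <- suppressWarnings(ppr_fit(syn$table, nterms = 2, max_terms = 4,
                                 df = 4, optlevel = 3, seed = 5))
  expect_equal(f2$fitted, f3$fitted)
})

test_that("fits are reproducible and invariant to column rescaling", {
  syn <- generate_table(synthetic_spec(n_compounds = 100, n_noise = 5,
                                       form = "ridge", seed = 29))
  tab <- syn$table
  f1 <- suppressWarnings(ppr_fit(tab, nterms = 2, max_terms = 3,
                                 df = 4, seed = 7))
  f2 <- suppressWarnings(ppr_fit(tab, nterms = 2, max_terms = 3,
                                 df = 4, seed = 7))
  expect_equal(f1$fitted, f2$fitted)
  expect_equal(f1$terms[[1]]$alpha, f2$terms[[1]]$alpha)
  # rescale and shift one input column: standardization absorbs it
  tab2 <- tab
  tab2$values[, 1] <- 100 * tab2$values[, 1] - 17
  f3 <- suppressWarnings(ppr_fit(tab2, nterms = 2, max_terms = 3,
                                 df = 4, seed = 7))
  expect_equal(f3$fitted, f1$fitted, tolerance = 1e-6)
  p1 <- predict(f1, tab)
  p3 <- predict(f3, tab2)
  expect_equal(as.numeric(p3), as.numeric(p1), tolerance = 1e-6)
})

test_that("predict reproduces stored fitted values on training data", {
  syn <- generate_table(synthetic_spec(n_compounds = 80, n_noise = 3,
                                       form = "ridge", seed = 31))
  fit <- suppressWarnings(ppr_fit(syn$table, nterms = 2, max_terms = 3,
                                  df = 4))
  expect_equal(as.numeric(predict(fit, syn$table)), fit$fitted,
               tolerance = 1e-10)
})

test_that("zero-scale models predict the response centre", {
  syn <- generate_table(synthetic_spec(n_compounds = 60, n_noise = 3,
                                       seed = 37))
  fit <- suppressWarnings(ppr_fit(syn$table, nterms = 1, df = 3))
  fit$terms <- lapply(fit$terms, function(tm) { tm$beta <- 0; tm })
  p <- predict(fit, syn$table)
  expect_equal(as.numeric(p),
               rep(fit$response_center, n_compounds(syn$table)))
})

test_that("stored smoothers evaluate like an independent natural spline", {
  set.seed(41)
  t <- sort(runif(50, -2, 2))
  r <- cos(t) + rnorm(50, sd = 0.1)
  s <- smooth_ridge(t, r, 6)
  probes <- c(-2.5, 0.3, 1.7)  # one beyond the training range
  ref <- spline(s$knots, s$values, method = "natural",
                xout = probes)$y
  expect_equal(eval_smoother(s, probes), ref, tolerance = 1e-12)
  # extrapolation flagged by predict
  fit <- suppressWarnings(
    ppr_fit(matrix(t, dimnames = list(NULL, "d1")), r, nterms = 1,
            df = 4))
  far <- matrix(c(0, 100), dimnames = list(NULL, "d1"))
  p <- predict(fit, far)
  expect_false(attr(p, "extrapolated")[1])
  expect_true(attr(p, "extrapolated")[2])
})

test_that("term importance is a unit-sum share, balanced for symmetric ridges", {
  syn <- generate_table(synthetic_spec(n_compounds = 80, n_noise = 3,
                                       seed = 43))
  f1 <- suppressWarnings(ppr_fit(syn$table, nterms = 1, df = 3))
  expect_equal(term_importance(f1), 1)
  # two orthogonal planted ridges of equal strength (squares: neither
  # can absorb the other, unlike near-linear shapes)
  set.seed(44)
  n <- 300L
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X[, 1]^2 + X[, 2]^2 + rnorm(n, sd = 0.05)
  fit <- suppressWarnings(ppr_fit(X, y, nterms = 2, max_terms = 3,
                                  df = 4, seed = 2))
  imp <- term_importance(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(unname(sort(imp)), c(0.5, 0.5), tolerance = 0.1)
})

test_that("serialized models reload and predict identically", {
  syn <- generate_table(synthetic_spec(n_compounds = 90, n_noise = 4,
                                       form = "ridge", seed = 47))
  fit <- suppressWarnings(ppr_fit(syn$table, nterms = 2, max_terms = 3,
                                  df = 5))
  path <- tempfile(fileext = ".json")
  ppr_save(fit, path)
  back <- ppr_load(path)
  expect_equal(as.numeric(predict(back, syn$table)),
               as.numeric(predict(fit, syn$table)), tolerance = 1e-12)
  expect_equal(back$hyperparams, fit$hyperparams)
})

test_that("the engine tracks the reference PPR implementation on smooth data", {
  set.seed(53)
  n <- 200L
  X <- matrix(rnorm(n * 3), n, 3)
  y <- (X[, 1] + X[, 2])^2 / 2 + rnorm(n, sd = 0.2)
  ours <- suppressWarnings(ppr_fit(X, y, nterms = 1, df = 6))
  ref <- stats::ppr(X, y, nterms = 1)
  r2_ours <- r2_score(y, ours$fitted)
  r2_ref <- r2_score(y, fitted(ref))
  expect_lt(abs(r2_ours - r2_ref), 0.05)
})

test_that("invalid hyperparameters are rejected", {
  tab <- random_table(50, 3, seed = 1)
  expect_error(ppr_fit(tab, nterms = 3, max_terms = 2), "max_terms")
  expect_error(ppr_fit(tab, nterms = 0), "nterms")
  expect_error(ppr_fit(tab, nterms = 1, df = 60), "df")
})
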