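test_that("a well-formed file round-trips through read/write", {
  df <- data.frame(id = c("a", "b", "c"), pIC50 = c(6.1, 7.2, 8.3),
                   d1 = 1:3, d2 = c(0.5, 0.1, -0.2))
  for (sep in c(",", "\t")) {
    path <- write_fixture_csv(df, sep)
    tab <- read_descriptor_table(path)
    expect_s3_class(tab, "descriptor_table")
    expect_equal(dim(tab), c(3L, 2L))
    expect_equal(tab$compound_ids, c("a", "b", "c"))
    expect_equal(tab$activity, df$pIC50)
    expect_equal(unname(tab$values[, "d2"]), df$d2)
    out <- tempfile()
    write_descriptor_table(tab, out)
    again <- read_descriptor_table(out)
    expect_equal(again$values, tab$values)
    expect_equal(again$activity, tab$activity)
  }
})

test_that("reading rejects duplicate ids and missing activity columns", {
  df <- data.frame(id = c("a", "a"), pIC50 = c(6, 7), d1 = 1:2)
  expect_error(read_descriptor_table(write_fixture_csv(df)), "a")
  df2 <- data.frame(id = c("a", "b"), potency = c(6, 7), d1 = 1:2)
  expect_error(read_descriptor_table(write_fixture_csv(df2)), "pIC50")
  expect_error(read_descriptor_table(tempfile()), "not found")
})

test_that("non-numeric cells are dropped with a report, or rejected", {
  df <- data.frame(id = c("a", "b", "c"), pIC50 = c(6, 7, 8),
                   d1 = c("1.5", "oops", "2.5"), d2 = c(1, 2, 3))
  path <- write_fixture_csv(df)
  expect_error(read_descriptor_table(path), "b")
  tab <- read_descriptor_table(path, on_invalid = "drop")
  expect_equal(n_compounds(tab), 2L)
  expect_equal(tab$compound_ids, c("a", "c"))
  log <- attr(tab, "removal_log")
  expect_equal(log$compound_id, "b")
  expect_equal(log$column, "d1")
})

test_that("split labels in the file are honoured", {
  df <- data.frame(id = c("a", "b", "c"), pIC50 = c(6, 7, 8),
                   split = c("train", "test", "train"), d1 = 1:3)
  tab <- read_descriptor_table(write_fixture_csv(df))
  expect_equal(tab$split, c("train", "test", "train"))
})

test_that("constant and duplicated descriptors are pruned", {
  set.seed(4)
  X <- cbind(v1 = rnorm(20), const = rep(2, 20), v2 = rnorm(20))
  X <- cbind(X, copy = X[, "v1"])
  tab <- descriptor_table(X, rnorm(20))
  pruned <- prune_descriptors(tab, corr_threshold = 0.99)
  expect_false("const" %in% descriptor_names(pruned))
  # exactly one of the r = 1 pair survives
  expect_equal(sum(c("v1", "copy") %in% descriptor_names(pruned)), 1L)
  log <- attr(pruned, "removal_log")
  expect_setequal(log$reason, c("constant", "collinear"))
})

test_that("collinearity pruning matches a brute-force greedy scan", {
  # independent naive re-implementation of the documented scan rule
  naive_prune <- function(X, thr) {
    keep <- colnames(X)
    repeat {
      cm <- abs(cor(X[, keep, drop = FALSE]))
      diag(cm) <- 0
      if (length(keep) < 2L || max(cm) < thr) break
      best <- c(NA_integer_, NA_integer_); best_r <- -1
      for (j in seq_along(keep)) for (i in seq_len(j - 1L))
        if (cm[i, j] > best_r) { best_r <- cm[i, j]; best <- c(i, j) }
      i <- best[1L]; j <- best[2L]
      mi <- mean(cm[i, -c(i, j)]); mj <- mean(cm[j, -c(i, j)])
      if (length(keep) == 2L) mi <- mj <- 0
      drop_ix <- if (mi > mj) i else j
      keep <- keep[-drop_ix]
    }
    keep
  }
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 10), 60, 10,
                dimnames = list(NULL, paste0("r", 1:10)))
    dup <- X[, 1:3] + matrix(rnorm(60 * 3, sd = 0.05), 60, 3)
    colnames(dup) <- paste0("dup", 1:3)
    X <- cbind(X, dup)
    tab <- descriptor_table(X, rnorm(60))
    pruned <- prune_descriptors(tab, corr_threshold = 0.95)
    expect_setequal(descriptor_names(pruned), naive_prune(X, 0.95))
  }
})

test_that("pruning is idempotent", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 8), 50, 8)
    X <- cbind(X, X[, 1] + rnorm(50, sd = 0.02), rep(1, 50))
    colnames(X) <- paste0("c", seq_len(ncol(X)))
    tab <- descriptor_table(X, rnorm(50))
    once <- prune_descriptors(tab, corr_threshold = 0.95)
    twice <- prune_descriptors(once, corr_threshold = 0.95)
    expect_equal(descriptor_names(twice), descriptor_names(once))
    expect_equal(nrow(attr(twice, "removal_log")), 0L)
  }
})

test_that("random splitting gives the requested counts, reproducibly", {
  tab <- random_table(128, 5, seed = 11)
  s1 <- split_train_test(tab, test_fraction = 25 / 128, seed = 42)
  expect_equal(sum(s1$split == "train"), 103L)
  expect_equal(sum(s1$split == "test"), 25L)
  s2 <- split_train_test(tab, test_fraction = 25 / 128, seed = 42)
  expect_identical(s1$split, s2$split)
  s3 <- split_train_test(tab, test_fraction = 25 / 128, seed = 43)
  expect_false(identical(s1$split, s3$split))
  # partition: every compound labelled exactly once
  expect_true(all(s1$split %in% c("train", "test")))
  expect_equal(sum(table(s1$split)), 128L)
})

test_that("explicit test-id lists override randomness", {
  tab <- random_table(10, 3, seed = 2)
  s <- split_train_test(tab, test_ids = tab$compound_ids[1:2])
  expect_equal(which(s$split == "test"), 1:2)
  expect_warning(split_train_test(tab, test_ids = tab$compound_ids),
                 "all compounds")
  expect_error(split_train_test(tab, test_ids = "nope"), "nope")
})
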