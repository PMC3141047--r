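#' Model specifications for cross-validation
#'
#' Lightweight descriptions of the two model families the evaluation
#' machinery can refit inside each fold: a multi-linear model on a fixed
#' descriptor subset, or a PPR model at fixed hyperparameters.
#'
#' @param subset descriptor names for the linear model.
#' @return a `model_spec` list.
#' @export
linear_spec <- function(subset) {
  stopifnot(length(subset) >= 1L)
  structure(list(type = "linear", subset = subset), class = "model_spec")
}

#' @rdname linear_spec
#' @inheritParams ppr_fit
#' @export
ppr_spec <- function(nterms, max_terms = nterms, df = 4, optlevel = 1L) {
  if (nterms > max_terms) stop("nterms must not exceed max_terms")
  structure(list(type = "ppr", nterms = as.integer(nterms),
                 max_terms = as.integer(max_terms), df = df,
                 optlevel = as.integer(optlevel)), class = "model_spec")
}

.fit_spec <- function(spec, table, seed) {
  switch(spec$type,
         linear = fit_ols(table, spec$subset),
         ppr = ppr_fit(table, nterms = spec$nterms,
                       max_terms = spec$max_terms, df = spec$df,
                       optlevel = spec$optlevel, seed = seed),
         stop("unknown model spec type: ", spec$type))
}

# balanced, seeded fold assignment over n rows
.make_folds <- function(n, k, seed) {
  if (k > n) stop("k must not exceed the number of training compounds")
  withr_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

.cv_with_folds <- function(tr, spec, folds, seed) {
  n <- n_compounds(tr)
  k <- max(folds)
  pred <- rep(NA_real_, n)
  per_fold <- data.frame(fold = seq_len(k), n_out = NA_integer_,
                         r2 = NA_real_, rmse = NA_real_)
  min_df <- if (spec$type == "linear") length(spec$subset) + 2L
            else ceiling(spec$df) + 3L
  for (f in seq_len(k)) {
    out <- folds == f
    if (sum(!out) < min_df)
      stop("fold ", f, " leaves fewer training rows than the model ",
           "degrees of freedom")
    fit <- .fit_spec(spec, table_rows(tr, !out), seed)
    p <- as.numeric(predict(fit, table_rows(tr, out)))
    pred[out] <- p
    per_fold$n_out[f] <- sum(out)
    per_fold$rmse[f] <- rmse(tr$activity[out], p)
    per_fold$r2[f] <- if (sum(out) >= 3L && stats::sd(p) > 0)
      r2_score(tr$activity[out], p) else NA_real_
  }
  list(r2_cv = r2_score(tr$activity, pred),
       rmse_cv = rmse(tr$activity, pred),
       predictions = data.frame(compound_id = tr$compound_ids,
                                fold = folds, y_exp = tr$activity,
                                y_pred = pred),
       per_fold = per_fold)
}

#' k-fold cross-validation of a QSAR model
#'
#' Splits the training compounds into `k` seeded, size-balanced folds,
#' refits the model with each fold held out, and pools the out-of-fold
#' predictions. R^2 and RMSE are computed on the pooled prediction vector
#' (every compound predicted exactly once out-of-fold); per-fold
#' statistics are reported alongside.
#'
#' @param x a [descriptor_table()]; rows labelled `train` are used.
#' @param spec a [linear_spec()] or [ppr_spec()].
#' @param k number of folds, default 5.
#' @param seed seed for the fold assignment (and the PPR tie-breaking).
#' @return a list: `r2_cv`, `rmse_cv`, `folds`, `predictions` (one row
#'   per compound), `per_fold`.
#' @export
kfold_cv <- function(x, spec, k = 5L, seed = 1L) {
  stopifnot(inherits(x, "descriptor_table"), inherits(spec, "model_spec"))
  tr <- suppressWarnings(split_rows(x, "train"))
  folds <- .make_folds(n_compounds(tr), k, seed)
  res <- .cv_with_folds(tr, spec, folds, seed)
  res$folds <- folds
  res
}

#' Hyperparameter grid for PPR
#'
#' Candidate values for the four PPR hyperparameters; the grid is the full
#' cross product with cells violating `nterms <= max_terms` skipped.
#'
#' @param nterms,max_terms,df,optlevel candidate vectors.
#' @return a `grid_spec` data frame of admissible cells.
#' @export
grid_spec <- function(nterms = 1:4, max_terms = c(4L, 6L, 8L),
                      df = c(4, 6, 8), optlevel = c(0L, 1L, 2L)) {
  g <- expand.grid(nterms = as.integer(nterms),
                   max_terms = as.integer(max_terms), df = df,
                   optlevel = as.integer(optlevel),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$nterms <= g$max_terms, , drop = FALSE]
  if (!nrow(g)) stop("empty grid after removing nterms > max_terms cells")
  rownames(g) <- NULL
  class(g) <- c("grid_spec", class(g))
  g
}

#' Multi-factor grid search over PPR hyperparameters
#'
#' Evaluates every admissible grid cell by k-fold cross-validation on the
#' training compounds, with one shared fold assignment so cells are
#' compared on identical resamples. The selected cell minimizes the
#' pooled cross-validated RMSE; exact ties are broken by parsimony
#' (smaller `nterms`, then smaller `max_terms`, then smaller `df`). The
#' held-out test compounds play no role in the selection.
#'
#' @param x a [descriptor_table()]; rows labelled `train` are used.
#' @param grid a [grid_spec()].
#' @param k folds, default 5.
#' @param seed fold-assignment seed.
#' @return an object of class `ppr_grid`: `cells` (one row per cell with
#'   train and CV statistics), `best` (the selected row), `best_spec`
#'   (a [ppr_spec()]), `folds`, `tie_break_note`.
#' @export
grid_search <- function(x, grid = grid_spec(), k = 5L, seed = 1L) {
  stopifnot(inherits(x, "descriptor_table"))
  tr <- suppressWarnings(split_rows(x, "train"))
  folds <- .make_folds(n_compounds(tr), k, seed)
  cells <- as.data.frame(grid)
  cells$train_r2 <- NA_real_; cells$train_rmse <- NA_real_
  cells$cv_r2 <- NA_real_; cells$cv_rmse <- NA_real_
  cells$error <- NA_character_
  per_fold <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    spec <- ppr_spec(cells$nterms[i], cells$max_terms[i], cells$df[i],
                     cells$optlevel[i])
    res <- tryCatch({
      cv <- .cv_with_folds(tr, spec, folds, seed)
      fit <- suppressWarnings(.fit_spec(spec, tr, seed))
      list(cv = cv, fit = fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      cells$error[i] <- conditionMessage(res)
      next
    }
    cells$train_r2[i] <- r2_score(tr$activity, res$fit$fitted)
    cells$train_rmse[i] <- rmse(tr$activity, res$fit$fitted)
    cells$cv_r2[i] <- res$cv$r2_cv
    cells$cv_rmse[i] <- res$cv$rmse_cv
    per_fold[[i]] <- res$cv$per_fold
  }
  ok <- !is.na(cells$cv_rmse)
  if (!any(ok)) stop("all grid cells failed to fit")
  ord <- order(cells$cv_rmse, cells$nterms, cells$max_terms, cells$df,
               na.last = TRUE)
  best_ix <- ord[1L]
  tied <- ok & cells$cv_rmse == cells$cv_rmse[best_ix]
  note <- if (sum(tied) > 1L)
    sprintf("%d cells tied on CV RMSE; parsimony tie-break applied",
            sum(tied)) else ""
  structure(list(cells = cells, best = cells[best_ix, , drop = FALSE],
                 best_spec = ppr_spec(cells$nterms[best_ix],
                                      cells$max_terms[best_ix],
                                      cells$df[best_ix],
                                      cells$optlevel[best_ix]),
                 best_index = best_ix, per_fold = per_fold,
                 folds = folds, k = k, seed = seed,
                 tie_break_note = note),
            class = "ppr_grid")
}

#' @export
print.ppr_grid <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "PPR grid search: %d cells, %d-fold CV\n  best: nterms=%d, max_terms=%d, df=%g, optlevel=%d (CV RMSE %.4f, CV R2 %.4f)\n",
    nrow(x$cells), x$k, b$nterms, b$max_terms, b$df, b$optlevel,
    b$cv_rmse, b$cv_r2))
  if (nzchar(x$tie_break_note)) cat(" ", x$tie_break_note, "\n")
  invisible(x)
}

#' Export the grid-search surface
#'
#' Writes the per-cell table (tab-delimited) and a JSON summary of the
#' selected cell — the data behind the usual R^2/RMSE-versus-(nterms,
#' max.terms) optimization surface plots.
#'
#' @param x a `ppr_grid` from [grid_search()].
#' @param path base output path; `<path>.tsv` and `<path>.json` are
#'   written.
#' @return paths, invisibly.
#' @export
grid_report <- function(x, path) {
  stopifnot(inherits(x, "ppr_grid"))
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(x$cells, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(best = as.list(x$best), k = x$k,
                            seed = x$seed,
                            tie_break_note = x$tie_break_note),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' PCA diagnostic of the train/test split
#'
#' Principal component analysis of the (standardized) selected
#' descriptors — equivalently, an eigendecomposition of their correlation
#' matrix. The first two score columns, labelled by split membership, show
#' whether the test compounds cover the same descriptor space as the
#' training compounds.
#'
#' @param x a [descriptor_table()].
#' @param subset descriptor names, at least two.
#' @return a list: `explained_variance` (percent per component, summing
#'   to 100) and `scores` (data frame: compound_id, split, PC1, PC2).
#' @export
pca_diagnostic <- function(x, subset) {
  stopifnot(inherits(x, "descriptor_table"))
  if (length(subset) < 2L) stop("need at least 2 descriptors")
  missing <- setdiff(subset, descriptor_names(x))
  if (length(missing))
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  X <- x$values[, subset, drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant descriptor(s) in subset: ",
         paste(subset[sds == 0], collapse = ", "))
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  list(explained_variance = ev,
       scores = data.frame(compound_id = x$compound_ids,
                           split = x$split,
                           PC1 = pr$x[, 1L], PC2 = pr$x[, 2L],
                           row.names = NULL))
}
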