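#' Construct a descriptor table
#'
#' A `descriptor_table` holds one row per compound: a numeric descriptor
#' matrix, the measured activity as pIC50 (-log10 of the IC50 in nM, so
#' larger means more potent), and a per-compound split label used to
#' separate model building from validation.
#'
#' @param values numeric matrix, compounds in rows, descriptors in columns.
#'   Must carry unique column names; row names are taken from
#'   `compound_ids` when given.
#' @param activity numeric vector of pIC50 values, one per row of `values`.
#' @param compound_ids character vector of unique compound identifiers.
#'   Defaults to the row names of `values`, or `cmpd1, cmpd2, ...`.
#' @param split per-compound label, each `"train"`, `"test"` or
#'   `"unassigned"`. Defaults to all unassigned.
#' @return An object of class `descriptor_table`.
#' @seealso [read_descriptor_table()], [prune_descriptors()],
#'   [split_train_test()]
#' @export
descriptor_table <- function(values, activity, compound_ids = NULL,
                             split = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("descriptor values must be numeric")
  n <- nrow(values)
  if (is.null(compound_ids)) {
    compound_ids <- if (!is.null(rownames(values))) rownames(values)
                    else paste0("cmpd", seq_len(n))
  }
  compound_ids <- as.character(compound_ids)
  if (length(compound_ids) != n)
    stop("compound_ids length (", length(compound_ids),
         ") does not match row count (", n, ")")
  dup <- compound_ids[duplicated(compound_ids)]
  if (length(dup))
    stop("duplicated compound id(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("D", seq_len(ncol(values)))
  dupd <- colnames(values)[duplicated(colnames(values))]
  if (length(dupd))
    stop("duplicated descriptor name(s): ",
         paste(unique(dupd), collapse = ", "))
  if (length(activity) != n)
    stop("activity length (", length(activity),
         ") does not match row count (", n, ")")
  if (!all(is.finite(values))) stop("non-finite descriptor values")
  if (!all(is.finite(activity))) stop("non-finite activity values")
  if (is.null(split)) split <- rep("unassigned", n)
  split <- as.character(split)
  if (length(split) != n) stop("split length does not match row count")
  bad <- setdiff(unique(split), c("train", "test", "unassigned"))
  if (length(bad))
    stop("invalid split label(s): ", paste(bad, collapse = ", "))
  rownames(values) <- compound_ids
  structure(list(values = values, activity = as.numeric(activity),
                 compound_ids = compound_ids, split = split),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("Descriptor table:", nrow(x$values), "compounds x",
      ncol(x$values), "descriptors\n")
  cat("  activity (pIC50) range:",
      sprintf("%.3f .. %.3f", min(x$activity), max(x$activity)), "\n")
  tab <- table(factor(x$split, levels = c("train", "test", "unassigned")))
  cat("  split:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Number of compounds / descriptor names
#'
#' Small accessors for a [descriptor_table()].
#' @param x a `descriptor_table`.
#' @return `n_compounds()` the number of rows; `descriptor_names()` the
#'   column names of the descriptor matrix.
#' @export
n_compounds <- function(x) nrow(x$values)

#' @rdname n_compounds
#' @export
descriptor_names <- function(x) colnames(x$values)

#' Subset a descriptor table by rows
#'
#' @param x a `descriptor_table`.
#' @param rows integer or logical row index.
#' @return a `descriptor_table` containing the selected compounds.
#' @export
table_rows <- function(x, rows) {
  descriptor_table(x$values[rows, , drop = FALSE], x$activity[rows],
                   x$compound_ids[rows], x$split[rows])
}

#' Rows of a table belonging to one split
#'
#' @param x a `descriptor_table`.
#' @param which `"train"` or `"test"`. If no compound carries the requested
#'   label, all rows are returned with a warning, so that unsplit tables can
#'   still be modelled.
#' @return a `descriptor_table`.
#' @export
split_rows <- function(x, which = c("train", "test")) {
  which <- match.arg(which)
  idx <- x$split == which
  if (!any(idx)) {
    warning("no compounds labelled '", which, "'; using all rows")
    idx <- rep(TRUE, n_compounds(x))
  }
  table_rows(x, idx)
}

#' Read a descriptor table from delimited text
#'
#' Expects a header row with a compound-id column, an activity column and
#' numeric descriptor columns; an optional `split` column may pre-assign
#' train/test membership. The delimiter is sniffed (comma or tab) unless
#' given.
#'
#' @param path file path.
#' @param activity_col name of the activity (pIC50) column.
#' @param id_col name of the compound-id column; defaults to the first
#'   column.
#' @param split_col name of an optional split column (values `train`,
#'   `test` or `unassigned`).
#' @param sep field delimiter, `","`, `"\t"`, or `NULL` to sniff.
#' @param on_invalid what to do with rows holding missing or non-numeric
#'   descriptor or activity entries: `"reject"` (default) stops with an
#'   error, `"drop"` removes the rows and records them in the
#'   `"removal_log"` attribute of the result.
#' @return a [descriptor_table()]; when rows were dropped, the attribute
#'   `removal_log` lists each dropped compound and the offending column.
#' @export
read_descriptor_table <- function(path, activity_col = "pIC50",
                                  id_col = NULL, split_col = "split",
                                  sep = NULL,
                                  on_invalid = c("reject", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L) stop("empty table: ", path)
  if (is.null(id_col)) id_col <- names(raw)[1L]
  if (!id_col %in% names(raw)) stop("missing id column: ", id_col)
  if (!activity_col %in% names(raw))
    stop("missing activity column: ", activity_col)
  ids <- raw[[id_col]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated compound id(s): ", paste(dup, collapse = ", "))
  split <- if (split_col %in% names(raw)) raw[[split_col]] else NULL
  desc_cols <- setdiff(names(raw), c(id_col, activity_col, split_col))
  if (!length(desc_cols)) stop("no descriptor columns in ", path)

  num <- suppressWarnings(
    vapply(raw[c(activity_col, desc_cols)], as.numeric,
           numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, c(activity_col, desc_cols)))
  bad_cell <- !is.finite(num) | is.na(num)
  bad_row <- rowSums(bad_cell) > 0L
  log <- NULL
  if (any(bad_row)) {
    first_bad <- apply(bad_cell[bad_row, , drop = FALSE], 1L,
                       function(z) colnames(num)[which(z)[1L]])
    log <- data.frame(compound_id = ids[bad_row], column = first_bad,
                      stringsAsFactors = FALSE)
    if (on_invalid == "reject")
      stop("non-numeric or missing entries in row(s): ",
           paste(ids[bad_row], collapse = ", "),
           " (first bad column: ", first_bad[1L], ")")
    keep <- !bad_row
    num <- num[keep, , drop = FALSE]
    ids <- ids[keep]
    if (!is.null(split)) split <- split[keep]
    if (!nrow(num)) stop("all rows dropped while reading ", path)
  }
  out <- descriptor_table(num[, desc_cols, drop = FALSE],
                          num[, activity_col], ids, split)
  attr(out, "removal_log") <- log
  out
}

#' Write a descriptor table as delimited text
#'
#' Inverse of [read_descriptor_table()]; the split column is written only
#' when at least one compound is assigned.
#'
#' @param x a `descriptor_table`.
#' @param path output path.
#' @param sep delimiter, default tab.
#' @param activity_col header used for the activity column.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, path, sep = "\t",
                                   activity_col = "pIC50") {
  df <- data.frame(compound_id = x$compound_ids,
                   activity = x$activity,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[2L] <- activity_col
  if (any(x$split != "unassigned")) df$split <- x$split
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove constant and highly collinear descriptors
#'
#' Two passes mirror standard QSAR pre-filtering. First, descriptors whose
#' variance is at most `var_eps` are removed (floating-point constancy).
#' Then pairs with |Pearson r| at or above `corr_threshold` are scanned
#' greedily: the pair with the largest |r| is resolved by dropping the
#' member with the larger mean absolute correlation to all other surviving
#' descriptors (keeping the more independent feature); exact ties drop the
#' later column. The scan repeats until no pair exceeds the threshold, so
#' the operation is idempotent.
#'
#' @param x a [descriptor_table()].
#' @param var_eps variance threshold for constancy, default `1e-12`.
#' @param corr_threshold absolute-correlation threshold in (0, 1],
#'   default `0.99`.
#' @return the pruned `descriptor_table`; attribute `removal_log` is a
#'   data frame with one row per removed descriptor (`descriptor`,
#'   `reason`, `detail`).
#' @export
prune_descriptors <- function(x, var_eps = 1e-12, corr_threshold = 0.99) {
  stopifnot(inherits(x, "descriptor_table"))
  if (n_compounds(x) < 2L) stop("need at least 2 compounds to prune")
  if (!(corr_threshold > 0 && corr_threshold <= 1))
    stop("corr_threshold must lie in (0, 1]")
  v <- x$values
  log <- data.frame(descriptor = character(), reason = character(),
                    detail = character(), stringsAsFactors = FALSE)

  vars <- apply(v, 2L, stats::var)
  const <- vars <= var_eps
  if (any(const)) {
    log <- rbind(log, data.frame(
      descriptor = colnames(v)[const], reason = "constant",
      detail = sprintf("variance %.3g", vars[const]),
      stringsAsFactors = FALSE))
    v <- v[, !const, drop = FALSE]
  }
  if (ncol(v) == 0L) stop("all descriptors removed (constant)")

  if (ncol(v) > 1L) {
    cm <- abs(stats::cor(v))
    diag(cm) <- 0
    repeat {
      mx <- max(cm)
      if (mx < corr_threshold) break
      hit <- which(cm == mx, arr.ind = TRUE)
      # first pair in column-major order for a deterministic scan
      hit <- hit[order(hit[, 2L], hit[, 1L]), , drop = FALSE]
      i <- min(hit[1L, ]); j <- max(hit[1L, ])
      others_i <- cm[i, -c(i, j)]
      others_j <- cm[j, -c(i, j)]
      mi <- if (length(others_i)) mean(others_i) else 0
      mj <- if (length(others_j)) mean(others_j) else 0
      drop_ix <- if (mi > mj) i else if (mj > mi) j else j
      log <- rbind(log, data.frame(
        descriptor = colnames(cm)[drop_ix], reason = "collinear",
        detail = sprintf("|r|=%.4f with %s", mx,
                         colnames(cm)[if (drop_ix == i) j else i]),
        stringsAsFactors = FALSE))
      cm <- cm[-drop_ix, -drop_ix, drop = FALSE]
      if (nrow(cm) < 2L) break
    }
    v <- v[, colnames(cm), drop = FALSE]
  }
  if (ncol(v) == 0L) stop("all descriptors removed")
  out <- descriptor_table(v, x$activity, x$compound_ids, x$split)
  attr(out, "removal_log") <- log
  out
}

#' Assign train/test membership
#'
#' Randomly assigns a fraction of compounds to the test set (seeded, hence
#' reproducible), or honours an explicit list of test compound ids.
#'
#' @param x a [descriptor_table()].
#' @param test_fraction fraction of compounds held out, in (0, 1). With 128
#'   compounds and `test_fraction = 25/128` this yields the conventional
#'   103 train / 25 test division.
#' @param test_ids explicit character vector of test compound ids;
#'   overrides `test_fraction`.
#' @param seed integer seed for the random draw.
#' @return the table with `split` labels set (`train`/`test`).
#' @export
split_train_test <- function(x, test_fraction = 0.2, test_ids = NULL,
                             seed = 1L) {
  stopifnot(inherits(x, "descriptor_table"))
  n <- n_compounds(x)
  if (!is.null(test_ids)) {
    unknown <- setdiff(test_ids, x$compound_ids)
    if (length(unknown))
      stop("unknown compound id(s) in test list: ",
           paste(unknown, collapse = ", "))
    is_test <- x$compound_ids %in% test_ids
    if (all(is_test)) warning("all compounds assigned to the test set")
    if (!any(is_test)) warning("empty test set")
  } else {
    if (!(test_fraction > 0 && test_fraction < 1))
      stop("test_fraction must lie in (0, 1)")
    n_test <- round(n * test_fraction)
    n_test <- max(1L, min(n - 1L, n_test))
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    idx <- sample.int(n, n_test)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    is_test <- seq_len(n) %in% idx
  }
  x$split <- ifelse(is_test, "test", "train")
  x
}
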