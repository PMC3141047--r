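#' Build a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis — input table, pruning
#' thresholds, train/test split, BMLR search settings, the PPR
#' hyperparameter grid and the CV fold count — into one validated list
#' that [run_pipeline()] executes. A configuration round-trips through
#' JSON unchanged, so runs are reproducible from the written config.
#'
#' @param input path to a delimited descriptor table (see
#'   [read_descriptor_table()]); alternatively supply `table` directly.
#' @param table a [descriptor_table()] (programmatic use).
#' @param activity_col activity column name in `input`.
#' @param id_col compound-id column; default first column.
#' @param var_eps,corr_threshold pruning thresholds
#'   ([prune_descriptors()]).
#' @param test_fraction held-out fraction ([split_train_test()]); ignored
#'   when the input already carries split labels.
#' @param bmlr_max_size,bmlr_breakpoint,bmlr_pair_corr_max,bmlr_beam_width
#'   BMLR search settings ([bmlr()]).
#' @param grid a [grid_spec()].
#' @param k CV folds, default 5.
#' @param seed master seed; the split, fold assignment and PPR
#'   tie-breaking all derive from it.
#' @param out_dir output directory for artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, table = NULL,
                       activity_col = "pIC50", id_col = NULL,
                       var_eps = 1e-12, corr_threshold = 0.99,
                       test_fraction = 25 / 128,
                       bmlr_max_size = 10L, bmlr_breakpoint = 0.02,
                       bmlr_pair_corr_max = 0.8,
                       bmlr_beam_width = 400L,
                       grid = grid_spec(), k = 5L, seed = 1L,
                       out_dir = "qsarppr-run") {
  cfg <- list(input = input, table = table, activity_col = activity_col,
              id_col = id_col, var_eps = var_eps,
              corr_threshold = corr_threshold,
              test_fraction = test_fraction,
              bmlr_max_size = as.integer(bmlr_max_size),
              bmlr_breakpoint = bmlr_breakpoint,
              bmlr_pair_corr_max = bmlr_pair_corr_max,
              bmlr_beam_width = as.integer(bmlr_beam_width),
              grid = as.data.frame(grid), k = as.integer(k),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks the configuration before any artifact is written, so a bad
#' config fails immediately with no partial outputs.
#'
#' @param cfg a `run_config`.
#' @return `cfg`, invisibly; errors otherwise.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$input) && is.null(cfg$table))
    stop("config needs either an input path or a descriptor table")
  if (!is.null(cfg$input) && !is.null(cfg$table))
    stop("supply input path or table, not both")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("input file not found: ", cfg$input)
  if (is.null(cfg$activity_col) || !nzchar(cfg$activity_col))
    stop("activity column name missing from config")
  if (!(cfg$test_fraction > 0 && cfg$test_fraction < 1))
    stop("test_fraction must lie in (0, 1)")
  if (cfg$k < 2L) stop("k must be at least 2")
  g <- cfg$grid
  need <- c("nterms", "max_terms", "df", "optlevel")
  if (!all(need %in% names(g)))
    stop("grid must have columns ", paste(need, collapse = ", "))
  if (any(g$nterms > g$max_terms))
    stop("grid contains cells with nterms > max_terms")
  invisible(cfg)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path config file; `.json`, or `.yaml`/`.yml` when the `yaml`
#'   package is available.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  grid_args <- raw$grid
  raw$grid <- NULL
  cfg_args <- raw[names(raw) %in% names(formals(run_config))]
  if (!is.null(grid_args))
    cfg_args$grid <- do.call(grid_spec, as.list(grid_args))
  do.call(run_config, cfg_args)
}

#' Write a run configuration as JSON
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$table <- NULL
  out$grid <- list(nterms = sort(unique(cfg$grid$nterms)),
                   max_terms = sort(unique(cfg$grid$max_terms)),
                   df = sort(unique(cfg$grid$df)),
                   optlevel = sort(unique(cfg$grid$optlevel)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.score_block <- function(y, pred) list(r2 = r2_score(y, as.numeric(pred)),
                                       rmse = rmse(y, as.numeric(pred)))

#' Run the full QSAR pipeline
#'
#' Executes prune, split, BMLR descriptor selection, grid-searched PPR on
#' the selected descriptors, and final train/test scoring, writing every
#' intermediate artifact into the output directory:
#' `pruned_table.tsv`, `removal_log.tsv`, `bmlr_report.tsv`,
#' `grid_surface.tsv`/`.json`, `ppr_model.json`, `predictions.tsv`,
#' `summary.json`, `config.json` and `run.log`. The summary holds the
#' train and test R^2/RMSE for both the linear (BMLR) and the nonlinear
#' (grid-search PPR) model — the usual head-to-head comparison table.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the summary, the fitted objects and
#'   artifact paths.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)
  logf <- path("run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("qsarppr %s | R %s | seed %d",
      as.character(utils::packageVersion("qsarppr")),
      paste(R.version$major, R.version$minor, sep = "."), cfg$seed)

  tab <- if (!is.null(cfg$table)) cfg$table
         else read_descriptor_table(cfg$input,
                                    activity_col = cfg$activity_col,
                                    id_col = cfg$id_col)
  say("input: %d compounds x %d descriptors", n_compounds(tab),
      length(descriptor_names(tab)))

  pruned <- prune_descriptors(tab, var_eps = cfg$var_eps,
                              corr_threshold = cfg$corr_threshold)
  rl <- attr(pruned, "removal_log")
  write_descriptor_table(pruned, path("pruned_table.tsv"))
  utils::write.table(rl, path("removal_log.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  say("prune: removed %d descriptors (%d constant, %d collinear); %d remain",
      nrow(rl), sum(rl$reason == "constant"),
      sum(rl$reason == "collinear"), length(descriptor_names(pruned)))

  if (!any(pruned$split != "unassigned")) {
    pruned <- split_train_test(pruned, test_fraction = cfg$test_fraction,
                               seed = cfg$seed)
  }
  say("split: %d train / %d test", sum(pruned$split == "train"),
      sum(pruned$split == "test"))

  sel <- bmlr(pruned, max_size = cfg$bmlr_max_size,
              breakpoint = cfg$bmlr_breakpoint,
              pair_corr_max = cfg$bmlr_pair_corr_max,
              beam_width = cfg$bmlr_beam_width)
  bmlr_report(sel, path("bmlr_report.tsv"))
  say("bmlr: selected %d descriptors (%s), train R2 %.4f",
      sel$selected_size,
      paste(sel$chosen$descriptor_names, collapse = "+"), sel$chosen$r2)

  selected <- sel$chosen$descriptor_names
  sub <- descriptor_table(pruned$values[, selected, drop = FALSE],
                          pruned$activity, pruned$compound_ids,
                          pruned$split)
  gs <- grid_search(sub, grid_spec(nterms = unique(cfg$grid$nterms),
                                   max_terms = unique(cfg$grid$max_terms),
                                   df = unique(cfg$grid$df),
                                   optlevel = unique(cfg$grid$optlevel)),
                    k = cfg$k, seed = cfg$seed)
  grid_report(gs, path("grid_surface"))
  b <- gs$best
  say("grid: best nterms=%d max_terms=%d df=%g optlevel=%d (CV RMSE %.4f)",
      b$nterms, b$max_terms, b$df, b$optlevel, b$cv_rmse)

  final <- suppressWarnings(
    ppr_fit(sub, nterms = b$nterms, max_terms = b$max_terms, df = b$df,
            optlevel = b$optlevel, seed = cfg$seed))
  ppr_save(final, path("ppr_model.json"))

  train <- split_rows(sub, "train"); test <- split_rows(sub, "test")
  pred <- data.frame(
    compound_id = sub$compound_ids, split = sub$split,
    y_exp = sub$activity,
    y_pred_bmlr = as.numeric(predict(sel, sub)),
    y_pred_gsppr = as.numeric(predict(final, sub)))
  utils::write.table(pred, path("predictions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  summary <- list(
    n_train = n_compounds(train), n_test = n_compounds(test),
    selected_descriptors = selected,
    bmlr = list(
      train = .score_block(train$activity, predict(sel, train)),
      test = .score_block(test$activity, predict(sel, test)),
      loo_r2_cv = sel$chosen$r2_cv),
    gsppr = list(
      hyperparams = list(nterms = b$nterms, max_terms = b$max_terms,
                         df = b$df, optlevel = b$optlevel),
      train = .score_block(train$activity, predict(final, train)),
      test = .score_block(test$activity, predict(final, test)),
      cv = list(k = cfg$k, r2 = b$cv_r2, rmse = b$cv_rmse)),
    seed = cfg$seed,
    artifacts = c("pruned_table.tsv", "removal_log.tsv",
                  "bmlr_report.tsv", "grid_surface.tsv",
                  "grid_surface.json", "ppr_model.json",
                  "predictions.tsv", "config.json"))
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_run_config(cfg, path("config.json"))
  say("bmlr   train R2 %.4f RMSE %.4f | test R2 %.4f RMSE %.4f",
      summary$bmlr$train$r2, summary$bmlr$train$rmse,
      summary$bmlr$test$r2, summary$bmlr$test$rmse)
  say("gs-ppr train R2 %.4f RMSE %.4f | test R2 %.4f RMSE %.4f",
      summary$gsppr$train$r2, summary$gsppr$train$rmse,
      summary$gsppr$test$r2, summary$gsppr$test$rmse)
  writeLines(log_lines, logf)
  invisible(list(summary = summary, bmlr = sel, grid = gs,
                 ppr = final, table = pruned, out_dir = cfg$out_dir))
}
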