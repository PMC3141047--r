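# Fit statistics for y ~ X[, subset] with intercept, given centred
# cross-products. Returns explained sum of squares; used by the beam
# search, where ranking by F at fixed size is equivalent to ranking by
# explained SS.
#   C    crossprod of centred descriptor columns
#   cy   crossprod of centred descriptors with centred y
.explained_ss <- function(C, cy, subset) {
  M <- tryCatch(solve(C[subset, subset, drop = FALSE]),
                error = function(e) NULL)
  if (is.null(M)) return(NA_real_)
  b <- M %*% cy[subset]
  drop(crossprod(cy[subset], b))
}

#' Ordinary least squares on a descriptor subset
#'
#' Fits activity on the named descriptors with an intercept and returns
#' the four statistics conventional in QSAR model tables: R^2 (squared
#' Pearson correlation of fitted vs observed), leave-one-out
#' cross-validated R^2, the squared standard error of estimate s^2, and
#' the Fisher F statistic.
#'
#' @param x a [descriptor_table()]; rows labelled `train` are used (all
#'   rows when nothing is labelled).
#' @param subset character vector of descriptor names.
#' @return an object of class `qsar_lm`: coefficients, intercept, n, r2,
#'   r2_cv, s2, f_stat, fitted values and residuals.
#' @export
fit_ols <- function(x, subset) {
  stopifnot(inherits(x, "descriptor_table"))
  tr <- suppressWarnings(split_rows(x, "train"))
  if (!length(subset)) stop("empty descriptor subset")
  missing <- setdiff(subset, descriptor_names(tr))
  if (length(missing))
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  X <- tr$values[, subset, drop = FALSE]
  y <- tr$activity
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L)
    stop("need n > p + 1 (n = ", n, ", p = ", p, ")")
  Xd <- cbind("(Intercept)" = 1, X)
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrx$pivot[(qrx$rank + 1L):ncol(Xd)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrx, y)
  fitted <- drop(Xd %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (stats::sd(fitted) > 0) stats::cor(fitted, y)^2 else 0
  s2 <- rss / (n - p - 1L)
  f_stat <- ((sst - rss) / p) / s2
  h <- rowSums(qr.Q(qrx)^2)
  r2_cv <- if (any(h >= 1 - 1e-10)) NA_real_
           else 1 - sum((res / (1 - h))^2) / sst
  structure(list(descriptor_names = subset,
                 coefficients = coefs[-1L], intercept = coefs[[1L]],
                 n = n, r2 = r2, r2_cv = r2_cv, s2 = s2, f_stat = f_stat,
                 fitted = fitted, residuals = res, leverage = h),
            class = "qsar_lm")
}

#' @export
print.qsar_lm <- function(x, digits = 4L, ...) {
  cat(sprintf(
    "Multi-linear QSAR model: %d descriptors, N = %d\n  R2 = %.4f, R2_cv(LOO) = %.4f, s2 = %.4f, F = %.2f\n",
    length(x$descriptor_names), x$n, x$r2, x$r2_cv, x$s2, x$f_stat))
  print(round(c("(Intercept)" = x$intercept, x$coefficients), digits))
  invisible(x)
}

#' @export
coef.qsar_lm <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' @export
residuals.qsar_lm <- function(object, ...) object$residuals

#' @export
fitted.qsar_lm <- function(object, ...) object$fitted

#' Predict activity from a linear QSAR model
#'
#' @param object a `qsar_lm` from [fit_ols()].
#' @param newdata a [descriptor_table()], matrix or data frame carrying
#'   the model's descriptor columns.
#' @param ... unused.
#' @return numeric vector of predicted pIC50 values.
#' @export
predict.qsar_lm <- function(object, newdata, ...) {
  X <- .as_descriptor_matrix(newdata, object$descriptor_names)
  drop(object$intercept + X %*% object$coefficients)
}

.as_descriptor_matrix <- function(newdata, cols) {
  if (inherits(newdata, "descriptor_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  missing <- setdiff(cols, colnames(newdata))
  if (length(missing))
    stop("newdata lacks descriptor(s): ", paste(missing, collapse = ", "))
  newdata[, cols, drop = FALSE]
}

#' Leave-one-out cross-validated R^2
#'
#' Computes LOO residuals by the closed-form hat-matrix identity
#' e_i / (1 - h_ii) — algebraically identical to refitting the model n
#' times with one compound held out each time — and returns
#' 1 - PRESS / SST.
#'
#' @inheritParams fit_ols
#' @return scalar (can be negative for models worse than the mean).
#' @export
loo_r2 <- function(x, subset) {
  fit <- fit_ols(x, subset)
  if (fit$n <= length(subset) + 2L)
    stop("need n > p + 2 for LOO")
  if (any(fit$leverage >= 1 - 1e-10))
    stop("leverage of 1: a compound is exactly determined by the fit")
  fit$r2_cv
}

#' Best multi-linear regression descriptor search
#'
#' A CODESSA-style heuristic best-subset search. Stage 1 ranks every
#' single descriptor by R^2. Stage 2 evaluates every descriptor pair whose
#' mutual |Pearson r| is below `pair_corr_max` and keeps the `beam_width`
#' best by the Fisher F statistic. Each later stage extends every retained
#' model with every descriptor not excessively correlated with any current
#' member, again retaining the `beam_width` best. Growth stops at
#' `max_size`, or earlier when the best R^2 gain from one more descriptor
#' falls below `breakpoint` — the guard against over-parameterised models;
#' the selected model is the last one before the breakpoint fired.
#'
#' The search is deterministic: ties in ranking are resolved by subset
#' order, and no randomness enters.
#'
#' @param x a [descriptor_table()]; rows labelled `train` are used.
#' @param max_size largest model size explored; kept below n/3 by
#'   convention (override with `size_guard = FALSE`).
#' @param breakpoint minimum R^2 gain required to grow the model, default
#'   0.02.
#' @param pair_corr_max collinearity ceiling between members of one model,
#'   default 0.8.
#' @param beam_width number of models retained per stage, default 400.
#' @param size_guard enforce `max_size < n / 3`.
#' @return an object of class `bmlr`: `models` (the per-size champions as
#'   [fit_ols()] objects), `chosen` (the selected model), `selected_size`,
#'   and `trace` (a per-size data frame of size, descriptors, r2, r2_cv,
#'   s2, f_stat).
#' @export
bmlr <- function(x, max_size = 10L, breakpoint = 0.02,
                 pair_corr_max = 0.8, beam_width = 400L,
                 size_guard = TRUE) {
  stopifnot(inherits(x, "descriptor_table"))
  tr <- suppressWarnings(split_rows(x, "train"))
  X <- tr$values
  y <- tr$activity
  n <- nrow(X); p <- ncol(X)
  if (size_guard && max_size >= n / 3)
    stop("max_size must stay below n/3 (n = ", n,
         "); set size_guard = FALSE to override")
  max_size <- min(max_size, p)

  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  C <- crossprod(Xc)
  cy <- drop(crossprod(Xc, yc))
  sst <- sum(yc^2)
  sds <- sqrt(diag(C))
  ok_var <- sds > 0
  corX <- abs(C / outer(sds, sds))
  adm <- corX < pair_corr_max & outer(ok_var, ok_var)
  diag(adm) <- FALSE

  # stage 1: all singles
  r2_single <- ifelse(ok_var, cy^2 / diag(C) / sst, -Inf)
  champions <- list(order(r2_single, decreasing = TRUE)[1L])
  best_ess <- r2_single * sst

  ess_by_size <- max(r2_single[ok_var]) * sst
  beam <- list(subsets = lapply(which(ok_var), identity),
               ess = best_ess[ok_var])

  size <- 1L
  while (size < max_size) {
    cand_sub <- list(); cand_ess <- numeric()
    # the pair stage enumerates every admissible pair; later stages extend
    # only the beam_width best current models
    ord <- order(beam$ess, decreasing = TRUE)
    keep <- if (size == 1L) ord
            else ord[seq_len(min(beam_width, length(ord)))]
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (bi in keep) {
      S <- beam$subsets[[bi]]
      cand <- which(rowSums(!adm[, S, drop = FALSE]) == 0L)
      cand <- cand[cand > 0 & !(cand %in% S)]
      if (size == 1L) cand <- cand[cand > S[1L]]  # unordered pairs once
      if (!length(cand)) next
      M <- tryCatch(solve(C[S, S, drop = FALSE]), error = function(e) NULL)
      if (is.null(M)) next
      b <- drop(M %*% cy[S])
      ess_S <- sum(cy[S] * b)
      U <- C[S, cand, drop = FALSE]
      denom <- diag(C)[cand] - colSums(U * (M %*% U))
      resid_cor <- cy[cand] - drop(crossprod(U, b))
      good <- denom > 1e-10 * diag(C)[cand]
      for (k in which(good)) {
        Snew <- sort(c(S, cand[k]))
        key <- paste(Snew, collapse = ",")
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        cand_sub[[length(cand_sub) + 1L]] <- Snew
        cand_ess[length(cand_sub)] <- ess_S + resid_cor[k]^2 / denom[k]
      }
    }
    if (!length(cand_sub)) {
      if (size == 1L)
        stop("no admissible descriptor pair: all descriptors mutually ",
             "correlated above pair_corr_max")
      warning("no admissible extension at size ", size + 1L,
              "; stopping early")
      break
    }
    ord <- order(cand_ess, decreasing = TRUE)
    keep <- ord[seq_len(min(beam_width, length(ord)))]
    beam <- list(subsets = cand_sub[keep], ess = cand_ess[keep])
    size <- size + 1L
    champions[[size]] <- beam$subsets[[1L]]
    ess_by_size[size] <- beam$ess[[1L]]
    gain <- (ess_by_size[size] - ess_by_size[size - 1L]) / sst
    if (gain < breakpoint) break
  }

  r2_by_size <- ess_by_size / sst
  breakpoint_fired <- length(r2_by_size) > 1L &&
    (r2_by_size[length(r2_by_size)] -
       r2_by_size[length(r2_by_size) - 1L]) < breakpoint
  selected_size <- if (breakpoint_fired) length(r2_by_size) - 1L
                   else length(r2_by_size)
  if (!breakpoint_fired && selected_size == max_size && max_size > 1L)
    warning("breakpoint criterion never fired; selecting max_size = ",
            max_size)

  models <- lapply(champions, function(S)
    fit_ols(tr, colnames(X)[S]))
  trace <- data.frame(
    size = seq_along(models),
    descriptors = vapply(models, function(m)
      paste(m$descriptor_names, collapse = "+"), character(1L)),
    r2 = vapply(models, `[[`, numeric(1L), "r2"),
    r2_cv = vapply(models, `[[`, numeric(1L), "r2_cv"),
    s2 = vapply(models, `[[`, numeric(1L), "s2"),
    f_stat = vapply(models, `[[`, numeric(1L), "f_stat"),
    stringsAsFactors = FALSE)
  structure(list(models = models, chosen = models[[selected_size]],
                 selected_size = selected_size, trace = trace,
                 breakpoint_fired = breakpoint_fired,
                 params = list(max_size = max_size,
                               breakpoint = breakpoint,
                               pair_corr_max = pair_corr_max,
                               beam_width = beam_width)),
            class = "bmlr")
}

#' @export
print.bmlr <- function(x, ...) {
  cat("BMLR descriptor search: selected size", x$selected_size,
      if (x$breakpoint_fired) "(breakpoint fired)" else
        "(breakpoint never fired)", "\n")
  print(x$chosen)
  invisible(x)
}

#' @export
summary.bmlr <- function(object, ...) {
  cat("Per-size champions:\n")
  print(object$trace, row.names = FALSE)
  invisible(object$trace)
}

#' @export
coef.bmlr <- function(object, ...) coef(object$chosen)

#' @export
predict.bmlr <- function(object, newdata, ...)
  predict(object$chosen, newdata, ...)

#' Write the per-size BMLR selection report
#'
#' One row per model size: descriptors, R^2, LOO R^2, s^2 and F — the
#' quantities usually plotted against model size to justify the selected
#' size.
#'
#' @param x a [bmlr()] object.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
bmlr_report <- function(x, path) {
  stopifnot(inherits(x, "bmlr"))
  utils::write.table(x$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
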