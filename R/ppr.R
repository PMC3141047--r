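# candidate starting directions for one ridge term: the least-squares
# direction of the residual on the standardized predictors (ridge-
# regularized when ill-conditioned), the coordinate axes, and a few
# seeded random draws. The least-squares start is ideal for monotone
# structure but blind to even (e.g. quadratic) ridges, whose linear
# trace is zero — the extra candidates let those be found too. The
# candidate whose df-matched smooth leaves the smallest residual SS
# seeds the Gauss-Newton refinement, so the choice is deterministic
# given data and seed.
.init_candidates <- function(Xs, r, seed) {
  p <- ncol(Xs)
  G <- crossprod(Xs)
  a <- tryCatch(drop(solve(G + diag(1e-8 * mean(diag(G)) + 1e-12, p),
                           crossprod(Xs, r))),
                error = function(e) rep(0, p))
  cands <- list()
  if (is.finite(sum(a^2)) && sum(a^2) > 1e-24)
    cands <- list(a / sqrt(sum(a^2)))
  if (p <= 25L)
    cands <- c(cands, lapply(seq_len(p), function(j) {
      e <- numeric(p); e[j] <- 1; e
    }))
  rand <- withr_seed(seed, replicate(3L, {
    v <- stats::rnorm(p)
    v / sqrt(sum(v^2))
  }, simplify = FALSE))
  c(cands, rand)
}

.init_direction <- function(Xs, r, df, seed) {
  best <- NULL
  best_rss <- Inf
  for (a in .init_candidates(Xs, r, seed)) {
    t <- drop(Xs %*% a)
    s <- tryCatch(smooth_ridge(t, r, df), error = function(e) NULL)
    if (is.null(s)) next
    rss <- sum((r - eval_smoother(s, t))^2)
    if (rss < best_rss) { best <- a; best_rss <- rss }
  }
  if (is.null(best))
    stop("no usable starting direction: all candidate projections ",
         "are degenerate")
  best
}

# evaluate `expr` under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

# fit one ridge term to residual r by alternating smoother refits with
# Gauss-Newton direction updates (step-halved so the residual SS never
# increases)
.fit_one_term <- function(Xs, r, df, a, tol, max_iter) {
  t <- drop(Xs %*% a)
  s <- smooth_ridge(t, r, df)
  g <- eval_smoother(s, t)
  rss <- sum((r - g)^2)
  converged <- FALSE
  final_delta <- NA_real_
  iters <- 0L
  for (iter in seq_len(max_iter)) {
    iters <- iter
    gp <- eval_smoother(s, t, deriv = 1L)
    Z <- Xs * gp
    e <- r - g
    da <- tryCatch({
      co <- qr.coef(qr(Z), e)
      co[is.na(co)] <- 0
      co
    }, error = function(err) rep(0, ncol(Xs)))
    if (sum(da^2) < 1e-24) { converged <- TRUE; final_delta <- 0; break }
    step <- 1
    accepted <- FALSE
    while (step >= 1 / 64) {
      a_new <- a + step * da
      nrm <- sqrt(sum(a_new^2))
      if (nrm > 1e-12) {
        a_new <- a_new / nrm
        t_new <- drop(Xs %*% a_new)
        s_new <- tryCatch(smooth_ridge(t_new, r, df),
                          error = function(err) NULL)
        if (!is.null(s_new)) {
          g_new <- eval_smoother(s_new, t_new)
          rss_new <- sum((r - g_new)^2)
          if (rss_new < rss) {
            final_delta <- (rss - rss_new) / max(rss, 1e-300)
            a <- a_new; t <- t_new; s <- s_new; g <- g_new
            rss <- rss_new
            accepted <- TRUE
            break
          }
        }
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; final_delta <- 0; break }
    if (final_delta < tol) { converged <- TRUE; break }
  }
  list(alpha = a, smoother = s, t = t, g = g, rss = rss,
       converged = converged, iters = iters, delta = final_delta)
}

# least-squares scales for the current term outputs; NA coefficients
# (collinear term outputs) become 0
.ls_beta <- function(H, yc) {
  b <- qr.coef(qr(H), yc)
  b[is.na(b)] <- 0
  b
}

#' Fit a projection pursuit regression model
#'
#' Approximates activity as a sum of ridge functions
#' \eqn{\hat y = \bar y + \sum_i \beta_i\, g_i(\alpha_i \cdot x)}: each
#' term projects the standardized descriptors onto a unit direction
#' \eqn{\alpha_i} and passes the projection through a smooth univariate
#' function \eqn{g_i} whose flexibility is set by `df` equivalent degrees
#' of freedom. Terms are grown greedily one at a time to `max_terms` —
#' each fitted by alternating a df-matched spline smooth of the current
#' residual with a Gauss-Newton update of the direction — then pruned
#' back to `nterms` by repeatedly dropping the least important term.
#'
#' `optlevel` controls how thoroughly the surviving terms are refitted
#' after each drop: at level 0 existing ridge terms are not refitted; at
#' level 1 the projection directions are kept but the ridge functions and
#' regression coefficients are refitted; levels 2 and 3 refit everything
#' including the directions (equivalent for a single response). Refits are
#' accepted only when they reduce the training residual sum of squares.
#' The final term scales \eqn{\beta_i} are always least squares on the
#' term outputs.
#'
#' @param x a [descriptor_table()] (rows labelled `train` are used) or a
#'   numeric predictor matrix.
#' @param y response vector; required when `x` is a matrix.
#' @param nterms number of ridge terms in the final model.
#' @param max_terms maximum number of terms grown before pruning,
#'   `>= nterms`.
#' @param df equivalent degrees of freedom of each ridge smoother.
#' @param optlevel refit thoroughness during pruning: 0, 1, 2 or 3.
#' @param seed integer; used only to break exact ties in direction
#'   initialization, so the fit is reproducible.
#' @param tol relative residual-SS change declaring a term converged.
#' @param max_iter maximum alternating iterations per term.
#' @return an object of class `ppr_fit` with elements `terms` (each a
#'   list: unit `alpha`, `smoother`, `beta`, `importance`), `center`,
#'   `scale`, `response_center`, `hyperparams`, `convergence`, `fitted`,
#'   `residuals`.
#' @examples
#' syn <- generate_table(synthetic_spec(n_compounds = 80, n_noise = 3,
#'                                      form = "ridge", seed = 7))
#' fit <- ppr_fit(syn$table, nterms = 2, max_terms = 4, df = 5)
#' fit
#' @export
ppr_fit <- function(x, y = NULL, nterms = 2L, max_terms = nterms,
                    df = 4, optlevel = 1L, seed = 1L, tol = 1e-4,
                    max_iter = 50L) {
  if (inherits(x, "descriptor_table")) {
    tr <- suppressWarnings(split_rows(x, "train"))
    X <- tr$values
    y <- tr$activity
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("y required when x is a matrix")
    if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  }
  nterms <- as.integer(nterms); max_terms <- as.integer(max_terms)
  if (nterms < 1L) stop("nterms must be >= 1")
  if (nterms > max_terms) stop("nterms must not exceed max_terms")
  if (!optlevel %in% 0:3) stop("optlevel must be 0, 1, 2 or 3")
  n <- nrow(X)
  if (n <= df + 2) stop("need n > df + 2")

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  ybar <- mean(y)
  yc <- y - ybar

  terms <- list()
  H <- matrix(numeric(), n, 0L)
  r <- yc
  iters <- integer(); deltas <- numeric(); conv <- logical()
  for (m in seq_len(max_terms)) {
    a0 <- .init_direction(Xs, r, df, seed + m)
    ft <- .fit_one_term(Xs, r, df, a0, tol, max_iter)
    terms[[m]] <- list(alpha = stats::setNames(ft$alpha, colnames(X)),
                       smoother = ft$smoother)
    H <- cbind(H, ft$g)
    # refit the existing terms around the newcomer, as thoroughly as
    # optlevel allows (level 1: smoothers and scales; 2-3: directions
    # too); greedy single passes otherwise lock in compromise
    # directions whenever the structure has more than one ridge
    if (optlevel >= 1L && m > 1L) {
      ref <- .backfit(Xs, yc, terms, H, df, optlevel, tol, max_iter)
      terms <- ref$terms; H <- ref$H
    }
    beta <- .ls_beta(H, yc)
    r <- yc - drop(H %*% beta)
    iters[m] <- ft$iters; deltas[m] <- ft$delta; conv[m] <- ft$converged
  }
  if (!all(conv))
    warning("ridge term(s) ", paste(which(!conv), collapse = ", "),
            " did not converge in ", max_iter, " iterations")

  # backward pruning to nterms
  while (length(terms) > nterms) {
    beta <- .ls_beta(H, yc)
    imp <- beta^2 * colSums(H^2)
    drop_ix <- which.min(imp)
    terms <- terms[-drop_ix]
    H <- H[, -drop_ix, drop = FALSE]
    if (optlevel >= 1L) {
      ref <- .backfit(Xs, yc, terms, H, df, optlevel, tol, max_iter)
      terms <- ref$terms; H <- ref$H
    }
  }

  beta <- .ls_beta(H, yc)
  fitted <- ybar + drop(H %*% beta)
  reg_ss <- beta^2 * colSums(H^2)
  total <- sum(reg_ss)
  for (i in seq_along(terms)) {
    terms[[i]]$beta <- beta[[i]]
    terms[[i]]$importance <- if (total > 0) reg_ss[[i]] / total
                             else NA_real_
  }
  structure(list(
    terms = terms, center = ctr, scale = scl, response_center = ybar,
    descriptor_names = colnames(X),
    hyperparams = list(nterms = nterms, max_terms = max_terms, df = df,
                       optlevel = as.integer(optlevel)),
    convergence = list(converged = all(conv), iters = iters,
                       final_delta = deltas),
    fitted = fitted, residuals = y - fitted, n = n),
    class = "ppr_fit")
}

# one-at-a-time refit of surviving terms on their partial residuals.
# optlevel 1 keeps directions; optlevel >= 2 re-runs the Gauss-Newton
# direction search per term. Each candidate refit is accepted only when
# the pooled residual SS (with least-squares scales) decreases.
.backfit <- function(Xs, yc, terms, H, df, optlevel, tol, max_iter,
                     passes = 2L) {
  rss_of <- function(H) {
    b <- .ls_beta(H, yc)
    sum((yc - drop(H %*% b))^2)
  }
  rss <- rss_of(H)
  for (pass in seq_len(passes)) {
    changed <- FALSE
    for (i in seq_along(terms)) {
      b <- .ls_beta(H, yc)
      partial <- yc - drop(H[, -i, drop = FALSE] %*% b[-i])
      t_i <- drop(Xs %*% terms[[i]]$alpha)
      cand <- if (optlevel >= 2L) {
        ft <- .fit_one_term(Xs, partial, df, terms[[i]]$alpha, tol,
                            max_iter)
        list(alpha = stats::setNames(ft$alpha, names(terms[[i]]$alpha)),
             smoother = ft$smoother, g = ft$g)
      } else {
        s_new <- tryCatch(smooth_ridge(t_i, partial, df),
                          error = function(e) NULL)
        if (is.null(s_new)) next
        list(alpha = terms[[i]]$alpha, smoother = s_new,
             g = eval_smoother(s_new, t_i))
      }
      H_new <- H
      H_new[, i] <- cand$g
      rss_new <- rss_of(H_new)
      if (rss_new < rss) {
        terms[[i]]$alpha <- cand$alpha
        terms[[i]]$smoother <- cand$smoother
        H <- H_new
        rss <- rss_new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(terms = terms, H = H)
}

#' @export
print.ppr_fit <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "Projection pursuit regression: %d ridge term(s) (grown to %d), df = %.1f, optlevel = %d\n",
    hp$nterms, hp$max_terms, hp$df, hp$optlevel))
  cat(sprintf("  n = %d, training R2 = %.4f, RMSE = %.4f\n", x$n,
              r2_score(x$fitted + x$residuals, x$fitted),
              sqrt(mean(x$residuals^2))))
  imp <- vapply(x$terms, `[[`, numeric(1L), "importance")
  cat("  term importance:", paste(sprintf("%.3f", imp), collapse = ", "),
      "\n")
  if (!x$convergence$converged)
    cat("  warning: not all terms converged\n")
  invisible(x)
}

#' @export
summary.ppr_fit <- function(object, ...) {
  print(object)
  for (i in seq_along(object$terms)) {
    tm <- object$terms[[i]]
    top <- sort(abs(tm$alpha), decreasing = TRUE)
    top <- names(top)[seq_len(min(5L, length(top)))]
    cat(sprintf("  term %d: beta = %.4f, leading loadings: %s\n", i,
                tm$beta,
                paste(sprintf("%s=%.3f", top, tm$alpha[top]),
                      collapse = ", ")))
  }
  invisible(object)
}

#' @export
residuals.ppr_fit <- function(object, ...) object$residuals

#' @export
fitted.ppr_fit <- function(object, ...) object$fitted

#' Predict activity from a fitted PPR model
#'
#' Standardizes the new descriptors with the training statistics and sums
#' the ridge-term contributions. Projections falling outside a term's
#' training range are evaluated by linear continuation of the smoother;
#' such rows are flagged in the `"extrapolated"` attribute of the result.
#'
#' @param object a [ppr_fit()] model.
#' @param newdata a [descriptor_table()], matrix or data frame with the
#'   training descriptor columns.
#' @param ... unused.
#' @return numeric vector of predicted pIC50 values, with a logical
#'   attribute `extrapolated` (one flag per row).
#' @export
predict.ppr_fit <- function(object, newdata, ...) {
  X <- .as_descriptor_matrix(newdata, object$descriptor_names)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  out <- rep(object$response_center, nrow(Xs))
  extra <- rep(FALSE, nrow(Xs))
  for (tm in object$terms) {
    t <- drop(Xs %*% tm$alpha)
    out <- out + tm$beta * eval_smoother(tm$smoother, t)
    extra <- extra | t < tm$smoother$range[1L] | t > tm$smoother$range[2L]
  }
  attr(out, "extrapolated") <- extra
  out
}

#' Plot the ridge functions of a PPR model
#'
#' One panel per term: the smoother over its training projection range,
#' scaled by the term coefficient.
#'
#' @param x a [ppr_fit()] model.
#' @param ... passed to [plot()].
#' @export
plot.ppr_fit <- function(x, ...) {
  k <- length(x$terms)
  op <- graphics::par(mfrow = c(1L, k))
  on.exit(graphics::par(op))
  for (i in seq_len(k)) {
    tm <- x$terms[[i]]
    tt <- seq(tm$smoother$range[1L], tm$smoother$range[2L],
              length.out = 200L)
    graphics::plot(tt, tm$beta * eval_smoother(tm$smoother, tt),
                   type = "l", xlab = sprintf("projection %d", i),
                   ylab = "contribution",
                   main = sprintf("term %d (imp. %.2f)", i,
                                  tm$importance), ...)
  }
  invisible(x)
}

#' Share of explained variation per ridge term
#'
#' The regression sum of squares attributable to each term (coefficient
#' squared times the term output sum of squares), normalized to sum to 1;
#' this is the ordering used when pruning terms.
#'
#' @param model a [ppr_fit()] model.
#' @return nonnegative vector summing to 1.
#' @export
term_importance <- function(model) {
  stopifnot(inherits(model, "ppr_fit"))
  imp <- vapply(model$terms, `[[`, numeric(1L), "importance")
  if (anyNA(imp)) stop("zero total regression sum of squares")
  imp
}

#' Save / load a PPR model as versioned JSON
#'
#' Serializes everything needed to evaluate the model exactly — term
#' directions, smoother knots and values, scales, standardization and
#' hyperparameters. Because evaluation always interpolates the stored
#' knot/value pairs, a reloaded model predicts identically.
#'
#' @param model a [ppr_fit()] model.
#' @param path JSON file path.
#' @return `ppr_save`: `path`, invisibly; `ppr_load`: a `ppr_fit` model.
#' @export
ppr_save <- function(model, path) {
  stopifnot(inherits(model, "ppr_fit"))
  payload <- list(
    format = "qsarppr/ppr", version = 1L,
    descriptor_names = model$descriptor_names,
    center = unname(model$center), scale = unname(model$scale),
    response_center = model$response_center,
    hyperparams = model$hyperparams,
    convergence = model$convergence,
    n = model$n,
    terms = lapply(model$terms, function(tm) list(
      alpha = unname(tm$alpha), beta = tm$beta,
      importance = tm$importance,
      knots = tm$smoother$knots, values = tm$smoother$values,
      df = tm$smoother$df, df_target = tm$smoother$df_target,
      range = tm$smoother$range)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ppr_save
#' @export
ppr_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "qsarppr/ppr"))
    stop("not a serialized PPR model: ", path)
  if (p$version != 1L) stop("unsupported model version: ", p$version)
  terms <- lapply(seq_len(nrow_or_len(p$terms)), function(i) {
    tm <- term_record(p$terms, i)
    list(alpha = stats::setNames(tm$alpha, p$descriptor_names),
         smoother = structure(list(knots = tm$knots, values = tm$values,
                                   df_target = tm$df_target, df = tm$df,
                                   lambda = NA_real_, range = tm$range),
                              class = "ridge_smoother"),
         beta = tm$beta, importance = tm$importance)
  })
  structure(list(
    terms = terms,
    center = stats::setNames(p$center, p$descriptor_names),
    scale = stats::setNames(p$scale, p$descriptor_names),
    response_center = p$response_center,
    descriptor_names = p$descriptor_names,
    hyperparams = as.list(p$hyperparams),
    convergence = as.list(p$convergence),
    fitted = NULL, residuals = NULL, n = p$n),
    class = "ppr_fit")
}

# jsonlite may simplify the term list to a data frame; index either form
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
term_record <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col)
    if (is.list(col)) col[[i]] else col[i])
  else x[[i]]
}
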