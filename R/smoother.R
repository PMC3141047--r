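#' Fit a df-matched ridge smoother
#'
#' Fits a one-dimensional cubic smoothing spline of partial residuals on
#' projected values, with the smoothing penalty calibrated so the
#' effective degrees of freedom (the trace of the linear smoother matrix)
#' matches `df`. The fit is stored as knot/value pairs and always
#' evaluated by natural-spline interpolation through them, which makes
#' evaluation identical before and after JSON serialization and gives
#' linear (bounded-slope) extrapolation beyond the training projection
#' range.
#'
#' With fewer than four distinct projected values a straight least-squares
#' line is fitted instead (a natural spline through two knots).
#'
#' @param t projected values (length >= 5).
#' @param r partial residuals, same length.
#' @param df requested equivalent degrees of freedom, `2 <= df < length(t)`.
#' @return an object of class `ridge_smoother`: `knots`, `values`,
#'   `df_target`, `df` (achieved trace), `lambda`, `range`.
#' @seealso [eval_smoother()]
#' @export
smooth_ridge <- function(t, r, df) {
  n <- length(t)
  if (length(r) != n) stop("t and r must have equal length")
  if (n < 5L) stop("need at least 5 points to smooth")
  if (df < 2) stop("df must be at least 2")
  if (df >= n) stop("df must be below the number of points")
  ux <- sort(unique(t))
  if (length(ux) < 2L)
    stop("degenerate projection: all projected values identical")
  if (length(ux) < 4L || df <= 2 + 1e-8) {
    co <- stats::coef(stats::lm.fit(cbind(1, t), r))
    knots <- range(ux)
    return(structure(list(knots = knots,
                          values = co[1L] + co[2L] * knots,
                          df_target = df, df = 2, lambda = Inf,
                          range = range(ux)),
                     class = "ridge_smoother"))
  }
  df_eff <- min(df, length(ux) - 1e-6)
  fit <- suppressWarnings(
    stats::smooth.spline(t, r, df = df_eff, all.knots = TRUE,
                         keep.data = FALSE))
  structure(list(knots = fit$x, values = fit$y, df_target = df,
                 df = fit$df, lambda = fit$lambda, range = range(ux)),
            class = "ridge_smoother")
}

#' Evaluate a ridge smoother
#'
#' Natural-spline interpolation through the stored knot/value pairs;
#' beyond the training range the natural spline continues linearly with
#' the boundary slope.
#'
#' @param s a `ridge_smoother` from [smooth_ridge()].
#' @param t points to evaluate at.
#' @param deriv 0 for the function, 1 for its first derivative.
#' @return numeric vector.
#' @export
eval_smoother <- function(s, t, deriv = 0L) {
  stopifnot(inherits(s, "ridge_smoother"))
  f <- stats::splinefun(s$knots, s$values, method = "natural")
  f(t, deriv = deriv)
}

#' @export
print.ridge_smoother <- function(x, ...) {
  cat(sprintf(
    "Ridge smoother: %d knots on [%.3g, %.3g], df %.2f (target %.2f)\n",
    length(x$knots), x$range[1L], x$range[2L], x$df, x$df_target))
  invisible(x)
}
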