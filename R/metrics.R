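#' Root-mean-square error
#'
#' `sqrt(mean((y_exp - y_pred)^2))`, the standard accuracy measure for
#' predicted pIC50 values.
#'
#' @param y_exp experimental values.
#' @param y_pred predicted values, same length.
#' @return nonnegative scalar.
#' @export
rmse <- function(y_exp, y_pred) {
  if (length(y_exp) != length(y_pred))
    stop("length mismatch: ", length(y_exp), " vs ", length(y_pred))
  if (!length(y_exp)) stop("empty vectors")
  sqrt(mean((y_exp - y_pred)^2))
}

#' Squared Pearson correlation
#'
#' The squared Pearson correlation coefficient between experimental and
#' predicted values — the R^2 convention used throughout QSAR model
#' reporting (affine-invariant, symmetric in its arguments).
#'
#' @param y_exp experimental values (non-constant).
#' @param y_pred predicted values (non-constant).
#' @return scalar in [0, 1].
#' @export
r2_score <- function(y_exp, y_pred) {
  if (length(y_exp) != length(y_pred))
    stop("length mismatch: ", length(y_exp), " vs ", length(y_pred))
  if (stats::sd(y_exp) == 0 || stats::sd(y_pred) == 0)
    stop("zero variance in input vector")
  stats::cor(y_exp, y_pred)^2
}
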