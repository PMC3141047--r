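#' Specification for a synthetic descriptor table
#'
#' Describes a descriptor table with planted structure for validating the
#' modelling pipeline end to end: a small set of informative descriptors
#' drives the activity through either a linear combination or a sum of
#' nonlinear ridge functions; collinear near-copies of the informative
#' columns and pure-noise columns pad the table to the wide shape typical
#' of QSAR descriptor sets (around a hundred compounds against hundreds
#' of descriptors).
#'
#' The default shape mirrors a conventional inhibitor study: 128
#' compounds, activity on a pIC50-like scale centred near 7, Gaussian
#' observation noise of 0.3 log units.
#'
#' @param n_compounds number of compounds, default 128.
#' @param n_informative number of activity-driving descriptors, default 3.
#' @param n_noise number of irrelevant standard-normal descriptors,
#'   default 100.
#' @param n_collinear_per_informative near-copies planted per informative
#'   descriptor, default 1.
#' @param form `"linear"` or `"ridge"` generative form.
#' @param coef linear coefficients (length `n_informative`); default
#'   `1.5, -1.0, 0.8, ...` recycled.
#' @param ridges for `form = "ridge"`: list of components, each
#'   `list(direction =, shape =, weight =)` with `direction` a vector
#'   over the informative descriptors (normalized internally) and `shape`
#'   one of `"square"`, `"sine"`, `"sigmoid"`. Default: two terms along
#'   fixed orthogonal directions — a monotone sigmoid main effect and a
#'   squared curvature term.
#' @param noise_sd standard deviation of the additive activity noise,
#'   default 0.3.
#' @param copy_noise_sd noise added to collinear copies, default 0.1
#'   (giving |r| around 0.995 with the parent column).
#' @param intercept activity baseline, default 7.
#' @param heavy_tail draw descriptors from a t(3) distribution instead of
#'   the standard normal.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 128L, n_informative = 3L,
                           n_noise = 100L,
                           n_collinear_per_informative = 1L,
                           form = c("linear", "ridge"), coef = NULL,
                           ridges = NULL, noise_sd = 0.3,
                           copy_noise_sd = 0.1, intercept = 7,
                           heavy_tail = FALSE, seed = 1L) {
  form <- match.arg(form)
  if (n_compounds <= n_informative + 2L)
    stop("n_compounds must exceed n_informative + 2")
  if (form == "linear") {
    if (is.null(coef))
      coef <- rep_len(c(1.5, -1.0, 0.8), n_informative)
    if (length(coef) != n_informative)
      stop("coef must have length n_informative")
  } else {
    if (is.null(ridges)) {
      # a monotone main effect plus a curvature term: nonlinear structure
      # that still leaves a linear trace for descriptor selection, as
      # real potency surfaces tend to
      d1 <- rep(1, n_informative)
      d2 <- if (n_informative >= 2L)
        c(1, -1, rep(0, n_informative - 2L)) else NULL
      ridges <- list(list(direction = d1, shape = "sigmoid",
                          weight = 1.5))
      if (!is.null(d2))
        ridges <- c(ridges,
                    list(list(direction = d2, shape = "square",
                              weight = 0.8)))
    }
    for (rg in ridges) {
      if (length(rg$direction) != n_informative)
        stop("ridge direction length must equal n_informative")
      if (!rg$shape %in% c("square", "sine", "sigmoid"))
        stop("unknown ridge shape: ", rg$shape)
    }
    ridges <- lapply(ridges, function(rg) {
      rg$direction <- rg$direction / sqrt(sum(rg$direction^2))
      rg
    })
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_collinear_per_informative =
                   as.integer(n_collinear_per_informative),
                 form = form, coef = coef, ridges = ridges,
                 noise_sd = noise_sd, copy_noise_sd = copy_noise_sd,
                 intercept = intercept, heavy_tail = heavy_tail,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.ridge_shape <- function(shape, t) {
  switch(shape,
         square = t^2,
         sine = sin(pi * t),
         sigmoid = tanh(t),
         stop("unknown ridge shape: ", shape))
}

#' Generate a synthetic descriptor table with known ground truth
#'
#' Draws the table described by a [synthetic_spec()]: informative columns
#' and noise columns are independent draws, collinear copies are the
#' informative columns plus small Gaussian perturbations, and the
#' activity is the generative form evaluated on the informative columns
#' plus observation noise. The same seed always reproduces the same
#' table.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `table` (a [descriptor_table()]) and `truth`
#'   (informative descriptor names, the generative form with its
#'   coefficients or ridge components, and the noiseless activity).
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_compounds
    ki <- spec$n_informative
    rdraw <- function(n) if (spec$heavy_tail) stats::rt(n, df = 3)
                         else stats::rnorm(n)
    Xi <- matrix(rdraw(n * ki), n, ki)
    colnames(Xi) <- paste0("inf", seq_len(ki))
    copies <- NULL
    if (spec$n_collinear_per_informative > 0L) {
      copies <- do.call(cbind, lapply(seq_len(ki), function(j) {
        m <- matrix(Xi[, j] +
                      stats::rnorm(n * spec$n_collinear_per_informative,
                                   sd = spec$copy_noise_sd),
                    n, spec$n_collinear_per_informative)
        colnames(m) <- paste0("inf", j, "_cp",
                              seq_len(spec$n_collinear_per_informative))
        m
      }))
    }
    noise <- NULL
    if (spec$n_noise > 0L) {
      noise <- matrix(rdraw(n * spec$n_noise), n, spec$n_noise)
      colnames(noise) <- paste0("noise", seq_len(spec$n_noise))
    }
    X <- cbind(Xi, copies, noise)
    signal <- if (spec$form == "linear") {
      drop(Xi %*% spec$coef)
    } else {
      Reduce(`+`, lapply(spec$ridges, function(rg)
        rg$weight * .ridge_shape(rg$shape, drop(Xi %*% rg$direction))))
    }
    noiseless <- spec$intercept + signal
    activity <- noiseless + stats::rnorm(n, sd = spec$noise_sd)
    ids <- sprintf("cmpd%03d", seq_len(n))
    tab <- descriptor_table(X, activity, ids)
    list(table = tab,
         truth = list(informative = colnames(Xi), form = spec$form,
                      coef = spec$coef, ridges = spec$ridges,
                      noiseless_activity = noiseless,
                      noise_sd = spec$noise_sd, seed = spec$seed))
  })
}

#' Write a synthetic table and its ground truth
#'
#' The table goes out in the same delimited format
#' [read_descriptor_table()] expects; the ground truth becomes a JSON
#' sidecar.
#'
#' @param syn result of [generate_table()].
#' @param table_path delimited-text output path.
#' @param truth_path JSON sidecar path.
#' @return the two paths, invisibly.
#' @export
write_synthetic <- function(syn, table_path, truth_path) {
  write_descriptor_table(syn$table, table_path)
  jsonlite::write_json(syn$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(table_path, truth_path))
}
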