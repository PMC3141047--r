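---
title: "Methods: linear and projection-pursuit QSAR modelling in qsarppr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear and projection-pursuit QSAR modelling in qsarppr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarppr)
```

## The modelling problem

Quantitative structure-activity relationship (QSAR) modelling regresses a
measured potency — here pIC50, the negative base-10 logarithm of the IC50
in nM — on numeric molecular descriptors computed from structure alone.
Descriptor tables are characteristically wide and redundant: on the order
of a hundred compounds against hundreds of descriptors, many of them
constant, nearly constant, or strongly intercorrelated. `qsarppr`
implements the two-stage strategy common in this setting:

1. **Best multi-linear regression (BMLR)** screens the descriptor pool
   and selects a small, weakly correlated subset that supports a good
   multi-linear model of the activity.
2. **Grid-search projection pursuit regression (GS-PPR)** then fits a
   nonlinear model on that subset, with its hyperparameters chosen by
   k-fold cross-validation over a grid rather than one-factor-at-a-time
   tuning.

The held-out test set enters only once, after every selection decision
has been made.

## Pre-filtering and splitting

`prune_descriptors()` removes descriptors with variance at most
`var_eps` (default `1e-12`, i.e. constancy up to floating point), then
greedily resolves pairs with |Pearson r| at or above `corr_threshold`
(default 0.99). Within a flagged pair the member with the larger mean
absolute correlation to all remaining descriptors is dropped, keeping
the more independent feature; exact ties drop the later column, so the
scan is deterministic and idempotent. Rows with missing or non-numeric
entries are rejected by default (`on_invalid = "reject"`) because silent
imputation would contaminate descriptor selection; an explicit drop
policy with a logged report is available.

`split_train_test()` holds out a seeded random fraction (default 25/128,
the conventional ~80/20 division at this cohort size) or an explicit id
list. `pca_diagnostic()` projects the selected descriptors onto their
first two principal components — computed from the correlation matrix,
since descriptor scales are heterogeneous — to check visually that test
compounds occupy the same descriptor space as the training compounds.

## BMLR: beam search with a breakpoint rule

`bmlr()` is a deterministic beam search. All single descriptors are
ranked by $R^2$; every pair whose mutual |r| is below `pair_corr_max`
(default 0.8) is evaluated, and the `beam_width` (default 400) best
models by Fisher F are retained; each later stage extends every retained
model with every admissible descriptor and retains the best again. At a
fixed size, ranking by F is equivalent to ranking by $R^2$, so retention
uses the explained sum of squares computed incrementally by block-matrix
updates rather than refitting each candidate.

Growth stops at `max_size` or as soon as the best attainable gain in
$R^2$ from one more descriptor falls below the **breakpoint** (default
0.02); the selected model is the last one before the breakpoint fired.
This is the usual guard against over-parameterisation: each accepted
descriptor must buy at least two points of explained variance. Reported
statistics per model are $R^2$ (squared Pearson correlation of fitted
and observed), the leave-one-out cross-validated $R^2$ computed by the
closed-form hat-matrix identity $e_i/(1-h_{ii})$, the squared standard
error of estimate $s^2$, and F.

## PPR: sums of ridge functions

`ppr_fit()` models the centred activity as
$$\hat y(x) = \bar y + \sum_{i=1}^{p} \beta_i\, g_i(\alpha_i^\top x_s),$$
where $x_s$ is the vector of standardized descriptors, each $\alpha_i$
is a unit-norm projection direction, and each $g_i$ is a univariate
smoother. Because interactions enter through linear projections rather
than partitions of the predictor space, the estimation problem stays
one-dimensional per term regardless of the number of descriptors.

**Smoothers.** Each $g_i$ is a cubic smoothing spline whose penalty is
calibrated so that the trace of the smoother matrix equals the requested
equivalent degrees of freedom `df` — the paper-facing smoothness control.
`df = 2` is exactly a straight line; larger values buy curvature. The
fitted spline is stored as knot/value pairs and always evaluated by
natural-spline interpolation through them, which (a) makes a serialized
and reloaded model evaluate identically to the in-memory one and (b)
gives linear, bounded-slope extrapolation beyond the training projection
range; extrapolated rows are flagged by `predict()`.

**Term fitting.** Terms are grown greedily to `max_terms`. A new term
starts from the best of a deterministic candidate pool — the
least-squares direction of the current residual, the coordinate axes,
and three seeded random draws — judged by the residual SS after one
smooth. The least-squares start is ideal for monotone structure but
blind to even (for example quadratic) ridges whose linear trace is
zero; the extra candidates let those be found. The direction is then
refined by Gauss-Newton steps using the smoother's derivative, with
step halving so the residual SS never increases, until the relative
change drops below `tol` (default `1e-4`) or `max_iter` (default 50)
iterations.

**Refitting levels.** After each term addition and after each pruning
drop, the surviving terms are revisited one at a time on their partial
residuals, as thoroughly as `optlevel` allows: at level 0 existing terms
are never refitted; at level 1 the ridge functions and the scale
coefficients are refitted but the directions are kept; levels 2 and 3
refit the directions too (they are equivalent for a single response, so
3 is an alias of 2). Refits are accepted only when they reduce the
pooled residual SS, which keeps the training fit monotone in refit
thoroughness. Refitting during growth matters in practice: a greedy
first term fitted to a two-ridge surface converges to a compromise
direction between the two, and only a direction-level refit (level 2+)
can rotate it back once the second term has claimed its share.

**Pruning.** From `max_terms` the model is cut back to `nterms` by
repeatedly dropping the term with the smallest share of the regression
sum of squares ($\beta_i^2 \sum_n g_i^2$, normalized — exposed as
`term_importance()`). Final scales $\beta$ are always least squares on
the term outputs, so training residuals are orthogonal to every term's
output.

## Grid search and evaluation

`grid_search()` evaluates the full cross product of candidate `nterms`,
`max_terms`, `df` and `optlevel` values (cells with
`nterms > max_terms` are skipped) by k-fold cross-validation (default
k = 5) on the training compounds only, with one shared, seeded,
size-balanced fold assignment so that cells are compared on identical
resamples. CV statistics are computed on the pooled out-of-fold
prediction vector (every compound predicted exactly once); per-fold
values are reported alongside. The selected cell minimizes pooled CV
RMSE with parsimony tie-breaks (smaller `nterms`, then `max_terms`,
then `df`). Tuning against the held-out test set — which optimization
surfaces in this literature sometimes suggest — is deliberately
avoided; both surfaces can still be exported and compared.

`rmse()` is $\sqrt{\tfrac1n \sum (y_{exp}-y_{pred})^2}$ and
`r2_score()` the squared Pearson correlation, the reporting conventions
of QSAR tables.

## Graph and geometry descriptors

Three interpretable descriptors that need only a connection table or 3D
coordinates are built in:

- `lp1()` — the leading eigenvalue of the unweighted adjacency matrix,
  a branching index (chains score lowest at fixed atom count, heavily
  branched graphs highest);
- `sic1()` — first-order structural information content: atoms are
  binned by (own element, multiset of neighbour elements) and the
  Shannon entropy of the class sizes is normalized by $\log_2 n$;
- `principal_moments()` / `pmic()` — eigenvalues of the mass-weighted
  inertia tensor about the centre of mass, sorted
  $I_A \le I_B \le I_C$; `pmic` reports $I_C$, following the standard
  spectroscopic convention, since "principal moment C" does not by
  itself pin down an axis. All three moments are exposed.

Topological descriptors default to the hydrogen-suppressed graph
(`hydrogen_policy = "heavy"`), matching common practice; explicit-H is a
flag. `sic1` ignores bond orders — the minimal defensible reading of
first-order neighbourhood symmetry; exact parity with any commercial
descriptor engine is not claimed. Descriptors requiring quantum-chemical
wavefunctions, leverage/GETAWAY matrices or dipole-weighted edge
adjacency are out of scope.

## The synthetic generator

`generate_table()` draws descriptor tables with known ground truth so
that every stage is testable without external data: independent
standard-normal descriptors (a t(3) option for heavy tails), collinear
near-copies of the informative columns (copy noise 0.1, giving
|r| ≈ 0.995), and an activity built either linearly or from ridge
components plus Gaussian noise (default 0.3 log units around a pIC50
baseline of 7). The default nonlinear surface is a monotone sigmoid
main effect plus an orthogonal squared curvature term — nonlinearity
with a linear trace, the regime where linear pre-selection remains
informative, as real potency surfaces tend to be.

What the generator does *not* emulate: scaffold clustering, activity
cliffs, heterogeneous descriptor marginals and discreteness, or
correlated noise-column blocks beyond the planted copies. Passing tests
therefore demonstrate correctness of the algorithms under controlled
structure, not performance claims about any particular chemical series.

```{r example, eval = FALSE}
syn <- generate_table(synthetic_spec(n_compounds = 128, form = "ridge",
                                     seed = 1))
cfg <- run_config(table = syn$table, test_fraction = 25 / 128, seed = 1,
                  out_dir = tempfile("qsar-run"))
res <- run_pipeline(cfg)
res$summary$gsppr$test
```

## Numerical choices and simulation scales

- Descriptor standardization uses training means and standard
  deviations; zero-spread columns standardize with scale 1 instead of
  dividing by zero.
- OLS fits go through QR; rank deficiency is an error naming the
  collinear columns rather than a silent drop.
- Leverage of 1 (an exactly determined point) makes LOO undefined and
  is reported as an error.
- The smoothing-spline trace calibration is delegated to the standard
  penalized-spline machinery with all knots retained, keeping the
  achieved trace within a few hundredths of the requested `df` at the
  cohort sizes used here.
- Validation simulations use cohorts of 100-300 compounds and up to
  ~100 noise descriptors, with 10-seed repetitions for the stochastic
  claims (planted-descriptor recovery, term-count detection, the
  linear-vs-nonlinear test comparison); term-count detection is checked
  at observation noise 0.4 and `optlevel = 2`, where a spurious extra
  ridge term measurably overfits in CV and direction refits can undo
  greedy compromises — at lower noise the extra term is nearly free and
  the identification becomes a coin flip.

## Known limitations

- The ridge smoother family is the df-matched smoothing spline; the
  variable-span local-linear "supersmoother" used by some PPR codes is
  not implemented, so bit-exact parity with other PPR implementations
  is neither expected nor claimed (differential agreement on smooth
  test problems is part of the test suite).
- The beam search is a heuristic: with a wide beam it provably matches
  exhaustive best-subset selection at small sizes (tested up to
  p = 10, size 3), but no optimality guarantee exists at screening
  scale.
- `bmlr()` retention ranks by F (equivalently per-size $R^2$); other
  implementations may rank by adjusted statistics and can select
  different champions when candidates are nearly tied.
- Single response only; classification and multi-response PPR are out
  of scope.
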