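# qsarppr

Linear and nonlinear QSAR modelling of compound potency from molecular
descriptor tables, for computational and medicinal chemists building
activity models from wide, redundant descriptor sets (on the order of a
hundred compounds against hundreds of descriptors).

The package implements a two-stage workflow:

1. **BMLR** — best multi-linear regression: a deterministic beam search
   over descriptor subsets with collinearity screening
   (|r| < `pair_corr_max` within a model) and a breakpoint stopping
   rule: growth stops once one more descriptor raises R² by less than
   `breakpoint` (default 0.02). Each candidate model reports R², the
   leave-one-out cross-validated R² (closed-form hat-matrix identity
   e_i/(1−h_ii)), s², and the Fisher F statistic.
2. **GS-PPR** — grid-search projection pursuit regression: the activity
   is modelled as a sum of ridge functions,

   ŷ(x) = ȳ + Σᵢ βᵢ gᵢ(αᵢᵀ x_s),

   with unit projection directions αᵢ, df-matched smoothing-spline
   ridge functions gᵢ, and least-squares scales βᵢ. The four
   hyperparameters — `nterms` (terms kept), `max_terms` (terms grown
   before pruning), `df` (equivalent degrees of freedom per smoother)
   and `optlevel` (refit thoroughness: 0 none, 1 smoothers and scales,
   2–3 directions too) — are selected by k-fold cross-validation over a
   full grid, on the training set only.

Supporting modules cover descriptor-table reading, validation and
pruning, reproducible train/test splitting, a PCA split diagnostic,
calculators for three graph/geometry descriptors (LP1, the leading
adjacency eigenvalue; SIC1, first-order structural information content;
PMIC, the largest principal moment of inertia), a synthetic
descriptor-table generator with planted linear/ridge structure, and an
end-to-end pipeline with a thin command-line front end
(`inst/scripts/qsar-ppr`).

## Worked example

```r
library(qsarppr)

# a synthetic inhibitor cohort: 128 compounds, 3 informative
# descriptors driving a sigmoid + square ridge surface, collinear
# copies and 100 noise columns
syn <- generate_table(synthetic_spec(n_compounds = 128, form = "ridge",
                                     seed = 1))
tab <- split_train_test(prune_descriptors(syn$table),
                        test_fraction = 25 / 128, seed = 1)
tab
#> Descriptor table: 128 compounds x 103 descriptors
#>   activity (pIC50) range: 5.084 .. 12.388
#>   split: train=103, test=25, unassigned=0

sel <- bmlr(tab, max_size = 8)   # linear stage
sel$chosen
#> Multi-linear QSAR model: 8 descriptors, N = 103
#>   R2 = 0.6249, R2_cv(LOO) = 0.5379, s2 = 0.8143, F = 19.57

sub <- descriptor_table(tab$values[, sel$chosen$descriptor_names],
                        tab$activity, tab$compound_ids, tab$split)
gs <- grid_search(sub, grid_spec(nterms = 1:4, max_terms = c(4, 7),
                                 df = c(4, 8), optlevel = c(0, 1)),
                  k = 5, seed = 1)
gs
#> PPR grid search: 32 cells, 5-fold CV
#>   best: nterms=3, max_terms=7, df=4, optlevel=1
#>   (CV RMSE 0.5324, CV R2 0.8587)

fit <- ppr_fit(sub, nterms = 3, max_terms = 7, df = 4, optlevel = 1,
               seed = 1)
test <- split_rows(sub, "test")
r2_score(test$activity, as.numeric(predict(fit, test)))   # 0.8615
rmse(test$activity, as.numeric(predict(fit, test)))       # 0.6066
```

On this cohort the linear model reaches test R² 0.31 (RMSE 1.42) while
the grid-searched PPR model reaches test R² 0.86 (RMSE 0.61): the
nonlinear stage recovers the planted curvature that no linear
combination of descriptors can express. The selected model's three
ridge terms carry importance shares 0.49/0.43/0.08 — two genuine
structure terms and one minor correction.

The same analysis runs in one call (and writes all artifacts — pruned
table, selection report, grid surface, serialized model, per-compound
predictions, summary JSON) via:

```r
res <- run_pipeline(run_config(table = syn$table, seed = 1,
                               out_dir = "qsarppr-run"))
```

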