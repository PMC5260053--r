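# stabsvm

Stable feature selection for high-dimensional binary classification —
biomarker discovery from expression matrices (bulk or single-cell RNA-seq,
microarray) where features vastly outnumber samples and naive selection is
irreproducible: tiny changes in the sample set swap large parts of the
selected gene list.

`stabsvm` selects features with an **ensemble of L1-norm support vector
machines**. The base learner is the L1-regularized squared-hinge SVM

```
min_{w,b}  ||w||_1 + C * sum_i max(0, 1 - y_i (w'x_i + b))^2
```

whose solution is sparse — the fitted support *is* the selected set, with
at most n (samples) active features. On each of n_b class-stratified
resamples (default 1000 draws of 80% of the data), the package tunes C by
cross-validated AUC, fits, drops zero-weight features, and iterates until
no further reduction helps; the AUC-best iteration per resample is kept.
A feature's **stability score S** (1 ≤ S ≤ n_b) is the number of resamples
whose optimal set retained it. Features are ranked by S, and a
**stability-ranked backward elimination** with a grid-tuned RBF-kernel SVM
scores every ranked prefix by cross-validated AUC and returns the
AUC-maximizing subset — an optimal feature set without a hand-set cutoff.
Selection stability is quantified by the mean pairwise **Tanimoto (Jaccard)
similarity** of the sets selected on random subsamples.

The package includes a seeded synthetic expression-data generator with
planted ground truth (informative features, correlated blocks, class
imbalance), delimited-text IO, broom-style `tidy()`/`glance()` and
ggplot2 `autoplot()` methods, and a command-line interface.

## Worked example

A desk-scale run on synthetic data with 10 planted informative features
among 1000, 200 samples at 3:1 class imbalance:

```r
library(stabsvm)

sim   <- simulate_expression(synthetic_spec(seed = 7))
split <- train_test_split(sim$dataset, test_fraction = 0.2, seed = 7)

cfg <- run_config(
  n_bootstraps = 50, cv_folds = 5,
  c_grid_selection = 10^(-2:2),
  c_grid_rbf = 10^(0:2), gamma_grid_rbf = 10^(-3:-1),
  seed = 7
)

sel <- ensemble_select(split$train, cfg)
sel
#> <ensemble_selection> 50 resamples, 193 features with S >= 1 (top score 50)
head(tidy(sel), 5)
#> # A tibble: 5 × 3
#>    rank feature_id stability_score
#>   <int> <chr>                <int>
#> 1     1 g0028                   50
#> 2     2 g0876                   50
#> 3     3 g0394                   50
#> 4     4 g0247                   50
#> 5     5 g0838                   50
sum(sim$truth %in% head(sel$ranking$feature_id, 15))
#> [1] 9
```

Nine of the ten planted features sit in the top 15 by stability (the
top-ranked genes all survived every one of the 50 resamples). Refining the
purified ranking by backward elimination and evaluating the chosen subset
on the untouched 20% test set:

```r
cfg$cv_folds <- 3L
stable <- stable_feature_set(sel, min_fraction = 0.1)
ranked <- head(sel$ranking$feature_id[sel$ranking$feature_id %in% stable], 40)
be <- backward_eliminate(split$train, ranked, cfg)
be
#> <backward_elimination> 40 sizes scored; optimum: 5 features, CV AUC 1.000

evaluate_on_holdout(split$train, split$test, be$optimal_subset, cfg)[
  , c("accuracy", "f1", "mcc", "auc")]
#> # A tibble: 1 × 4
#>   accuracy    f1   mcc   auc
#>      <dbl> <dbl> <dbl> <dbl>
#> 1     0.95 0.909 0.882     1
```

The backward curve peaks at a 5-gene subset whose cross-validated AUC is
1.000 on this strongly separable synthetic cohort; on the independent test
set the subset reaches AUC 1.0 with accuracy 0.95. `autoplot(be)` draws
the AUC-versus-subset-size curve with the optimum highlighted;
`autoplot(sel)` shows the stability-score ranking.

Selection stability of the full method versus the same eliminator without
instance perturbation is measured by
`run_stability_experiment(dataset, "ensemble" | "single", ...)`, which
returns mean and SD of the pairwise Tanimoto similarity across subsample
selections.

## Command line

```sh
Rscript inst/cli/stabsvm.R simulate --n-samples 200 --n-features 1000 --seed 7 \
    --out-matrix m.tsv --out-labels l.tsv --out-truth t.tsv
Rscript inst/cli/stabsvm.R select --matrix m.tsv --labels l.tsv \
    --n-bootstraps 1000 --folds 10 --seed 7 --out report.json --ranked-out features.tsv
Rscript inst/cli/stabsvm.R backward --matrix m.tsv --labels l.tsv \
    --ranked features.tsv --out backward.json --curve-out curve.tsv
Rscript inst/cli/stabsvm.R stability --matrix m.tsv --labels l.tsv \
    --selector ensemble --n-subsamples 20 --out stability.json
```

Every subcommand accepts `--config file.yaml` mirroring its flags (flags
override the file) and echoes the resolved configuration into its JSON
report for provenance.

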