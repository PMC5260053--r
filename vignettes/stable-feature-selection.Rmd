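---
title: "Stable feature selection with ensemble L1-norm SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable feature selection with ensemble L1-norm SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabsvm)
```

## The problem

Biomarker discovery from expression data is a feature-selection problem in
the p >> n regime: tens of thousands of genes, at most a few hundred
samples, and often strong class imbalance (e.g. early-stage versus
advanced-stage tumours at 3:1). Sparse linear classifiers handle the
dimensionality well, but their selections are notoriously irreproducible:
perturbing the sample set slightly can swap large parts of the selected
gene set, and among correlated genes an L1 penalty tends to keep one
member of a group and silently drop the rest. A gene list that changes
with every resample is a poor biomarker candidate list, however well it
classifies.

`stabsvm` addresses this with an ensemble: the sparse selection is
repeated on many resampled versions of the data and the results are
aggregated into a per-feature **stability score**, which then drives a
backward search for the best-performing subset.

## The model

The sparse base learner is the L1-regularized squared-hinge support
vector machine

$$
\min_{w,\,b}\ \|w\|_1 \;+\; C \sum_{i=1}^{n}
\max\!\bigl(0,\ 1 - y_i (w^\top x_i + b)\bigr)^2 ,
$$

with a linear kernel $k(x, y) = x^\top y$. The L1 penalty drives most
coordinates of $w$ to exactly zero, so the fitted support *is* the
selected feature set, and for data in general position its size is
bounded by the number of samples — exactly what is needed when
p >> n. The squared hinge makes the loss differentiable, which the
solver exploits (see *Numerical design* below).

### The ensemble loop

For a training set $X$ with labels in $\{+1, -1\}$:

1. Draw $n_b$ class-stratified resamples, each containing a fraction
   $f$ of the samples (defaults $n_b = 1000$, $f = 0.8$, drawn
   **without** replacement).
2. On each resample, tune $C$ over a decade grid
   ($10^{-5} \dots 10^{4}$ by default) by mean AUC under stratified
   k-fold cross-validation (default $k = 10$); ties go to the smaller,
   more regularized $C$.
3. Fit the L1-SVM at the tuned $C$ and **eliminate** every feature with
   a zero coefficient; record the cross-validated AUC of the reduced
   set.
4. Repeat tuning, fitting and elimination on the shrinking feature set
   until a fit eliminates nothing further, until all weights vanish
   (the previous set then stands), or until one feature remains.
5. Keep, for each resample, the recorded iteration with the highest
   cross-validated AUC — elimination is only accepted as far as it
   helped.
6. The **stability score** $S$ of a feature is the number of resamples
   whose optimal surviving set contains it ($1 \le S \le n_b$; features
   never kept are dropped).

AUC rather than accuracy is the criterion throughout because the target
cohorts are imbalanced; accuracy is maximized by the trivial
majority-class classifier long before a useful decision boundary exists.

### Backward elimination

Stability ranks features, but gives no cutoff. The refinement phase
takes the stability-ranked list (ties broken by mean absolute fitted
weight, then lexicographically — the ranking is fully deterministic) and
scores every prefix of size $k, k-1, \dots, 1$ by cross-validated AUC of
an RBF-kernel SVM, $k(x,y) = \exp(-\gamma |x-y|^2)$, with $(C, \gamma)$
grid-tuned per subset size (defaults $C \in 10^{-5}..10^{10}$,
$\gamma \in 10^{-9}..10^{3}$ by decades). The RBF kernel is appropriate
here because the feature count after purification is modest. The fold
partition is drawn once and reused across all sizes, so curve points
differ only in the feature set, not in fold noise. The returned optimum
is the prefix with the maximal mean AUC; exact ties across sizes go to
the smallest subset (parsimony).

### Stability evaluation

Selection stability is measured by the Tanimoto set similarity

$$
T(S_i, S_j) = 1 - \frac{|S_i| + |S_j| - 2|S_i \cap S_j|}
                        {|S_i| + |S_j| - |S_i \cap S_j|}
            = \frac{|S_i \cap S_j|}{|S_i \cup S_j|},
$$

averaged over all $n(n-1)/2$ unordered pairs of selections obtained on
random 80% subsamples of the data (default 20 subsamples). A method
whose mean pairwise $T$ is higher reselects the same features more
consistently. The reported standard deviation is the population SD of
the pairwise values — the only population of more than one value a
single experiment provides. Note the printed double-sum form of the
multi-set mean is read as the sum over unordered pairs $i < j$; any
other index reading is inconsistent with its $2/(n(n-1))$ normalizer.

In `run_stability_experiment()` the `"ensemble"` selector is the method
end-to-end: ensemble selection, purification to features with
$S \ge 10\%\, n_b$ (a practical cut for pushing the feature count well
below the sample count), and backward elimination to the AUC-optimal
subset. The `"single"` baseline is the same elimination loop run once
on the full subsample without instance perturbation — the configuration
whose instability motivates the ensemble.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_bootstraps` | 1000 | ensemble size $n_b$; stability scores converge with growing $n_b$, and runtime is linear in it |
| `subsample_fraction` | 0.8 | fraction of samples per resample (dimensionless) |
| `with_replacement` | `FALSE` | `TRUE` switches to classical bagging; the default subsampling matches "resamples containing 80% of the data" |
| `cv_folds` | 10 | folds of every internal cross-validation; must not exceed the minority class count |
| `c_grid_selection` | $10^{-5}..10^{4}$ | decade grid for the linear phase |
| `c_grid_rbf`, `gamma_grid_rbf` | $10^{-5}..10^{10}$, $10^{-9}..10^{3}$ | decade grids for the RBF phase |
| `zero_tolerance` | $10^{-10}$ | magnitude at or below which a coefficient counts as zero; guards float dust without touching genuine small weights |
| `stratified` | `TRUE` | class-stratified resamples and folds; with 3:1 imbalance, unstratified draws can produce single-class folds |
| `seed` | 1 | every random draw in a run derives from it |

## The synthetic data generator

`simulate_expression()` produces the test bed: a standardized
samples-by-features Gaussian matrix with

* a chosen number of **informative features** whose class-conditional
  means differ by `effect_size` (in units of the within-class SD;
  default 1.5),
* optional **equicorrelated blocks** (default three blocks of five at
  $\rho = 0.7$) that are class-neutral unless `class_linked_blocks` is
  set, in which case they model redundant signal groups — the regime
  where a single L1 fit keeps one group member and the ensemble spreads
  stability scores across the group,
* independent Gaussian noise everywhere else, and
* labels hitting `class_ratio` exactly (rounded), default 0.25 as in
  staged tumour cohorts.

The default shape is 200 x 1000 — a deliberate desk-scale rendition of
a cohort of a few hundred samples by twenty thousand genes; the
generator accepts the full-scale shape but the test suite does not use
it. What the generator does **not** emulate: count noise
(negative-binomial mean-variance coupling), library-size and batch
effects, heavy-tailed expression, or annotation errors. Passing tests
therefore demonstrate that the algorithm recovers planted structure
under idealized Gaussian noise, not that it is robust to every artefact
of real sequencing data.

At the default effect size the planted signal is strong: an 8-feature
subset already separates classes almost perfectly, which is the
intended regime for testing *recovery* (the calibration requirement is
that a single tuned L1 fit retains most of the truth). A side effect
worth knowing: cross-validated AUC curves saturate at exactly 1.0 over
many subset sizes, so the parsimony tie-break of the backward phase
legitimately returns very small subsets on such data.

## Numerical design

The L1-SVM solver is written for this package (no installed R solver
fits the L1-penalized squared-hinge form; `glmnet` penalizes different
losses and the libsvm-based packages solve L2 duals). It is a cyclic
coordinate-descent with per-coordinate Newton steps and an Armijo line
search, in the style of the liblinear family the method was designed
around, with three package-specific choices:

* **Stopping rule.** Iteration stops when the L1 norm of the
  minimum-norm subgradient falls below `tol` times
  $\max(1, \min(\text{first-sweep violation}, p))$. Capping the scale
  at the coordinate count matters at large $C$: the first-sweep
  gradient grows with $C$ while each coordinate's violation near an
  optimum is $O(1)$ (the unit L1 subgradient), so an uncapped relative
  rule declares victory after two sweeps with a grossly dense iterate.
  Defaults: `tol` $10^{-3}$ and 1000 sweeps per phase, with $10^{-2}$
  and a 150-sweep cap inside cross-validated tuning, where only the
  AUC ranking of grid values matters.
* **Continuation.** For $C > 10$ without a warm start, the solver first
  runs loose solves along a decade-spaced path up to $C$. A separable
  problem at large $C$ is an L1-minimization LP in disguise; cold-started
  coordinate descent zig-zags there, while each decade jump from a warm
  start is mild.
* **Active-set polish.** After the main solve, the support is re-solved
  tightly and rechecked against the full problem, collapsing coefficient
  dust to exact zeros. The per-round sweep budget is scaled to the
  support size, and is escalated only when the support exceeds the
  sample count — a certificate of non-convergence, since the exact
  solution cannot have more than $n$ active coefficients for data in
  general position. Inside the ensemble loop a lighter polish profile
  is used; residual dust there survives one iteration at most, because
  the next iteration re-fits on the reduced set.

Coordinate order is randomized by a fixed-seed internal generator, so
every fit is bit-reproducible for given data and $C$. AUC is computed
rank-based with midranks (the Mann–Whitney form), which is exactly the
ROC integral and threshold-free; decision values of the linear model
are $w^\top x + b$.

Other conventions: the positive class defaults to the minority class
(the advanced stage in the motivating cohorts — a declared positive
class is required by F1, MCC and AUC); MCC with a zero denominator
factor is reported as 0 with `mcc_defined = FALSE`; an elimination
iteration in which *all* weights vanish does not emit an empty set (the
previous set stands); per-class test-set sizes in
`train_test_split()` are `round(fraction * n_class)`, which reproduces
standard staged-cohort arithmetic (352 samples at 268/84 give an 80/20
split of 281/71); and missing values are a hard error in the reader —
upstream filtering is out of scope, so refusing beats silent dropping.

## Desk-scale test conditions

The shipped test-suite and acceptance script run the full pipeline at
reduced scale, chosen once: 50-resample ensembles on 200 x 1000
matrices, 3–5 cross-validation folds, the reduced grids
$C \in 10^{-2}..10^{2}$ (linear), $C \in \{1, 10, 100\} \times \gamma
\in \{10^{-3}, 10^{-2}, 10^{-1}\}$ (RBF), and backward elimination
started from the top 30–40 ranked features (the size-floor guard also
exposed on the command line). The full-scale defaults remain the
documented protocol; nothing in the algorithm depends on the reduced
sizes.

## Known limitations

* Binary classification only; no multi-class extension.
* The stability score is a count, not a probability with error control:
  it orders features but does not bound false selections.
* Backward elimination evaluates *prefixes* of the stability ranking
  only; it never reorders, so a feature ranked low by stability cannot
  re-enter even if it would complement the top set.
* Cross-validated AUC of subsets selected on the same data is optimistic
  (selection bias); honest performance numbers must come from
  `evaluate_on_holdout()` on samples untouched by selection, and the
  package refuses train/test overlap outright.
* The method is stochastic by nature; results are reproducible only
  through the seed discipline of `run_config()`.
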