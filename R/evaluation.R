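#' Confusion-matrix classification metrics
#'
#' Accuracy, F1 and the Matthews correlation coefficient from raw
#' confusion counts:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), F1 = 2TP/(2TP+FP+FN),
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' When any MCC denominator factor is zero (e.g. the classifier never
#' predicts one class) the MCC is reported as 0 with `mcc_defined =
#' FALSE`.
#'
#' @param tp,tn,fp,fn Non-negative integer counts; `tp` may also be a
#'   list/tibble with fields `tp`, `tn`, `fp`, `fn`.
#' @return A one-row tibble: `accuracy`, `f1`, `mcc`, `mcc_defined`.
#' @examples
#' confusion_metrics(45, 40, 10, 5)
#' @export
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp
    tn <- counts$tn
    fp <- counts$fp
    fn <- counts$fn
  }
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (anyNA(v) || any(v < 0)) abort("counts must be non-negative numbers")
  total <- tp + tn + fp + fn
  if (total < 1) abort("at least one count must be positive")
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc_defined <- denom2 > 0
  tibble::tibble(
    accuracy = (tp + tn) / total,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    mcc = if (mcc_defined) {
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
    } else 0,
    mcc_defined = mcc_defined
  )
}

# Confusion counts of +1/-1 predictions against +1/-1 truth.
confusion_counts <- function(predicted, actual) {
  list(
    tp = sum(predicted == 1 & actual == 1),
    tn = sum(predicted == -1 & actual == -1),
    fp = sum(predicted == 1 & actual == -1),
    fn = sum(predicted == -1 & actual == 1)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for ties: the probability
#' that a random positive scores above a random negative, counting ties
#' as half. Threshold-free, and exactly the integral of the ROC curve.
#'
#' @param scores Numeric decision values (higher = more positive).
#' @param labels Class labels, +1/-1 (or anything [expression_dataset()]
#'   accepts via two levels; positives are `labels > 0` for numeric).
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1))
#' @export
auc_score <- function(scores, labels) {
  if (!is.numeric(labels)) labels <- encode_labels(labels)
  pos <- labels > 0
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort("both classes required for AUC")
  if (any(!is.finite(scores))) abort("scores must be finite")
  r <- rank(scores) # midranks
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Tanimoto similarity of two feature sets
#'
#' T(A, B) = 1 - (|A| + |B| - 2|A∩B|) / (|A| + |B| - |A∩B|), which
#' reduces algebraically to the Jaccard index |A∩B| / |A∪B|: 1 for
#' identical sets, 0 for disjoint ones.
#'
#' @param set_a,set_b Character vectors (duplicates ignored). At least
#'   one must be non-empty.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c("a", "b", "c"), c("b", "c", "d"))
#' @export
tanimoto <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (length(a) == 0 && length(b) == 0) {
    abort("Tanimoto similarity is undefined for two empty sets")
  }
  inter <- length(intersect(a, b))
  1 - (length(a) + length(b) - 2 * inter) /
    (length(a) + length(b) - inter)
}

#' Mean pairwise Tanimoto similarity of several feature sets
#'
#' The selection-stability statistic: the arithmetic mean of T over all
#' n(n-1)/2 unordered pairs of sets, with the population standard
#' deviation of the pairwise values.
#'
#' @param subsets List of at least two character vectors.
#' @return An object of class `stability_report`: list with
#'   `mean_tanimoto`, `sd_tanimoto`, `n_subsamples`, and `per_pair`
#'   (tibble `i`, `j`, `tanimoto`).
#' @examples
#' mean_tanimoto(list(c("a", "b"), c("a", "b"), c("b", "c")))
#' @export
mean_tanimoto <- function(subsets) {
  n <- length(subsets)
  if (n < 2) abort("need at least two sets")
  pairs <- utils::combn(n, 2)
  tt <- vapply(seq_len(ncol(pairs)), function(k) {
    tanimoto(subsets[[pairs[1, k]]], subsets[[pairs[2, k]]])
  }, numeric(1))
  structure(list(
    mean_tanimoto = mean(tt),
    sd_tanimoto = sqrt(mean((tt - mean(tt))^2)),
    n_subsamples = n,
    per_pair = tibble::tibble(
      i = pairs[1, ], j = pairs[2, ], tanimoto = tt
    )
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> mean Tanimoto %.3f (sd %.3f) over %d sets (%d pairs)\n",
    x$mean_tanimoto, x$sd_tanimoto, x$n_subsamples, nrow(x$per_pair)
  ))
  invisible(x)
}

#' Selection-stability experiment over random subsamples
#'
#' Draws `n_subsamples` stratified subsamples of the dataset (each a
#' `fraction` of the samples), runs the chosen selector end-to-end on
#' each, and summarizes the pairwise Tanimoto similarity of the selected
#' sets. The `"ensemble"` selector is the full method: stability
#' selection via [ensemble_select()], purification to features scoring
#' at least `min_stability_fraction` of the ensemble size, and
#' stability-ranked [backward_eliminate()] down to the CV-AUC-maximizing
#' subset. `"single"` is the no-perturbation baseline
#' [select_single_dataset()].
#'
#' @param dataset An [expression_dataset()].
#' @param selector `"ensemble"` or `"single"`.
#' @param n_subsamples Number of random subsamples (default 20).
#' @param fraction Subsample fraction (default 0.8).
#' @param config A [run_config()] forwarded to the selector; its seed
#'   drives the subsample draws and all nested runs.
#' @param min_stability_fraction Stability threshold gating the backward
#'   phase of the ensemble selector.
#' @param backward Refine the ensemble selection by backward elimination
#'   (the full method; disable for a raw thresholded selection).
#' @param max_backward_size Size floor-guard: backward elimination starts
#'   from at most this many top-ranked features, keeping desk-scale
#'   experiments tractable.
#' @return A `stability_report` (see [mean_tanimoto()]) with attributes
#'   `selector` and `subsets`.
#' @export
run_stability_experiment <- function(dataset,
                                     selector = c("ensemble", "single"),
                                     n_subsamples = 20L, fraction = 0.8,
                                     config = run_config(),
                                     min_stability_fraction = 0.1,
                                     backward = TRUE,
                                     max_backward_size = 50L) {
  selector <- match.arg(selector)
  check_dataset(dataset)
  n <- n_samples(dataset)
  size <- floor(fraction * n)
  counts <- table(dataset$labels)
  per_class <- allocate_per_class(as.integer(counts), size)
  names(per_class) <- names(counts)

  seeds <- derive_seeds(config$seed, 2L * n_subsamples)
  draw_seeds <- seeds[seq_len(n_subsamples)]
  run_seeds <- seeds[-seq_len(n_subsamples)]

  subsets <- vector("list", n_subsamples)
  for (s in seq_len(n_subsamples)) {
    idx <- with_seed_(draw_seeds[s], {
      sort(unlist(lapply(names(per_class), function(cl) {
        sample(which(dataset$labels == as.integer(cl)), per_class[[cl]])
      }), use.names = FALSE))
    })
    sub <- dataset[idx, ]
    cfg_s <- config
    cfg_s$seed <- run_seeds[s]
    subsets[[s]] <- tryCatch(
      switch(selector,
        ensemble = {
          sel <- ensemble_select(sub, cfg_s)
          stable <- stable_feature_set(sel, min_stability_fraction)
          ranked <- sel$ranking$feature_id[sel$ranking$feature_id %in% stable]
          ranked <- head(ranked, max_backward_size)
          if (backward && length(ranked) > 1) {
            backward_eliminate(sub, ranked, cfg_s)$optimal_subset
          } else {
            ranked
          }
        },
        single = select_single_dataset(sub, cfg_s)
      ),
      error = function(e) {
        abort(sprintf("selector failed on subsample %d: %s", s,
                      conditionMessage(e)))
      }
    )
  }
  rep <- mean_tanimoto(subsets)
  attr(rep, "selector") <- selector
  attr(rep, "subsets") <- subsets
  rep
}

#' Evaluate a feature subset on an independent holdout set
#'
#' Trains a grid-tuned RBF-SVM on the training set restricted to the
#' selected features and reports accuracy, F1, MCC and AUC on the test
#' set. Train and test must not share sample ids; an overlap aborts the
#' evaluation, because any leakage of test samples into selection or
#' training invalidates the estimate.
#'
#' @param train,test [expression_dataset()]s with disjoint sample ids.
#' @param features Character vector of selected features (present in
#'   both).
#' @param config A [run_config()]; supplies the RBF grids, folds, seed.
#' @return A one-row tibble: `accuracy`, `f1`, `mcc`, `auc`,
#'   `mcc_defined`, `best_c`, `best_gamma`.
#' @export
evaluate_on_holdout <- function(train, test, features,
                                config = run_config()) {
  check_dataset(train)
  check_dataset(test, min_per_class = 1L)
  overlap <- intersect(sample_ids(train), sample_ids(test))
  if (length(overlap) > 0) {
    abort(paste0(
      "train and test share sample id(s): ",
      paste(head(overlap, 5), collapse = ", "), " - refusing to evaluate"
    ))
  }
  features <- as.character(features)
  for (nm in list(train = train, test = test)) {
    miss <- setdiff(features, feature_ids(nm))
    if (length(miss) > 0) {
      abort(paste0(
        "feature(s) absent: ", paste(head(miss, 5), collapse = ", ")
      ))
    }
  }
  tr <- train[, features]
  ev <- evaluate_subset(
    tr, c_grid = config$c_grid_rbf, gamma_grid = config$gamma_grid_rbf,
    folds = config$cv_folds, seed = config$seed
  )
  # balanced class weights: AUC-tuned (C, gamma) pairs rank well but can
  # place the decision threshold so an imbalanced cohort is predicted
  # all-majority; weighting restores meaningful class predictions without
  # touching the decision-value ranking used for AUC
  cw <- table(factor(tr$labels, levels = c(-1, 1)))
  cw <- sum(cw) / (2 * cw)
  fit <- e1071::svm(
    x = tr$x, y = factor(tr$labels, levels = c(-1, 1)),
    kernel = "radial", cost = ev$best_c, gamma = ev$best_gamma,
    scale = FALSE, class.weights = cw
  )
  xte <- test$x[, features, drop = FALSE]
  pr <- predict(fit, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos_first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1] == "1"
  dec <- if (pos_first) dv[, 1] else -dv[, 1]
  pred <- as.integer(as.character(pr))
  m <- confusion_metrics(confusion_counts(pred, test$labels))
  m$auc <- auc_score(dec, test$labels)
  m$best_c <- ev$best_c
  m$best_gamma <- ev$best_gamma
  m[, c("accuracy", "f1", "mcc", "auc", "mcc_defined",
        "best_c", "best_gamma")]
}
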