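#' Generate resampled datasets for the ensemble
#'
#' Draws `config$n_bootstraps` subsamples of size
#' `floor(subsample_fraction * n)` from the dataset, class-stratified by
#' default so the minority class is never lost. The default draws without
#' replacement ("80% of the data"); `with_replacement = TRUE` in the
#' config gives classical bagging.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [run_config()].
#' @param seed Seed override; defaults to `config$seed`.
#' @return A list of integer sample-index vectors.
#' @export
generate_bootstraps <- function(dataset, config = run_config(),
                                seed = config$seed) {
  check_dataset(dataset)
  n <- n_samples(dataset)
  size <- floor(config$subsample_fraction * n)
  if (size < config$cv_folds) {
    abort(sprintf(
      "subsample size %d is smaller than cv_folds = %d", size, config$cv_folds
    ))
  }
  labels <- dataset$labels
  counts <- table(labels)
  if (config$stratified) {
    per_class <- allocate_per_class(as.integer(counts), size)
    names(per_class) <- names(counts)
  }
  seeds <- derive_seeds(seed, config$n_bootstraps)
  lapply(seq_len(config$n_bootstraps), function(b) {
    with_seed_(seeds[b], {
      if (config$stratified) {
        idx <- unlist(lapply(names(per_class), function(cl) {
          pool <- which(labels == as.integer(cl))
          sample(pool, per_class[[cl]], replace = config$with_replacement)
        }), use.names = FALSE)
      } else {
        idx <- sample(n, size, replace = config$with_replacement)
        if (length(unique(labels[idx])) < 2) {
          abort("unstratified draw lost a class; use stratified = TRUE")
        }
      }
      sort(idx)
    })
  })
}

#' Run the iterative zero-weight elimination on one dataset view
#'
#' The inner loop of the ensemble: on the given (resampled) dataset,
#' repeatedly (1) tune C by cross-validated AUC on the current feature
#' set, (2) fit the L1-SVM at the tuned C, (3) drop features with zero
#' weight, and (4) record the cross-validated AUC of the reduced set at
#' that C. The loop stops when a fit eliminates nothing further, when all
#' weights vanish (the previous iteration then stands as final), or when a
#' single feature remains. The cross-validation fold partition is fixed
#' once per trace.
#'
#' @param dataset An [expression_dataset()] (typically a bootstrap view).
#' @param config A [run_config()].
#' @param seed Seed override for the fold partition.
#' @return An object of class `elimination_trace`: tibble with columns
#'   `iteration`, `n_features`, `tuned_c`, `cv_auc`, `features`
#'   (list-column), `weights` (list-column), plus attribute
#'   `terminated_reason` in `"no-zeros-remaining"`, `"all-weights-zero"`,
#'   `"single-feature-floor"`.
#' @export
run_elimination_trace <- function(dataset, config = run_config(),
                                  seed = config$seed) {
  check_dataset(dataset)
  fold_ids <- as.integer(stratified_folds(dataset$labels, config$cv_folds, seed))
  yv <- as.numeric(dataset$labels)
  xm <- dataset$x
  # fold fits only feed AUC-based model selection, so a modest sweep cap
  # is enough and keeps tuning cheap
  cv_cap <- min(config$svm_max_iter, 150L)
  current <- feature_ids(dataset)
  rows <- list()
  reason <- NULL
  repeat {
    xv <- xm[, current, drop = FALSE]
    auc_mat <- l1svm_cv_auc_cpp(
      xv, yv, config$c_grid_selection, fold_ids, 1e-2, cv_cap
    )
    mean_auc <- colMeans(auc_mat)
    best <- which.max(mean_auc) # first max = smallest C on ties
    best_c <- config$c_grid_selection[best]
    # light polish profile: exact zeros still emerge, and later iterations
    # clean any residual dust on the much smaller surviving set
    fit <- l1svm_fit_cpp(xv, yv, best_c, config$svm_tol,
                         config$svm_max_iter, NULL, 0, TRUE, 1e7, 2L)
    w <- as.numeric(fit$weights)
    names(w) <- current
    keep <- abs(w) > config$zero_tolerance
    surviving <- current[keep]

    if (length(surviving) == 0 || length(surviving) == length(current)) {
      # nothing survives (all weights zero) or nothing was eliminated:
      # the previous iteration stands; a first iteration is still recorded
      # so the trace is never empty
      if (length(rows) == 0) {
        rows[[1]] <- list(
          features = current, tuned_c = best_c,
          cv_auc = unname(mean_auc[best]), weights = w
        )
      }
      reason <- if (length(surviving) == 0) {
        "all-weights-zero"
      } else {
        "no-zeros-remaining"
      }
      break
    }

    # score the reduced set at the iteration's tuned C
    red_auc <- l1svm_cv_auc_cpp(
      xm[, surviving, drop = FALSE], yv, best_c, fold_ids, 1e-2, cv_cap
    )
    rows[[length(rows) + 1]] <- list(
      features = surviving, tuned_c = best_c,
      cv_auc = mean(red_auc), weights = w[keep]
    )
    current <- surviving
    if (length(current) == 1) {
      reason <- "single-feature-floor"
      break
    }
  }

  out <- tibble::tibble(
    iteration = seq_along(rows),
    n_features = vapply(rows, function(r) length(r$features), integer(1)),
    tuned_c = vapply(rows, function(r) r$tuned_c, numeric(1)),
    cv_auc = vapply(rows, function(r) r$cv_auc, numeric(1)),
    features = lapply(rows, function(r) r$features),
    weights = lapply(rows, function(r) r$weights)
  )
  attr(out, "terminated_reason") <- reason
  class(out) <- c("elimination_trace", class(out))
  out
}

#' Pick the optimal iteration of an elimination trace
#'
#' Returns the surviving feature set of the iteration with the highest
#' cross-validated AUC; ties go to the earliest (largest) set, so excess
#' elimination never wins on a tie.
#'
#' @param trace An [run_elimination_trace()] result.
#' @return Character vector of feature ids.
#' @export
select_optimal_subset <- function(trace) {
  if (nrow(trace) == 0) abort("empty elimination trace")
  best <- which.max(trace$cv_auc) # first max = earliest iteration
  trace$features[[best]]
}

#' Aggregate per-bootstrap feature sets into stability scores
#'
#' The stability score S of a feature is the number of resampled datasets
#' whose optimal surviving set contains it (1 <= S <= n); features never
#' selected are absent.
#'
#' @param subsets List of character vectors (one optimal set per resample).
#' @param n_bootstraps The ensemble size n.
#' @return An object of class `stability_scores`: tibble with columns
#'   `feature_id`, `score`, attribute `n_bootstraps`.
#' @export
aggregate_stability <- function(subsets, n_bootstraps = length(subsets)) {
  if (length(subsets) != n_bootstraps) {
    abort("length(subsets) must equal n_bootstraps")
  }
  counts <- table(unlist(lapply(subsets, unique), use.names = FALSE))
  out <- tibble::tibble(
    feature_id = as.character(names(counts)),
    score = as.integer(counts)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$feature_id)
  attr(out, "n_bootstraps") <- as.integer(n_bootstraps)
  class(out) <- c("stability_scores", class(out))
  out
}

#' Rank features by stability score
#'
#' Descending stability score; ties are broken by descending mean
#' absolute weight (when supplied) and then lexicographically by feature
#' id, so the ranking is fully deterministic.
#'
#' @param scores A [aggregate_stability()] result (or tibble with
#'   `feature_id`, `score`).
#' @param weight_hint Optional named numeric: mean |w| per feature across
#'   the ensemble, used as first tie-break.
#' @return A tibble with columns `rank`, `feature_id`, `stability_score`.
#' @export
rank_by_stability <- function(scores, weight_hint = NULL) {
  if (nrow(scores) == 0) {
    return(tibble::tibble(
      rank = integer(), feature_id = character(), stability_score = integer()
    ))
  }
  hint <- rep(0, nrow(scores))
  if (!is.null(weight_hint)) {
    hint <- unname(weight_hint[scores$feature_id])
    hint[is.na(hint)] <- 0
  }
  ord <- order(-scores$score, -hint, scores$feature_id)
  tibble::tibble(
    rank = seq_len(nrow(scores)),
    feature_id = scores$feature_id[ord],
    stability_score = scores$score[ord]
  )
}

#' Ensemble L1-SVM stable feature selection
#'
#' The full ensemble: draw `n_bootstraps` stratified subsamples, run the
#' iterative zero-weight elimination on each, keep each resample's
#' AUC-maximizing subset, and count for every feature the number of
#' resamples that kept it (its stability score S). Features are returned
#' ranked by S.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [run_config()]; `config$seed` makes the whole run
#'   reproducible.
#' @param keep_traces Keep every per-resample elimination trace (memory
#'   grows with `n_bootstraps`).
#' @return An object of class `ensemble_selection`: list with `scores`
#'   (a [aggregate_stability()] tibble), `ranking` (tibble `rank`,
#'   `feature_id`, `stability_score`), `weight_hint` (named numeric mean
#'   |w|), `subsets` (list of per-resample optimal sets), `config`, and
#'   optionally `traces`.
#' @examples
#' \donttest{
#' sim <- simulate_expression(synthetic_spec(
#'   n_samples = 80, n_features = 100, n_informative = 5, seed = 1
#' ))
#' sel <- ensemble_select(sim$dataset, run_config(
#'   n_bootstraps = 20, cv_folds = 5, c_grid_selection = 10^(-2:1), seed = 1
#' ))
#' head(sel$ranking)
#' }
#' @export
ensemble_select <- function(dataset, config = run_config(),
                            keep_traces = FALSE) {
  check_dataset(dataset)
  master <- derive_seeds(config$seed, config$n_bootstraps + 1L)
  boots <- generate_bootstraps(dataset, config, seed = master[1])
  trace_seeds <- master[-1]

  traces <- vector("list", config$n_bootstraps)
  subsets <- vector("list", config$n_bootstraps)
  w_sum <- numeric(0)
  w_cnt <- numeric(0)
  for (b in seq_len(config$n_bootstraps)) {
    tr <- run_elimination_trace(dataset[boots[[b]], ], config,
                                seed = trace_seeds[b])
    best <- which.max(tr$cv_auc)
    subsets[[b]] <- tr$features[[best]]
    wb <- abs(tr$weights[[best]])
    if (length(wb) > 0) {
      add <- setdiff(names(wb), names(w_sum))
      if (length(add) > 0) {
        w_sum[add] <- 0
        w_cnt[add] <- 0
      }
      w_sum[names(wb)] <- w_sum[names(wb)] + wb
      w_cnt[names(wb)] <- w_cnt[names(wb)] + 1
    }
    if (keep_traces) traces[[b]] <- tr
  }
  scores <- aggregate_stability(subsets, config$n_bootstraps)
  weight_hint <- w_sum / pmax(w_cnt, 1)
  structure(list(
    scores = scores,
    ranking = rank_by_stability(scores, weight_hint),
    weight_hint = weight_hint,
    subsets = subsets,
    config = config,
    traces = if (keep_traces) traces else NULL
  ), class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf(
    "<ensemble_selection> %d resamples, %d features with S >= 1 (top score %d)\n",
    x$config$n_bootstraps, nrow(x$scores),
    if (nrow(x$scores)) max(x$scores$score) else 0L
  ))
  invisible(x)
}

#' Single-dataset L1-SVM selection (no instance perturbation)
#'
#' The non-ensemble baseline: one elimination trace on the full dataset
#' (the identity resample), returning its AUC-maximizing subset. Used to
#' demonstrate how much selection stability the ensemble adds.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [run_config()]; only the grids, folds, seed and solver
#'   settings are used.
#' @return Character vector of selected feature ids.
#' @export
select_single_dataset <- function(dataset, config = run_config()) {
  trace <- run_elimination_trace(dataset, config, seed = config$seed)
  select_optimal_subset(trace)
}

#' Threshold an ensemble selection into one feature set
#'
#' Keeps features whose stability score reaches `min_fraction` of the
#' ensemble size (default 10%, a practical cut for reducing features far
#' below the sample count).
#'
#' @param selection An [ensemble_select()] result.
#' @param min_fraction Minimum S / n_bootstraps to keep a feature.
#' @return Character vector of feature ids.
#' @export
stable_feature_set <- function(selection, min_fraction = 0.1) {
  thr <- max(1L, ceiling(min_fraction * selection$config$n_bootstraps))
  selection$scores$feature_id[selection$scores$score >= thr]
}
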