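# RBF-SVM cross-validation machinery for the refinement phase. The
# classifier here is the standard C-SVM with kernel exp(-gamma |x - y|^2)
# (libsvm via e1071); scores are out-of-fold decision values, summarized
# as mean AUC across folds.

# Mean out-of-fold AUC for one (cost, gamma) pair under a fixed fold
# partition. Decision-value orientation is resolved from libsvm's column
# label so the positive class always scores high.
rbf_cv_auc <- function(x, y, fold_ids, cost, gamma) {
  k <- max(fold_ids)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold_ids != f
    fit <- e1071::svm(
      x = x[tr, , drop = FALSE], y = factor(y[tr], levels = c(-1, 1)),
      kernel = "radial", cost = cost, gamma = gamma, scale = FALSE
    )
    pr <- predict(fit, x[!tr, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    pos_first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1] == "1"
    dec <- if (pos_first) dv[, 1] else -dv[, 1]
    aucs[f] <- auc_score(dec, y[!tr])
  }
  mean(aucs)
}

#' Grid-tuned RBF-SVM cross-validation score of a feature subset
#'
#' Evaluates the dataset view under every (C, gamma) pair of the grids by
#' mean stratified-CV AUC of the RBF-kernel SVM and returns the maximum
#' with its arg-max pair. Ties resolve toward smaller C, then smaller
#' gamma.
#'
#' @param data An [expression_dataset()] already restricted to the subset
#'   of interest.
#' @param c_grid,gamma_grid Strictly increasing positive grids.
#' @param folds Number of stratified folds.
#' @param fold_ids Optional fixed fold assignment (overrides
#'   `folds`/`seed`).
#' @param seed Seed for the fold assignment.
#' @return List with `mean_cv_auc`, `best_c`, `best_gamma`, and `grid`
#'   (tibble of `cost`, `gamma`, `mean_auc`).
#' @export
evaluate_subset <- function(data, c_grid = 10^(-5:10),
                            gamma_grid = 10^(-9:3), folds = 10L,
                            fold_ids = NULL, seed = NULL) {
  check_dataset(data)
  fold_ids <- fold_ids %||% stratified_folds(data$labels, folds, seed)
  grid <- expand.grid(gamma = gamma_grid, cost = c_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # order rows by (cost, gamma) so the first maximum realizes the tie-break
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  mean_auc <- vapply(seq_len(nrow(grid)), function(i) {
    rbf_cv_auc(data$x, data$labels, fold_ids, grid$cost[i], grid$gamma[i])
  }, numeric(1))
  best <- which.max(mean_auc)
  list(
    mean_cv_auc = mean_auc[best],
    best_c = grid$cost[best],
    best_gamma = grid$gamma[best],
    grid = tibble::tibble(
      cost = grid$cost, gamma = grid$gamma, mean_auc = mean_auc
    )
  )
}

#' Stability-ranked backward feature elimination
#'
#' Starting from the full ranked list (size k), repeatedly removes the
#' lowest-stability feature and scores every prefix of size k, k-1, ..., 1
#' by grid-tuned RBF-SVM cross-validated AUC. The fold partition is drawn
#' once and shared across all sizes so curve points are comparable. The
#' optimal subset is the prefix maximizing the mean CV AUC; ties across
#' sizes resolve to the smallest (most parsimonious) subset.
#'
#' @param dataset An [expression_dataset()] containing every ranked
#'   feature.
#' @param ranked Character vector of features in descending stability
#'   order, or a ranking tibble from [rank_by_stability()].
#' @param config A [run_config()]; supplies the RBF grids, fold count and
#'   seed.
#' @param fold_ids Optional fixed fold assignment.
#' @return An object of class `backward_elimination`: list with
#'   `auc_curve` (tibble `subset_size`, `mean_cv_auc`, `best_c`,
#'   `best_gamma`), `optimal_size`, `optimal_subset`, `optimal_auc`,
#'   `ranked`.
#' @examples
#' \donttest{
#' sim <- simulate_expression(synthetic_spec(
#'   n_samples = 60, n_features = 20, n_informative = 3, seed = 2
#' ))
#' cfg <- run_config(cv_folds = 5, c_grid_rbf = 10^(0:2),
#'                   gamma_grid_rbf = 10^(-3:-1), seed = 2)
#' be <- backward_eliminate(sim$dataset, c(sim$truth, "f1"), cfg)
#' be$optimal_subset
#' }
#' @export
backward_eliminate <- function(dataset, ranked, config = run_config(),
                               fold_ids = NULL) {
  check_dataset(dataset)
  if (is.data.frame(ranked)) ranked <- ranked$feature_id
  ranked <- as.character(ranked)
  if (length(ranked) == 0) abort("`ranked` must name at least one feature")
  missing_f <- setdiff(ranked, feature_ids(dataset))
  if (length(missing_f) > 0) {
    abort(paste0(
      "ranked feature(s) absent from dataset: ",
      paste(head(missing_f, 5), collapse = ", ")
    ))
  }
  fold_ids <- fold_ids %||%
    stratified_folds(dataset$labels, config$cv_folds, config$seed)

  k <- length(ranked)
  sizes <- seq(k, 1)
  rows <- vector("list", k)
  best_auc <- -Inf
  best_size <- k
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    ev <- evaluate_subset(
      dataset[, ranked[seq_len(s)]],
      c_grid = config$c_grid_rbf, gamma_grid = config$gamma_grid_rbf,
      fold_ids = fold_ids
    )
    rows[[i]] <- tibble::tibble(
      subset_size = s, mean_cv_auc = ev$mean_cv_auc,
      best_c = ev$best_c, best_gamma = ev$best_gamma
    )
    # sizes descend, so >= hands ties to the smaller subset
    if (ev$mean_cv_auc >= best_auc) {
      best_auc <- ev$mean_cv_auc
      best_size <- s
    }
  }
  curve <- dplyr::bind_rows(rows)
  structure(list(
    auc_curve = curve,
    optimal_size = best_size,
    optimal_subset = ranked[seq_len(best_size)],
    optimal_auc = best_auc,
    ranked = ranked
  ), class = "backward_elimination")
}

#' @export
print.backward_elimination <- function(x, ...) {
  cat(sprintf(
    "<backward_elimination> %d sizes scored; optimum: %d features, CV AUC %.3f\n",
    nrow(x$auc_curve), x$optimal_size, x$optimal_auc
  ))
  invisible(x)
}
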