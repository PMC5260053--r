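#' Fit an L1-regularized squared-hinge SVM
#'
#' Solves
#' \deqn{\min_{w,b} \|w\|_1 + C \sum_i \max(0,\, 1 - y_i(w^\top x_i + b))^2}
#' by cyclic coordinate descent with Newton steps, pathwise continuation
#' for large `cost`, and an active-set polish that collapses coefficient
#' dust to exact zeros. The L1 penalty drives most coefficients to zero,
#' so the fit doubles as an embedded feature selector; for data in general
#' position the support size is bounded by the number of samples.
#'
#' @param data An [expression_dataset()].
#' @param cost Positive regularization weight C on the squared-hinge loss
#'   (larger C = less regularization).
#' @param tol Stopping tolerance on the summed violation of the optimality
#'   conditions, relative to its natural per-coordinate scale.
#' @param max_iter Maximum coordinate-descent sweeps for the main phase.
#' @param polish Run the active-set polish phase (recommended; disable
#'   only for throwaway fits inside custom loops).
#'
#' @return An object of class `l1svm`: list with `weights` (named numeric,
#'   one per feature), `intercept`, `cost`, `iterations`, `converged`.
#' @examples
#' ds <- simulate_expression(synthetic_spec(
#'   n_samples = 60, n_features = 40, n_informative = 5, seed = 1
#' ))$dataset
#' fit <- fit_l1_svm(ds, cost = 0.5)
#' sum(fit$weights != 0)
#' @export
fit_l1_svm <- function(data, cost, tol = 1e-3, max_iter = 1000L,
                       polish = TRUE) {
  check_dataset(data)
  if (!is.numeric(cost) || length(cost) != 1 || cost <= 0) {
    abort("`cost` must be a single positive number")
  }
  res <- l1svm_fit_cpp(data$x, as.numeric(data$labels), cost, tol,
                       as.integer(max_iter), NULL, 0, polish)
  if (!res$converged) {
    warn(sprintf(
      "L1-SVM solver not fully converged after %d sweeps (cost = %g)",
      res$iterations, cost
    ))
  }
  w <- as.numeric(res$weights)
  names(w) <- feature_ids(data)
  structure(list(
    weights = w,
    intercept = as.numeric(res$intercept),
    cost = cost,
    iterations = res$iterations,
    converged = res$converged
  ), class = "l1svm")
}

#' @export
print.l1svm <- function(x, ...) {
  cat(sprintf(
    "<l1svm> C = %g, %d/%d nonzero weights, intercept %.4g%s\n",
    x$cost, sum(x$weights != 0), length(x$weights), x$intercept,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Predict decision values from an L1-SVM fit
#'
#' @param object An `l1svm` fit.
#' @param newdata An [expression_dataset()] or numeric matrix containing
#'   at least the fitted features.
#' @param type `"decision"` for the raw margin \eqn{w^\top x + b},
#'   `"class"` for sign labels.
#' @param ... Ignored.
#' @return Numeric decision values or +1/-1 class predictions.
#' @export
predict.l1svm <- function(object, newdata, type = c("decision", "class"),
                          ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "expression_dataset")) newdata$x else newdata
  missing_f <- setdiff(names(object$weights), colnames(x))
  if (length(missing_f) > 0) {
    abort(paste0(
      "newdata lacks fitted feature(s): ",
      paste(head(missing_f, 5), collapse = ", ")
    ))
  }
  dec <- drop(x[, names(object$weights), drop = FALSE] %*% object$weights) +
    object$intercept
  if (type == "class") ifelse(dec >= 0, 1L, -1L) else dec
}

#' Tune the L1-SVM regularization parameter by cross-validated AUC
#'
#' Evaluates every value of `c_grid` by mean out-of-fold AUC under
#' class-stratified k-fold cross-validation and returns the maximizer.
#' Ties are broken toward the smaller (more regularized) C.
#'
#' @param data An [expression_dataset()].
#' @param c_grid Strictly increasing positive grid of C values.
#' @param folds Number of folds (default 10).
#' @param fold_ids Optional externally supplied fold assignment (integers
#'   1..k); overrides `folds`/`seed`.
#' @param seed Seed for the fold assignment.
#' @param tol,max_iter Solver settings for the fold fits; tuning tolerates
#'   looser solves than a final fit.
#'
#' @return A list with `best_c`, `best_auc`, and `grid`, a tibble of
#'   `cost` and `mean_auc`.
#' @export
tune_regularization <- function(data, c_grid = 10^(-5:4), folds = 10L,
                                fold_ids = NULL, seed = NULL, tol = 1e-2,
                                max_iter = 1000L) {
  check_dataset(data)
  if (is.unsorted(c_grid, strictly = TRUE) || any(c_grid <= 0)) {
    abort("c_grid must be positive and strictly increasing")
  }
  fold_ids <- fold_ids %||% stratified_folds(data$labels, folds, seed)
  auc_mat <- l1svm_cv_auc_cpp(
    data$x, as.numeric(data$labels), as.numeric(c_grid),
    as.integer(fold_ids), tol, as.integer(max_iter)
  )
  mean_auc <- colMeans(auc_mat)
  best <- which.max(mean_auc) # which.max takes the first (smallest C) on ties
  list(
    best_c = c_grid[best],
    best_auc = unname(mean_auc[best]),
    grid = tibble::tibble(cost = as.numeric(c_grid), mean_auc = unname(mean_auc))
  )
}

#' Drop features whose fitted weight is (numerically) zero
#'
#' @param model An `l1svm` fit.
#' @param features Character vector of candidate features, aligned with
#'   the model (defaults to all fitted features).
#' @param tol Magnitude at or below which a weight counts as zero.
#' @return The surviving features, in their original order.
#' @examples
#' m <- structure(
#'   list(weights = c(a = 0.5, b = 0, c = -0.2)),
#'   class = "l1svm"
#' )
#' eliminate_zero_features(m)
#' @export
eliminate_zero_features <- function(model, features = names(model$weights),
                                    tol = 1e-10) {
  w <- model$weights[features]
  if (anyNA(w)) abort("model is not aligned to `features`")
  features[abs(w) > tol]
}

#' @rdname tidy.stabsvm
#' @export
tidy.l1svm <- function(x, ...) {
  tibble::tibble(
    term = names(x$weights),
    estimate = unname(x$weights)
  )
}

#' @rdname glance.stabsvm
#' @export
glance.l1svm <- function(x, ...) {
  tibble::tibble(
    cost = x$cost,
    n_features = length(x$weights),
    n_nonzero = sum(x$weights != 0),
    iterations = x$iterations,
    converged = x$converged
  )
}
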