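#' Construct a labeled expression dataset
#'
#' Bundles a samples-by-features numeric matrix with binary class labels.
#' This is the container every selection and evaluation function operates
#' on. Labels are stored internally as +1 / -1; the positive class is the
#' biologically "interesting" one (e.g. advanced tumour stage) and is the
#' reference class for F1, MCC and AUC.
#'
#' @param x Numeric matrix, rows = samples, columns = features. Must be
#'   finite throughout.
#' @param labels Per-sample class labels. Either already coded +1 / -1, or
#'   any two-level vector (character, factor, numeric), in which case
#'   `positive_class` decides the coding.
#' @param sample_ids,feature_ids Unique identifiers; default to the
#'   dimnames of `x` and are generated (`s1...`, `f1...`) when absent.
#' @param positive_class For two-level non-numeric labels, the level mapped
#'   to +1. Defaults to the minority class, the usual situation in staged
#'   tumour cohorts where the advanced stage is rare.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `x` (matrix with dimnames) and `labels` (named integer vector of
#'   +1/-1, aligned to rows of `x`).
#' @examples
#' x <- matrix(rnorm(20), 4, 5)
#' ds <- expression_dataset(x, labels = c("t", "n", "n", "n"))
#' ds$labels
#' @export
expression_dataset <- function(x, labels, sample_ids = rownames(x),
                               feature_ids = colnames(x),
                               positive_class = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix (samples x features)")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(x)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(x)) {
    abort("length(sample_ids) must equal nrow(x)")
  }
  if (length(feature_ids) != ncol(x)) {
    abort("length(feature_ids) must equal ncol(x)")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0(
      "duplicate sample ids: ",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(feature_ids)) {
    abort(paste0(
      "duplicate feature ids: ",
      paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")
    ))
  }
  if (length(labels) != nrow(x)) {
    abort("length(labels) must equal nrow(x)")
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-finite value in matrix at sample '%s', feature '%s'",
      sample_ids[bad[1]], feature_ids[bad[2]]
    ))
  }
  labels <- encode_labels(labels, positive_class)
  dimnames(x) <- list(sample_ids, feature_ids)
  names(labels) <- sample_ids
  structure(list(x = x, labels = labels), class = "expression_dataset")
}

# Map a two-level label vector onto {+1, -1}.
encode_labels <- function(labels, positive_class = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels) && all(labels %in% c(-1, 1))) {
    lab <- as.integer(labels)
  } else {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2) {
      abort(sprintf(
        "labels must take exactly 2 values, got %d (%s)",
        length(lev), paste(head(lev, 5), collapse = ", ")
      ))
    }
    if (is.null(positive_class)) {
      counts <- table(as.character(labels))
      positive_class <- names(counts)[which.min(counts)]
    }
    positive_class <- as.character(positive_class)
    if (!positive_class %in% lev) {
      abort(sprintf("positive_class '%s' not found in labels", positive_class))
    }
    lab <- ifelse(as.character(labels) == positive_class, 1L, -1L)
  }
  if (length(unique(lab)) < 2) {
    abort("both classes must be present")
  }
  lab
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<expression_dataset> %d samples x %d features (+1: %d, -1: %d)\n",
    nrow(x$x), ncol(x$x), tab[["1"]], tab[["-1"]]
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$x)

#' Subset an expression dataset
#'
#' Standard `[samples, features]` subsetting by index or id. Dropping one
#' class entirely is an error, because every downstream fit needs both.
#'
#' @param x An [expression_dataset()].
#' @param i,j Sample / feature indices or ids.
#' @param ... Ignored.
#' @return An `expression_dataset` restricted to the requested rows/columns.
#' @export
`[.expression_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  xm <- x$x[i, j, drop = FALSE]
  lab <- x$labels[i]
  if (length(unique(lab)) < 2) {
    abort("subset drops one class entirely")
  }
  structure(list(x = xm, labels = lab), class = "expression_dataset")
}

n_samples <- function(ds) nrow(ds$x)
n_features <- function(ds) ncol(ds$x)
feature_ids <- function(ds) colnames(ds$x)
sample_ids <- function(ds) rownames(ds$x)

check_dataset <- function(ds, min_per_class = 2L) {
  if (!inherits(ds, "expression_dataset")) {
    abort("expected an `expression_dataset`; see ?expression_dataset")
  }
  tab <- table(ds$labels)
  if (length(tab) < 2 || any(tab < min_per_class)) {
    abort(sprintf("need at least %d samples in each class", min_per_class))
  }
  invisible(ds)
}

#' Run configuration for ensemble selection
#'
#' Collects every tunable of the selection pipeline in one place. The
#' defaults mirror the reference protocol for staged-tumour expression
#' cohorts: 1000 subsamples of 80% of the data, 10-fold cross-validation,
#' a decade grid C in 1e-5..1e4 for the sparse linear phase, and decade
#' grids C in 1e-5..1e10, gamma in 1e-9..1e3 for the RBF refinement phase.
#'
#' @param n_bootstraps Number of resampled datasets for the ensemble.
#' @param subsample_fraction Fraction of samples drawn into each resample.
#' @param cv_folds Folds for every internal cross-validation.
#' @param c_grid_selection Regularization grid for the L1-SVM.
#' @param c_grid_rbf,gamma_grid_rbf Grids for the RBF-SVM refinement.
#' @param zero_tolerance Coefficients with absolute value at or below this
#'   are treated as zero when eliminating features.
#' @param seed Integer seed; all randomness in a run flows from it.
#' @param stratified Stratify resamples and folds by class (recommended for
#'   imbalanced cohorts).
#' @param with_replacement Draw resamples with replacement (classical
#'   bagging) instead of the default 80% subsampling without replacement.
#' @param svm_tol,svm_max_iter Stopping tolerance (on the optimality
#'   violation sum) and sweep cap for the coordinate-descent L1-SVM solver.
#'
#' @return A list of class `stabsvm_config`.
#' @examples
#' cfg <- run_config(n_bootstraps = 50, seed = 1)
#' cfg$c_grid_selection
#' @export
run_config <- function(n_bootstraps = 1000L,
                       subsample_fraction = 0.8,
                       cv_folds = 10L,
                       c_grid_selection = 10^(-5:4),
                       c_grid_rbf = 10^(-5:10),
                       gamma_grid_rbf = 10^(-9:3),
                       zero_tolerance = 1e-10,
                       seed = 1L,
                       stratified = TRUE,
                       with_replacement = FALSE,
                       svm_tol = 1e-3,
                       svm_max_iter = 1000L) {
  check_grid <- function(g, nm) {
    if (length(g) == 0 || any(!is.finite(g)) || any(g <= 0) ||
        is.unsorted(g, strictly = TRUE)) {
      abort(sprintf("%s must be non-empty, positive and strictly increasing", nm))
    }
  }
  if (n_bootstraps < 1) abort("n_bootstraps must be a positive integer")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("subsample_fraction must lie in (0, 1]")
  }
  if (cv_folds < 2) abort("cv_folds must be at least 2")
  check_grid(c_grid_selection, "c_grid_selection")
  check_grid(c_grid_rbf, "c_grid_rbf")
  check_grid(gamma_grid_rbf, "gamma_grid_rbf")
  if (zero_tolerance < 0) abort("zero_tolerance must be non-negative")
  structure(list(
    n_bootstraps = as.integer(n_bootstraps),
    subsample_fraction = subsample_fraction,
    cv_folds = as.integer(cv_folds),
    c_grid_selection = as.numeric(c_grid_selection),
    c_grid_rbf = as.numeric(c_grid_rbf),
    gamma_grid_rbf = as.numeric(gamma_grid_rbf),
    zero_tolerance = zero_tolerance,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    stratified = isTRUE(stratified),
    with_replacement = isTRUE(with_replacement),
    svm_tol = svm_tol,
    svm_max_iter = as.integer(svm_max_iter)
  ), class = "stabsvm_config")
}

#' @export
print.stabsvm_config <- function(x, ...) {
  cat("<stabsvm_config>\n")
  cat(sprintf(
    "  %d resamples at fraction %.2f (%s replacement, %s)\n",
    x$n_bootstraps, x$subsample_fraction,
    if (x$with_replacement) "with" else "without",
    if (x$stratified) "stratified" else "unstratified"
  ))
  cat(sprintf("  %d-fold CV, seed %s\n", x$cv_folds,
              x$seed %||% "<none>"))
  cat(sprintf(
    "  C grid (L1): %g .. %g (%d); C grid (RBF): %g .. %g (%d); gamma: %g .. %g (%d)\n",
    min(x$c_grid_selection), max(x$c_grid_selection), length(x$c_grid_selection),
    min(x$c_grid_rbf), max(x$c_grid_rbf), length(x$c_grid_rbf),
    min(x$gamma_grid_rbf), max(x$gamma_grid_rbf), length(x$gamma_grid_rbf)
  ))
  invisible(x)
}
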