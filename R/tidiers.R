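#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy stabsvm result objects
#'
#' broom-style one-row-per-term/observation summaries: `tidy()` on an
#' `l1svm` fit returns its coefficients, on an `ensemble_selection` the
#' stability ranking, on a `backward_elimination` the AUC-vs-size curve,
#' and on a `stability_report` the pairwise Tanimoto values.
#'
#' @param x A stabsvm result object.
#' @param ... Ignored.
#' @return A tibble.
#' @name tidy.stabsvm
NULL

#' Glance at stabsvm result objects
#'
#' One-row summaries of fitted objects, broom-style.
#'
#' @param x A stabsvm result object.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @name glance.stabsvm
NULL

#' @rdname tidy.stabsvm
#' @method tidy ensemble_selection
#' @export
tidy.ensemble_selection <- function(x, ...) {
  x$ranking
}

#' @rdname glance.stabsvm
#' @method glance ensemble_selection
#' @export
glance.ensemble_selection <- function(x, ...) {
  tibble::tibble(
    n_bootstraps = x$config$n_bootstraps,
    n_selected = nrow(x$scores),
    max_score = if (nrow(x$scores)) max(x$scores$score) else 0L,
    median_subset_size = stats::median(lengths(x$subsets))
  )
}

#' @rdname tidy.stabsvm
#' @method tidy backward_elimination
#' @export
tidy.backward_elimination <- function(x, ...) {
  x$auc_curve
}

#' @rdname glance.stabsvm
#' @method glance backward_elimination
#' @export
glance.backward_elimination <- function(x, ...) {
  tibble::tibble(
    n_sizes = nrow(x$auc_curve),
    optimal_size = x$optimal_size,
    optimal_auc = x$optimal_auc
  )
}

#' @rdname tidy.stabsvm
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  x$per_pair
}

#' @rdname glance.stabsvm
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    mean_tanimoto = x$mean_tanimoto,
    sd_tanimoto = x$sd_tanimoto,
    n_subsamples = x$n_subsamples
  )
}

#' Plot the AUC-versus-subset-size curve
#'
#' The backward-elimination trace: mean cross-validated AUC of each
#' ranked-prefix subset, with the optimum highlighted.
#'
#' @param object A [backward_eliminate()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot backward_elimination
#' @export
autoplot.backward_elimination <- function(object, ...) {
  curve <- object$auc_curve
  opt <- curve[curve$subset_size == object$optimal_size, ]
  ggplot2::ggplot(curve, ggplot2::aes(.data$subset_size, .data$mean_cv_auc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = opt, colour = "red", size = 2.5) +
    ggplot2::labs(
      x = "Feature subset size",
      y = "Mean cross-validated AUC",
      title = sprintf(
        "Backward elimination: optimum at %d features (AUC %.3f)",
        object$optimal_size, object$optimal_auc
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot stability scores of an ensemble selection
#'
#' Bar chart of the top-ranked features' stability scores (the number of
#' resamples whose optimal subset retained each feature).
#'
#' @param object An [ensemble_select()] result.
#' @param top_n How many features to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ensemble_selection
#' @export
autoplot.ensemble_selection <- function(object, top_n = 30, ...) {
  d <- head(object$ranking, top_n)
  d$feature_id <- factor(d$feature_id, levels = rev(d$feature_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$stability_score, .data$feature_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = sprintf("Stability score (of %d resamples)",
                  object$config$n_bootstraps),
      y = NULL,
      title = sprintf("Top %d features by selection stability", nrow(d))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the pairwise Tanimoto distribution of a stability report
#'
#' @param object A [run_stability_experiment()] / [mean_tanimoto()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(object$per_pair, ggplot2::aes(.data$tanimoto)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_tanimoto,
                        colour = "red", linetype = 2) +
    ggplot2::labs(
      x = "Pairwise Tanimoto similarity",
      y = "Pairs",
      title = sprintf("Selection stability: mean T = %.3f (sd %.3f)",
                      object$mean_tanimoto, object$sd_tanimoto)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
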