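#' Write a selection run report as JSON
#'
#' Serializes a full selection run - resolved configuration, stability
#' scores, optional backward-elimination curve and optimal subset, and
#' optional holdout metrics - into one JSON document with a stable
#' schema (keys: `config`, `stability_scores`, `auc_curve`,
#' `optimal_subset`, `metrics`, `tool_version`).
#'
#' @param selection An [ensemble_select()] result.
#' @param path Output path.
#' @param backward Optional [backward_eliminate()] result.
#' @param metrics Optional one-row metrics tibble from
#'   [evaluate_on_holdout()].
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path, backward = NULL,
                                   metrics = NULL) {
  cfg <- selection$config
  report <- list(
    tool_version = as.character(utils::packageVersion("stabsvm")),
    config = unclass(cfg),
    stability_scores = selection$ranking,
    auc_curve = if (!is.null(backward)) backward$auc_curve else NULL,
    optimal_subset = if (!is.null(backward)) backward$optimal_subset else NULL,
    optimal_auc = if (!is.null(backward)) backward$optimal_auc else NULL,
    metrics = metrics
  )
  jsonlite::write_json(
    report[!vapply(report, is.null, logical(1))],
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a selection report written by [write_selection_report()]
#'
#' @param path JSON path.
#' @return A list mirroring the report schema.
#' @export
read_selection_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
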