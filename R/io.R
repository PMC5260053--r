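#' Read an expression dataset from delimited text
#'
#' Reads a samples-by-features matrix (TSV or CSV, auto-detected from the
#' file extension) whose header row holds feature ids and whose first
#' column holds sample ids. Labels come either from a separate two-column
#' file (`sample_id`, `label`) or from a named column of the matrix file.
#' Labels are aligned to the matrix by sample-id join, so row order in the
#' label file is irrelevant.
#'
#' @param matrix_path Path to the matrix file.
#' @param labels Path to a two-column label file; ignored when
#'   `label_column` is given.
#' @param label_column Name of a column of the matrix file holding labels.
#' @param positive_class Label value mapped to +1 (default: minority class).
#' @param transpose Set `TRUE` for genes-as-rows files (header = sample
#'   ids, first column = feature ids).
#' @param delim Field delimiter; default `","` for `.csv`, tab otherwise.
#'
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(matrix_path, labels = NULL,
                                    label_column = NULL,
                                    positive_class = NULL,
                                    transpose = FALSE, delim = NULL) {
  tab <- read_delim_auto(matrix_path, delim)
  if (ncol(tab) < 2) abort("matrix file needs an id column plus data columns")

  lab_tab <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(tab)) {
      abort(sprintf("label column '%s' not found in %s", label_column, matrix_path))
    }
    lab_tab <- tibble::tibble(
      sample_id = as.character(tab[[1]]),
      label = tab[[label_column]]
    )
    tab <- tab[setdiff(names(tab), label_column)]
  } else if (!is.null(labels)) {
    lt <- read_delim_auto(labels, delim)
    if (ncol(lt) < 2) abort("label file needs columns: sample id, label")
    lab_tab <- tibble::tibble(
      sample_id = as.character(lt[[1]]),
      label = lt[[2]]
    )
  } else {
    abort("supply `labels` (a file) or `label_column`")
  }

  ids <- as.character(tab[[1]])
  vals <- tab[-1]
  not_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0(
      "non-numeric cells in column(s): ",
      paste(head(not_num, 5), collapse = ", ")
    ))
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (transpose) x <- t(x)

  if (anyDuplicated(lab_tab$sample_id)) {
    abort("duplicate sample ids in label source")
  }
  missing_ids <- setdiff(rownames(x), lab_tab$sample_id)
  if (length(missing_ids) > 0) {
    abort(paste0(
      "no label for sample(s): ", paste(head(missing_ids, 5), collapse = ", ")
    ))
  }
  lab <- lab_tab$label[match(rownames(x), lab_tab$sample_id)]

  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "missing value at sample '%s', feature '%s'; filter upstream",
      rownames(x)[bad[1]], colnames(x)[bad[2]]
    ))
  }
  ds <- expression_dataset(x, lab, positive_class = positive_class)
  check_dataset(ds)
  ds
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression_dataset()]: the matrix goes to
#' `matrix_path` (first column `sample_id`, one column per feature) and
#' the +1/-1 labels to `labels_path` (`sample_id`, `label`).
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,labels_path Output paths; delimiter follows the
#'   matrix file extension.
#' @return `dataset`, invisibly.
#' @export
write_expression_dataset <- function(dataset, matrix_path, labels_path) {
  check_dataset(dataset, min_per_class = 1L)
  out <- tibble::as_tibble(dataset$x)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(dataset$x)), out
  )
  write_delim_auto(out, matrix_path)
  write_delim_auto(
    tibble::tibble(
      sample_id = names(dataset$labels),
      label = unname(dataset$labels)
    ),
    labels_path
  )
  invisible(dataset)
}

#' Write a stability-ranked feature list
#'
#' @param ranking A tibble with columns `rank`, `feature_id`,
#'   `stability_score`, as produced by [rank_by_stability()].
#' @param path Output TSV path.
#' @return `ranking`, invisibly.
#' @export
write_ranked_features <- function(ranking, path) {
  cols <- c("rank", "feature_id", "stability_score")
  if (!all(cols %in% names(ranking))) {
    abort("ranking needs columns rank, feature_id, stability_score")
  }
  readr::write_tsv(ranking[cols], path)
  invisible(ranking)
}

#' Read a ranked feature list written by [write_ranked_features()]
#'
#' @param path TSV path.
#' @return A tibble with columns `rank`, `feature_id`, `stability_score`.
#' @export
read_ranked_features <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      rank = readr::col_integer(),
      feature_id = readr::col_character(),
      stability_score = readr::col_double()
    )
  )
}

read_delim_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    name_repair = "minimal"
  )
}

write_delim_auto <- function(tab, path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tab, path, delim = delim)
}
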