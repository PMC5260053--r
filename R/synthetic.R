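#' Specification for a synthetic expression dataset
#'
#' Describes an expression-like dataset with known ground truth for
#' benchmarking selection methods in the p >> n regime: a small set of
#' informative features carrying a standardized mean shift between
#' classes, optional equicorrelated feature blocks (redundant-signal
#' groups when tied to the class), and independent Gaussian noise for the
#' rest. Defaults give a 200 x 1000 matrix with 3:1 class imbalance and
#' 10 informative features at shift 1.5 - a desk-scale rendition of a
#' staged tumour RNA-seq cohort (hundreds of samples, tens of thousands
#' of genes, rare advanced stage).
#'
#' @param n_samples,n_features Matrix shape.
#' @param n_informative Number of planted class-informative features.
#' @param effect_size Standardized mean shift between classes on
#'   informative features (before column standardization).
#' @param n_corr_blocks,block_size Number and size of equicorrelated
#'   feature blocks.
#' @param block_rho Within-block correlation in \[0, 1).
#' @param class_ratio Positive-class fraction in (0, 1).
#' @param noise_sd Within-class standard deviation of every feature.
#' @param class_linked_blocks Give the correlated blocks a shared
#'   class-dependent shift (redundant signal groups).
#' @param seed Integer seed; the generator is fully deterministic.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200L, n_features = 1000L,
                           n_informative = 10L, effect_size = 1.5,
                           n_corr_blocks = 3L, block_size = 5L,
                           block_rho = 0.7, class_ratio = 0.25,
                           noise_sd = 1, class_linked_blocks = FALSE,
                           seed = 1L) {
  if (n_informative + n_corr_blocks * block_size > n_features) {
    abort("informative + block features exceed n_features")
  }
  if (block_rho < 0 || block_rho >= 1) abort("block_rho must lie in [0, 1)")
  if (class_ratio <= 0 || class_ratio >= 1) {
    abort("class_ratio must lie in (0, 1)")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  n_pos <- round(class_ratio * n_samples)
  if (n_pos < 2 || n_samples - n_pos < 2) {
    abort("each class needs at least 2 samples; adjust class_ratio")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    effect_size = effect_size,
    n_corr_blocks = as.integer(n_corr_blocks),
    block_size = as.integer(block_size),
    block_rho = block_rho,
    class_ratio = class_ratio,
    noise_sd = noise_sd,
    class_linked_blocks = isTRUE(class_linked_blocks),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with planted truth
#'
#' Draws the dataset described by a [synthetic_spec()]: class labels with
#' exact (rounded) class counts, informative columns shifted by
#' +/- effect_size/2 per class, equicorrelated Gaussian blocks
#' (correlation `block_rho`), independent Gaussian noise elsewhere, and
#' finally per-column standardization to mean 0, sd 1 (mirroring z-scored
#' expression input). Feature positions are shuffled so informative
#' columns are not clustered at one end.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `dataset` (an [expression_dataset()]), `truth`
#'   (character vector of informative feature ids; when
#'   `class_linked_blocks` is set, block members are included), and
#'   `blocks` (list of block feature ids).
#' @examples
#' sim <- simulate_expression(synthetic_spec(
#'   n_samples = 50, n_features = 100, n_informative = 5, seed = 7
#' ))
#' dim(sim$dataset)
#' sim$truth
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must come from synthetic_spec()")
  }
  n <- spec$n_samples
  p <- spec$n_features
  n_pos <- round(spec$class_ratio * n)
  feat_ids <- sprintf("g%0*d", nchar(p), seq_len(p))

  with_seed_(spec$seed, {
    y <- sample(c(rep(1L, n_pos), rep(-1L, n - n_pos)))
    shift <- ifelse(y == 1L, spec$effect_size / 2, -spec$effect_size / 2)

    x <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p)

    pos <- sample(p, spec$n_informative + spec$n_corr_blocks * spec$block_size)
    inf_idx <- pos[seq_len(spec$n_informative)]
    block_idx <- if (spec$n_corr_blocks > 0) {
      split(
        pos[-seq_len(spec$n_informative)],
        rep(seq_len(spec$n_corr_blocks), each = spec$block_size)
      )
    } else {
      list()
    }

    x[, inf_idx] <- x[, inf_idx] + shift

    # equicorrelated block: sqrt(rho) * shared + sqrt(1-rho) * own noise
    for (blk in block_idx) {
      shared <- rnorm(n, sd = spec$noise_sd)
      own <- matrix(rnorm(n * length(blk), sd = spec$noise_sd), n)
      xb <- sqrt(spec$block_rho) * shared + sqrt(1 - spec$block_rho) * own
      if (spec$class_linked_blocks) xb <- xb + shift
      x[, blk] <- xb
    }

    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  })

  colnames(x) <- feat_ids
  rownames(x) <- sprintf("s%0*d", nchar(n), seq_len(n))
  truth_idx <- inf_idx
  if (spec$class_linked_blocks) {
    truth_idx <- c(inf_idx, unlist(block_idx, use.names = FALSE))
  }
  list(
    dataset = expression_dataset(x, y),
    truth = sort(feat_ids[truth_idx]),
    blocks = lapply(block_idx, function(i) sort(feat_ids[i]))
  )
}

#' Stratified train/test split
#'
#' Partitions the samples into disjoint training and test sets. With
#' stratification the test set receives `round(test_fraction * n_c)`
#' samples of each class c (clamped so both sides keep every class).
#'
#' @param dataset An [expression_dataset()].
#' @param test_fraction Fraction of samples for the test set.
#' @param stratified Stratify by class (default TRUE).
#' @param seed Seed for the draw.
#' @return A list of two [expression_dataset()]s, `train` and `test`.
#' @examples
#' sim <- simulate_expression(synthetic_spec(
#'   n_samples = 50, n_features = 20, seed = 3
#' ))
#' sp <- train_test_split(sim$dataset, 0.2, seed = 3)
#' dim(sp$train)
#' @export
train_test_split <- function(dataset, test_fraction = 0.2,
                             stratified = TRUE, seed = NULL) {
  check_dataset(dataset)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must lie in (0, 1)")
  }
  n <- n_samples(dataset)
  test_idx <- with_seed_(seed, {
    if (stratified) {
      unlist(lapply(unique(dataset$labels), function(cl) {
        pool <- which(dataset$labels == cl)
        k <- round(test_fraction * length(pool))
        k <- min(max(k, 1L), length(pool) - 2L)
        sample(pool, k)
      }), use.names = FALSE)
    } else {
      k <- round(test_fraction * n)
      k <- min(max(k, 1L), n - 2L)
      sample(n, k)
    }
  })
  test_idx <- sort(test_idx)
  list(
    train = dataset[-test_idx, ],
    test = dataset[test_idx, ]
  )
}
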