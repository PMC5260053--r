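#' @importFrom rlang %||% abort warn
#' @importFrom stats predict rnorm sd
#' @importFrom utils head modifyList
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Derive `n` independent child seeds from one parent seed. Keeps every seed
# strictly below 2^31 so it is always a valid R integer.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(2147483646L, n))
}

# Class-stratified k-fold assignment; returns an integer vector in 1..k.
# Every fold receives at least one sample of each class when k does not
# exceed the smaller class count (enforced).
stratified_folds <- function(labels, k, seed = NULL) {
  k <- as.integer(k)
  if (k < 2) abort("cross-validation needs at least 2 folds")
  min_class <- min(table(labels))
  if (k > min_class) {
    abort(sprintf(
      "cv_folds = %d exceeds the smaller class count (%d)", k, min_class
    ))
  }
  fold <- integer(length(labels))
  with_seed_(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Split an integer total across classes proportionally to class counts,
# by largest remainder, with at least one sample per class.
allocate_per_class <- function(class_counts, total) {
  exact <- total * class_counts / sum(class_counts)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    top <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  zero <- base == 0
  if (any(zero)) {
    donor <- which.max(base)
    base[zero] <- 1
    base[donor] <- base[donor] - sum(zero)
    if (base[donor] < 1) abort("subsample too small to keep both classes")
  }
  base
}
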