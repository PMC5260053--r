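# Desk-scale configuration used throughout the suite: reduced decade grids
# and small fold counts keep runs tractable while exercising the same code
# paths as the full protocol. Any run_config() argument can be overridden.
test_config <- function(n_bootstraps = 20L, cv_folds = 5L, seed = 1L, ...) {
  args <- utils::modifyList(
    list(
      n_bootstraps = n_bootstraps,
      cv_folds = cv_folds,
      c_grid_selection = 10^(-2:2),
      c_grid_rbf = 10^(0:2),
      gamma_grid_rbf = 10^(-3:-1),
      seed = seed
    ),
    list(...)
  )
  do.call(run_config, args)
}

# small, clearly separated two-class dataset
make_separable <- function(n = 40, p = 6, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1L, -1L), each = n / 2)
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- x[, 1] + gap * (y == 1) - gap / 2
    expression_dataset(x, y)
  })
}

# mixed-signal fixture: a few informative features among noise
make_planted <- function(n = 60, p = 12, informative = 3, delta = 2,
                         ratio = 0.5, seed = 1) {
  simulate_expression(synthetic_spec(
    n_samples = n, n_features = p, n_informative = informative,
    effect_size = delta, n_corr_blocks = 0, block_size = 0,
    class_ratio = ratio, seed = seed
  ))
}
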