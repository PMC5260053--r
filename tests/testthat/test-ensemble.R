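test_that("bootstrap draws have the right size, distinctness and classes", {
  ds <- make_planted(n = 10, p = 6, informative = 2, ratio = 0.4, seed = 1)$dataset
  cfg <- test_config(n_bootstraps = 25L, cv_folds = 2L)
  boots <- generate_bootstraps(ds, cfg)
  expect_length(boots, 25)
  for (b in boots) {
    expect_length(b, 8) # floor(0.8 * 10)
    expect_false(anyDuplicated(b) > 0)
    expect_true(all(b %in% 1:10))
    expect_setequal(unique(ds$labels[b]), c(1L, -1L))
  }
})

test_that("subsample size follows floor(fraction * n) at cohort scale", {
  # 281 samples split 214/67 like an 80% training cohort
  sim <- simulate_expression(synthetic_spec(
    n_samples = 281, n_features = 20, n_informative = 2,
    n_corr_blocks = 0, block_size = 0, class_ratio = 67 / 281, seed = 2
  ))
  cfg <- test_config(n_bootstraps = 5L)
  boots <- generate_bootstraps(sim$dataset, cfg)
  expect_true(all(lengths(boots) == 224)) # floor(0.8 * 281)
  # stratification preserves the class balance
  tab <- table(sim$dataset$labels[boots[[1]]])
  expect_identical(as.integer(tab[["1"]]), 53L)
  expect_identical(as.integer(tab[["-1"]]), 171L)
})

test_that("fraction 1 without replacement is the identity resample", {
  ds <- make_planted(n = 12, p = 5, informative = 2, ratio = 0.5, seed = 3)$dataset
  cfg <- test_config(n_bootstraps = 3L, cv_folds = 2L,
                     subsample_fraction = 1)
  boots <- generate_bootstraps(ds, cfg)
  for (b in boots) expect_identical(b, 1:12)
})

test_that("bootstrap generation is reproducible and seed-sensitive", {
  ds <- make_planted(n = 30, p = 8, informative = 2, seed = 4)$dataset
  cfg <- test_config(n_bootstraps = 10L)
  expect_identical(generate_bootstraps(ds, cfg), generate_bootstraps(ds, cfg))
  cfg2 <- test_config(n_bootstraps = 10L, seed = 99L)
  expect_false(identical(generate_bootstraps(ds, cfg),
                         generate_bootstraps(ds, cfg2)))
})

test_that("with-replacement draws can repeat indices", {
  ds <- make_planted(n = 20, p = 5, informative = 2, ratio = 0.5, seed = 5)$dataset
  cfg <- test_config(n_bootstraps = 20L, with_replacement = TRUE)
  boots <- generate_bootstraps(ds, cfg)
  expect_true(any(vapply(boots, function(b) anyDuplicated(b) > 0, logical(1))))
})

test_that("elimination traces shrink strictly and record every iteration", {
  sim <- make_planted(n = 60, p = 80, informative = 4, delta = 1.5,
                      ratio = 0.3, seed = 7)
  cfg <- test_config(cv_folds = 3L)
  tr <- run_elimination_trace(sim$dataset, cfg)
  expect_s3_class(tr, "elimination_trace")
  expect_gte(nrow(tr), 1)
  expect_true(all(diff(tr$n_features) < 0 | nrow(tr) == 1))
  sets <- tr$features
  if (nrow(tr) > 1) {
    for (i in 2:nrow(tr)) {
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
      expect_lt(length(sets[[i]]), length(sets[[i - 1]]))
    }
  }
  expect_true(all(is.finite(tr$cv_auc) & tr$cv_auc >= 0 & tr$cv_auc <= 1))
  expect_true(attr(tr, "terminated_reason") %in%
                c("no-zeros-remaining", "all-weights-zero",
                  "single-feature-floor"))
})

test_that("an all-zero first fit keeps the pre-elimination feature set", {
  # pure noise and a vanishing C force w = 0 at the first iteration
  sim <- make_planted(n = 30, p = 20, informative = 0, delta = 0,
                      ratio = 0.5, seed = 8)
  cfg <- test_config(cv_folds = 3L, c_grid_selection = 1e-8)
  tr <- run_elimination_trace(sim$dataset, cfg)
  expect_identical(nrow(tr), 1L)
  expect_identical(attr(tr, "terminated_reason"), "all-weights-zero")
  expect_identical(tr$features[[1]], colnames(sim$dataset$x))
})

test_that("optimal-subset selection is argmax with earliest-iteration ties", {
  fake <- tibble::tibble(
    iteration = 1:3, n_features = c(5L, 3L, 2L),
    tuned_c = c(1, 1, 1), cv_auc = c(0.80, 0.90, 0.85),
    features = list(letters[1:5], letters[1:3], letters[1:2]),
    weights = list(NULL, NULL, NULL)
  )
  expect_identical(select_optimal_subset(fake), letters[1:3])
  fake$cv_auc <- c(0.9, 0.9, 0.8)
  expect_identical(select_optimal_subset(fake), letters[1:5])
  expect_identical(select_optimal_subset(fake[1, ]), letters[1:5])
})

test_that("stability scores count resamples and respect the 1..n bounds", {
  subsets <- list(c("a", "b"), c("a", "c"), c("a", "b", "c"), "d")
  sc <- aggregate_stability(subsets, 4)
  expect_identical(attr(sc, "n_bootstraps"), 4L)
  s <- setNames(sc$score, sc$feature_id)
  expect_identical(s[["a"]], 3L)
  expect_identical(s[["b"]], 2L)
  expect_identical(s[["d"]], 1L)
  expect_true(all(sc$score >= 1 & sc$score <= 4))
  expect_false("e" %in% sc$feature_id)
  # duplicated ids inside one subset count once
  sc2 <- aggregate_stability(list(c("a", "a"), "a"), 2)
  expect_identical(sc2$score, 2L)
  expect_error(aggregate_stability(subsets, 5), "must equal")
})

test_that("stability ranking is deterministic with documented tie-breaks", {
  sc <- tibble::tibble(feature_id = c("a", "b", "c"), score = c(5L, 3L, 5L))
  r <- rank_by_stability(sc)
  expect_identical(r$feature_id, c("a", "c", "b"))
  r2 <- rank_by_stability(sc, weight_hint = c(a = 0.1, c = 0.9))
  expect_identical(r2$feature_id, c("c", "a", "b"))
  r3 <- rank_by_stability(tibble::tibble(
    feature_id = character(), score = integer()
  ))
  expect_identical(nrow(r3), 0L)
})

test_that("ensemble selection is reproducible end to end", {
  sim <- make_planted(n = 50, p = 60, informative = 3, delta = 1.5,
                      ratio = 0.3, seed = 10)
  cfg <- test_config(n_bootstraps = 8L, cv_folds = 3L, seed = 21L)
  s1 <- ensemble_select(sim$dataset, cfg)
  s2 <- ensemble_select(sim$dataset, cfg)
  expect_identical(s1$scores$feature_id, s2$scores$feature_id)
  expect_identical(s1$scores$score, s2$scores$score)
  expect_identical(s1$ranking, s2$ranking)
  # the ranking is the tidy() view
  expect_identical(tidy(s1), s1$ranking)
  expect_identical(glance(s1)$n_bootstraps, 8L)
})

test_that("the single-dataset baseline equals its definition and repeats", {
  sim <- make_planted(n = 50, p = 40, informative = 3, delta = 2,
                      ratio = 0.3, seed = 11)
  cfg <- test_config(cv_folds = 3L, seed = 31L)
  a <- select_single_dataset(sim$dataset, cfg)
  b <- select_optimal_subset(run_elimination_trace(sim$dataset, cfg))
  expect_identical(a, b)
  expect_identical(a, select_single_dataset(sim$dataset, cfg))
  expect_lte(length(a), nrow(sim$dataset$x))
})

test_that("fitted supports never exceed the sample count", {
  sim <- make_planted(n = 30, p = 200, informative = 3, delta = 1.5,
                      ratio = 0.3, seed = 12)
  for (cost in 10^(-1:2)) {
    fit <- suppressWarnings(fit_l1_svm(sim$dataset, cost))
    expect_lte(sum(abs(fit$weights) > 1e-10), 30)
  }
})
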