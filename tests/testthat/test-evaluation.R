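test_that("confusion metrics reproduce hand-computed values", {
  perfect <- confusion_metrics(50, 50, 0, 0)
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$f1, 1)
  expect_identical(perfect$mcc, 1)

  m <- confusion_metrics(45, 40, 10, 5)
  expect_equal(m$accuracy, 0.85, tolerance = 1e-12)
  expect_equal(m$f1, 90 / 105, tolerance = 1e-12)
  expect_equal(m$mcc, 1750 / sqrt(6187500), tolerance = 1e-12)
  expect_equal(m$mcc, 0.7035265, tolerance = 1e-6)
  expect_true(m$mcc_defined)

  # a classifier that never predicts positive has an undefined MCC
  deg <- confusion_metrics(0, 80, 0, 20)
  expect_false(deg$mcc_defined)
  expect_identical(deg$mcc, 0)
  expect_error(confusion_metrics(0, 0, 0, 0), "positive")
  # list form
  expect_equal(
    confusion_metrics(list(tp = 45, tn = 40, fp = 10, fn = 5)), m
  )
})

test_that("MCC hits +1 / -1 exactly when the table is error-free or inverted", {
  withr::with_seed(13, {
    for (i in 1:50) {
      tp <- sample(0:8, 1)
      tn <- sample(0:8, 1)
      fp <- sample(0:3, 1)
      fn <- sample(0:3, 1)
      if (tp + tn + fp + fn == 0) next
      m <- confusion_metrics(tp, tn, fp, fn)
      if (!m$mcc_defined) next
      expect_identical(m$mcc == 1, fp == 0 && fn == 0)
      expect_identical(m$mcc == -1, tp == 0 && tn == 0)
    }
  })
})

test_that("AUC equals pairwise ordering probability with midrank ties", {
  expect_identical(auc_score(c(3, 2, 1), c(1, -1, -1)), 1)
  expect_identical(auc_score(c(1, 1, 1, 1), c(1, 1, -1, -1)), 0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1)), 0.75)
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")

  pair_auc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == -1]
    s <- 0
    for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
    s / (length(pos) * length(neg))
  }
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(5:40, 1)
      labels <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
      scores <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
      expect_equal(auc_score(scores, labels), pair_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("flipping the score sign complements the AUC on tie-free scores", {
  withr::with_seed(7, {
    for (i in 1:20) {
      scores <- rnorm(30)
      labels <- c(1, -1, sample(c(1, -1), 28, replace = TRUE))
      expect_equal(
        auc_score(scores, labels) + auc_score(-scores, labels), 1,
        tolerance = 1e-12
      )
    }
  })
})

test_that("Tanimoto similarity equals the Jaccard index", {
  expect_identical(tanimoto(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_identical(tanimoto(c("a", "b"), c("c", "d")), 0)
  expect_equal(tanimoto(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_identical(tanimoto(character(), "a"), 0)
  expect_error(tanimoto(character(), character()), "undefined")

  # property: against a brute-force membership counter on random pairs,
  # and symmetric
  universe <- paste0("g", 1:30)
  withr::with_seed(11, {
    for (i in 1:1000) {
      a <- sample(universe, sample(0:15, 1))
      b <- sample(universe, sample(1:15, 1))
      inter <- sum(vapply(unique(a), function(e) e %in% b, logical(1)))
      uni <- length(unique(c(a, b)))
      expect_equal(tanimoto(a, b), inter / uni, tolerance = 1e-12)
      expect_identical(tanimoto(a, b), tanimoto(b, a))
    }
  })
})

test_that("mean Tanimoto averages all unordered pairs", {
  same <- mean_tanimoto(list(c("a", "b"), c("a", "b"), c("a", "b")))
  expect_identical(same$mean_tanimoto, 1)
  expect_identical(same$sd_tanimoto, 0)
  expect_identical(nrow(same$per_pair), 3L)

  two <- mean_tanimoto(list(c("a", "b", "c"), c("b", "c", "d")))
  expect_equal(two$mean_tanimoto, 0.5)
  expect_identical(two$sd_tanimoto, 0)

  # hand-enumerated pairs: T = 1, 0.25, 0.25, mean 0.5
  three <- mean_tanimoto(list(c("a", "b"), c("a", "b"), c("b", "x", "y")))
  expect_equal(sort(three$per_pair$tanimoto), c(0.25, 0.25, 1))
  expect_equal(three$mean_tanimoto, 0.5)
  expect_error(mean_tanimoto(list(c("a"))), "two sets")

  # invariant to input ordering
  sets <- list(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"))
  m1 <- mean_tanimoto(sets)
  m2 <- mean_tanimoto(rev(sets))
  expect_equal(m1$mean_tanimoto, m2$mean_tanimoto)
  expect_equal(m1$sd_tanimoto, m2$sd_tanimoto)
  expect_identical(glance(m1)$n_subsamples, 4L)
})

test_that("holdout evaluation refuses overlapping samples and scores cleanly", {
  sim <- make_planted(n = 80, p = 10, informative = 3, delta = 2.5,
                      ratio = 0.5, seed = 23)
  sp <- train_test_split(sim$dataset, 0.25, seed = 2)
  cfg <- test_config(cv_folds = 3L)
  expect_error(
    evaluate_on_holdout(sp$train, sp$train, sim$truth, cfg),
    "share sample"
  )
  m <- evaluate_on_holdout(sp$train, sp$test, sim$truth, cfg)
  expect_true(all(c("accuracy", "f1", "mcc", "auc") %in% names(m)))
  expect_gte(m$auc, 0.9) # strong planted signal transfers to the holdout
  expect_error(
    evaluate_on_holdout(sp$train, sp$test, "not_a_feature", cfg),
    "absent"
  )
})

test_that("stability experiments are reproducible and selector-tagged", {
  sim <- make_planted(n = 60, p = 40, informative = 3, delta = 2,
                      ratio = 0.3, seed = 29)
  cfg <- test_config(n_bootstraps = 5L, cv_folds = 3L, seed = 77L)
  r1 <- run_stability_experiment(sim$dataset, "single", n_subsamples = 4,
                                 config = cfg)
  r2 <- run_stability_experiment(sim$dataset, "single", n_subsamples = 4,
                                 config = cfg)
  expect_identical(r1$mean_tanimoto, r2$mean_tanimoto)
  expect_identical(attr(r1, "subsets"), attr(r2, "subsets"))
  expect_identical(attr(r1, "selector"), "single")
  expect_identical(nrow(r1$per_pair), 6L)
  expect_equal(r1$mean_tanimoto, mean(r1$per_pair$tanimoto))
})
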