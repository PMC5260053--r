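test_that("a single-candidate grid and a single-feature list are returned as-is", {
  ds <- make_separable(n = 24, p = 4, seed = 1)
  ev <- evaluate_subset(ds, c_grid = 10, gamma_grid = 0.01, folds = 3, seed = 1)
  expect_identical(ev$best_c, 10)
  expect_identical(ev$best_gamma, 0.01)
  expect_identical(nrow(ev$grid), 1L)

  be <- backward_eliminate(ds, "f1", test_config(cv_folds = 3L))
  expect_identical(nrow(be$auc_curve), 1L)
  expect_identical(be$optimal_subset, "f1")
})

test_that("well-separated clusters score a perfect cross-validated AUC", {
  ds <- make_separable(n = 40, p = 4, gap = 10, seed = 2)
  ev <- evaluate_subset(ds, c_grid = 10^(0:2), gamma_grid = 10^(-3:-1),
                        folds = 4, seed = 2)
  expect_equal(ev$mean_cv_auc, 1, tolerance = 1e-12)
})

test_that("grid ties resolve to the smallest C, then smallest gamma", {
  ds <- make_separable(n = 30, p = 3, gap = 10, seed = 3)
  ev <- evaluate_subset(ds, c_grid = c(1, 10), gamma_grid = c(0.001, 0.01),
                        folds = 3, seed = 3)
  ties <- ev$grid[ev$grid$mean_auc == ev$mean_cv_auc, ]
  ord <- order(ties$cost, ties$gamma)
  expect_identical(ev$best_c, ties$cost[ord][1])
  expect_identical(ev$best_gamma, ties$gamma[ord][1])
})

test_that("backward elimination matches exhaustive prefix evaluation", {
  # independent oracle: score every ranked prefix with e1071 directly,
  # AUC by explicit positive-negative pair counting, same fold partition
  sim <- make_planted(n = 60, p = 6, informative = 2, delta = 2.5,
                      ratio = 0.5, seed = 13)
  ds <- sim$dataset
  cfg <- test_config(cv_folds = 3L, seed = 5L)
  fold_ids <- stabsvm:::stratified_folds(ds$labels, 3, seed = 99)

  pair_auc <- function(scores, labels) {
    pos <- which(labels == 1)
    neg <- which(labels == -1)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    tot / (length(pos) * length(neg))
  }
  oracle_eval <- function(x, y, cost, gamma) {
    fold_auc <- numeric(3)
    for (f in 1:3) {
      tr <- fold_ids != f
      fit <- e1071::svm(x = x[tr, , drop = FALSE],
                        y = factor(y[tr], levels = c(-1, 1)),
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      pr <- predict(fit, x[!tr, , drop = FALSE], decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      dec <- if (strsplit(colnames(dv), "/")[[1]][1] == "1") dv[, 1] else -dv[, 1]
      fold_auc[f] <- pair_auc(dec, y[!tr])
    }
    mean(fold_auc)
  }

  for (ranked in list(c("g2", "g5", "g1", "g4", "g6", "g3"),
                      c("g3", "g1", "g6"))) {
    k <- length(ranked)
    oracle_curve <- numeric(k)
    for (s in k:1) {
      best <- -Inf
      for (cost in cfg$c_grid_rbf) for (gamma in cfg$gamma_grid_rbf) {
        best <- max(best, oracle_eval(
          ds$x[, ranked[1:s], drop = FALSE], ds$labels, cost, gamma
        ))
      }
      oracle_curve[s] <- best
    }
    oracle_opt <- ranked[seq_len(which(oracle_curve == max(oracle_curve))[1])]

    be <- backward_eliminate(ds, ranked, cfg, fold_ids = fold_ids)
    expect_equal(
      be$auc_curve$mean_cv_auc[order(be$auc_curve$subset_size)],
      oracle_curve,
      tolerance = 1e-12
    )
    expect_identical(be$optimal_subset, oracle_opt)
  }
})

test_that("a trailing noise feature is excluded from the optimum", {
  # two informative features ranked first, one pure-noise feature last:
  # the 2-feature prefix must beat the 3-feature one
  sim <- make_planted(n = 80, p = 3, informative = 2, delta = 2.5,
                      ratio = 0.5, seed = 17)
  truth_first <- c(sim$truth, setdiff(colnames(sim$dataset$x), sim$truth))
  be <- backward_eliminate(sim$dataset, truth_first,
                           test_config(cv_folds = 4L, seed = 3L))
  expect_true(all(be$optimal_subset %in% sim$truth))
})

test_that("the curve is complete and the optimum is its maximum prefix", {
  sim <- make_planted(n = 40, p = 8, informative = 2, delta = 2,
                      ratio = 0.5, seed = 19)
  ranked <- colnames(sim$dataset$x)
  cfg <- test_config(cv_folds = 3L)
  be <- backward_eliminate(sim$dataset, ranked, cfg)
  expect_identical(sort(be$auc_curve$subset_size), 1:8)
  expect_true(all(be$auc_curve$mean_cv_auc >= 0 & be$auc_curve$mean_cv_auc <= 1))
  expect_equal(be$optimal_auc, max(be$auc_curve$mean_cv_auc))
  expect_identical(be$optimal_subset, ranked[seq_len(be$optimal_size)])
  # ties across sizes go to the most parsimonious subset
  top <- be$auc_curve$subset_size[
    be$auc_curve$mean_cv_auc == be$optimal_auc
  ]
  expect_identical(be$optimal_size, min(top))
  expect_identical(glance(be)$optimal_size, be$optimal_size)
  expect_identical(tidy(be), be$auc_curve)
})
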