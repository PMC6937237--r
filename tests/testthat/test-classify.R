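test_that("fold plans partition patients, grouped and reproducible", {
  pats <- sprintf("p%02d", 1:23)
  labs <- rep(c("A", "B", "C"), length.out = 23)
  plan <- make_folds(pats, labs, k = 5, seed = 3)
  expect_length(plan$folds, 5)
  expect_setequal(unlist(plan$folds), pats)
  expect_identical(anyDuplicated(unlist(plan$folds)), 0L)
  # stratification: fold class counts within 1 of each other
  for (cl in c("A", "B", "C")) {
    per_fold <- vapply(plan$folds, function(f) sum(labs[match(f, pats)] == cl), 0L)
    expect_lte(diff(range(per_fold)), 1L)
  }
  # same seed -> identical plan (reused across feature sets)
  expect_identical(serialize(make_folds(pats, labs, k = 5, seed = 3), NULL),
                   serialize(plan, NULL))
  # k = n gives leave-one-patient-out
  loo <- suppressWarnings(make_folds(pats, labs, k = 23, seed = 1))
  expect_true(all(lengths(loo$folds) == 1))
  expect_error(make_folds(pats, labs, k = 24, seed = 1), "exceeds")
  expect_warning(make_folds(pats[1:5], c("A", "A", "A", "A", "B"), k = 3,
                            seed = 1), "non-strict")
})

test_that("f-statistic matches hand ANOVA and aov on small inputs", {
  # classes {1,2} vs {3,4}: SSB = 4, SSW = 1, df (1, 2) -> F = 8
  expect_equal(f_statistic(matrix(c(1, 2, 3, 4), 4, 1),
                           c("a", "a", "b", "b")), 8)
  # constant feature -> 0
  expect_equal(f_statistic(matrix(5, 6, 1), rep(c("a", "b"), 3)), 0)
  # oracle: aov per feature on random data
  set.seed(51)
  x <- matrix(rnorm(8 * 5), 8, 5)
  g <- rep(c("a", "b", "c"), c(3, 3, 2))
  f <- f_statistic(x, g)
  for (j in 1:5) {
    ref <- summary(aov(x[, j] ~ factor(g)))[[1]]$`F value`[1]
    expect_equal(f[j], ref, tolerance = 1e-8)
  }
  # screening keeps the top-m by F with stable index ties
  ff <- c(1, 3, 3, 2, 5)
  expect_identical(rgpipe:::top_m_indices(ff, 3), c(2L, 3L, 5L))
})

test_that("balanced accuracy averages per-class recall", {
  expect_equal(balanced_accuracy(matrix(c(2, 1, 0, 1), 2, 2)), 0.75)
  expect_equal(balanced_accuracy(diag(c(3, 7, 2))), 1)
  # balanced classes: equals plain accuracy
  cm <- matrix(c(6, 2, 4, 8), 2, 2, byrow = TRUE)  # 8 per class... no: rows sum 8, 12
  cm <- matrix(c(6, 4, 3, 7), 2, 2, byrow = TRUE)  # both rows sum 10
  expect_equal(balanced_accuracy(cm), sum(diag(cm)) / sum(cm))
  expect_error(balanced_accuracy(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)),
               "test sample")
})

test_that("auprc matches threshold enumeration, including ties", {
  expect_equal(auprc(c(.9, .8, .7, .6), c(TRUE, FALSE, TRUE, FALSE)), 5 / 6)
  expect_equal(auprc(c(.9, .8), c(TRUE, FALSE)), 1)          # perfect
  expect_equal(auprc(4:1, c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_error(auprc(c(1, 2), c(FALSE, FALSE)), "positive")
  # exhaustive oracle on all inputs of <= 8 samples (random scores, ties)
  set.seed(52)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    p <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(p)) p[1] <- TRUE
    expect_equal(auprc(s, p), auprc_bruteforce(s, p), tolerance = 1e-10)
  }
  # multiclass: mean of the one-vs-rest values
  dv <- cbind(A = c(2, 1, 0), B = c(0, 2, 1), C = c(1, 0, 2))
  labs <- c("A", "B", "C")
  expect_equal(auprc_multiclass(dv, labs),
               mean(c(auprc(dv[, 1], labs == "A"),
                      auprc(dv[, 2], labs == "B"),
                      auprc(dv[, 3], labs == "C"))))
})

test_that("nested CV recovers separable classes and stays at chance on noise", {
  set.seed(53)
  n <- 24
  y <- rep(c("A", "B", "C"), each = 8)
  # orthogonal class shifts -> one-vs-rest separable
  x <- matrix(rnorm(n * 12, 0, 0.3), n, 12)
  x[y == "A", 1] <- x[y == "A", 1] + 4
  x[y == "B", 2] <- x[y == "B", 2] + 4
  x[y == "C", 3] <- x[y == "C", 3] + 4
  pats <- sprintf("q%02d", 1:n)
  plan <- make_folds(pats, y, k = 4, seed = 5)
  cv <- nested_cv(x, y, pats, plan, cost_grid = c(0.1, 10), inner_k = 2,
                  seed = 6)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$mean_auprc, 1)
  expect_length(cv$per_fold, 4)
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))

  # shuffled labels: mean accuracy within the permutation CI of 1/3
  accs <- c()
  for (s in 1:8) {
    yp <- sample(y)
    cvp <- nested_cv(x, yp, pats, plan, cost_grid = 1, seed = s)
    accs <- c(accs, cvp$mean_accuracy)
  }
  expect_lt(abs(mean(accs) - 1 / 3), 0.12)
})

test_that("test-fold perturbations never leak into selection or models", {
  co <- small_cohort(n = 15, seed = 61)
  cl <- clinical_table(co)
  x <- cohort_radiomic_features(co)
  y <- factor(cl$genotype)
  plan <- suppressWarnings(make_folds(cl$patient_id, cl$genotype, k = 3,
                                      seed = 7))
  base <- nested_cv(x, y, cl$patient_id, plan, m_select = 20,
                    cost_grid = c(0.1, 10), inner_k = 2, seed = 8)
  for (i in seq_len(plan$k)) {
    rows <- which(cl$patient_id %in% plan$folds[[i]])
    x2 <- x
    x2[rows, ] <- x[sample(rows), sample(ncol(x))]   # scramble test rows
    pert <- nested_cv(x2, y, cl$patient_id, plan, m_select = 20,
                      cost_grid = c(0.1, 10), inner_k = 2, seed = 8)
    expect_identical(pert$per_fold[[i]]$selected_features,
                     base$per_fold[[i]]$selected_features)
    expect_identical(pert$per_fold[[i]]$chosen_cost,
                     base$per_fold[[i]]$chosen_cost)
    expect_equal(pert$per_fold[[i]]$weights, base$per_fold[[i]]$weights,
                 tolerance = 1e-12)
  }
})

test_that("chance runs centre on the class-count baseline", {
  set.seed(71)
  n <- 24
  y <- rep(c("A", "B"), each = 12)
  pats <- sprintf("c%02d", 1:n)
  x <- matrix(rnorm(n), n, 1)
  plan <- make_folds(pats, y, k = 4, seed = 2)
  ch <- chance_run(x, y, pats, plan, n_repeats = 20, seed = 3,
                   cost_grid = 1)
  expect_identical(dim(ch$accuracy), c(20L, 4L))
  expect_lt(abs(ch$mean_accuracy - 0.5), 0.08)
})
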