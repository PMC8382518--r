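test_that("stratified folds partition samples and preserve class balance", {
  y <- rep(c("a", "b"), each = 5)
  folds <- stratified_folds(y, 5, seed = 1)
  expect_length(folds, 5)
  # one sample per class per fold
  for (f in folds) {
    expect_length(f, 2)
    expect_setequal(y[f], c("a", "b"))
  }
  # partition laws on an unbalanced problem
  set.seed(2)
  y2 <- sample(rep(c("x", "y", "z"), c(12, 9, 6)))
  folds2 <- stratified_folds(y2, 4, seed = 3)
  expect_setequal(unlist(folds2), seq_along(y2))
  expect_equal(sum(lengths(folds2)), length(y2))
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(folds2[[i]], folds2[[j]]), 0)
  # within-fold class counts off by at most one from perfect proportion
  for (f in folds2) {
    tab <- table(factor(y2[f], levels = c("x", "y", "z")))
    expect_true(all(abs(tab - c(3, 2.25, 1.5)) <= 1))
  }

  expect_identical(stratified_folds(y2, 4, seed = 3), folds2)
  expect_error(stratified_folds(y, 11, seed = 1), "exceeds")
  expect_warning(stratified_folds(c("a", "a", "a", "b"), 3, seed = 1),
                 "fewer members")
})

test_that("separable data scores perfectly and bookkeeping holds", {
  skip_if_not_installed("class")
  set.seed(10)
  n <- 30
  cl <- rep(1:3, each = 10)
  X <- rbind(10 * (cl == 1), 10 * (cl == 2), 10 * (cl == 3)) +
    matrix(rnorm(3 * n, sd = 0.1), 3, n)
  d <- expression_dataset(X, paste0("g", 1:3), paste0("s", 1:n),
                          labels = paste0("c", cl))
  cv <- cross_validated_accuracy(d, 1:3, classifier_knn(1), n_folds = 5,
                                 n_repeats = 5, seed = 1)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_length(cv$per_fold, 25)
  expect_equal(cv$mean_accuracy, mean(cv$per_fold))
})

test_that("permuted labels score at chance", {
  skip_if_not_installed("class")
  sim <- generate_dataset(synthetic_spec(n_samples = 60, seed = 11))
  d <- sim$data
  set.seed(12)
  d$labels <- sample(d$labels)   # break the gene-label association
  cv <- cross_validated_accuracy(d, 1:30, classifier_knn(1), n_folds = 5,
                                 n_repeats = 5, seed = 2)
  # 3 balanced classes: chance 1/3, binomial se over 60 held-out samples
  se <- sqrt((1 / 3) * (2 / 3) / 60)
  expect_lt(abs(cv$mean_accuracy - 1 / 3), 3 * se)
})

test_that("selection curve reports the best result over the grid", {
  skip_if_not_installed("class")
  sim <- generate_dataset(synthetic_spec(n_samples = 36, n_clusters = 3,
                                         n_informative = 6, n_redundant = 6,
                                         n_noise = 30, seed = 13))
  grid <- list(g3cs_config(n_clusters = 3, alpha = 0.1, seed = 13,
                           max_iter = 40),
               g3cs_config(n_clusters = 3, alpha = 1, seed = 13,
                           max_iter = 40))
  curve <- selection_curve(sim$data, grid, gene_counts = c(5, 10),
                           classifier = classifier_knn(1),
                           n_folds = 3, n_repeats = 2, seed = 5)
  expect_equal(curve$gene_counts, c(5L, 10L))
  expect_equal(nrow(curve$summary), 2)

  # max-dominance: best-over-grid >= each single grid member
  for (i in seq_along(curve$gene_counts)) {
    for (cfg in grid) {
      f <- g3cs_fit(sim$data, cfg)
      cv <- cross_validated_accuracy(
        sim$data, rank_genes(f, curve$gene_counts[i])$selected,
        classifier_knn(1), n_folds = 3, n_repeats = 2, seed = 5)
      expect_gte(curve$results[[i]]$mean_accuracy, cv$mean_accuracy)
    }
  }

  # degenerate single-point grid equals a direct evaluation
  c1 <- selection_curve(sim$data, grid[1], gene_counts = 5,
                        classifier = classifier_knn(1),
                        n_folds = 3, n_repeats = 2, seed = 5)
  f <- g3cs_fit(sim$data, grid[[1]])
  direct <- cross_validated_accuracy(sim$data, rank_genes(f, 5)$selected,
                                     classifier_knn(1), 3, 2, seed = 5)
  expect_equal(c1$results[[1]]$mean_accuracy, direct$mean_accuracy)

  expect_error(selection_curve(sim$data, list(), gene_counts = 5),
               "nonempty")
})

test_that("svm and random-forest adapters honour the contract", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("randomForest")
  set.seed(14)
  n <- 24
  cl <- rep(c("a", "b"), each = n / 2)
  X <- rbind(ifelse(cl == "a", 5, -5), ifelse(cl == "a", -5, 5)) +
    matrix(rnorm(2 * n, sd = 0.2), 2, n)
  d <- expression_dataset(X, c("g1", "g2"), paste0("s", 1:n), labels = cl)
  for (clf in list(classifier_svm(), classifier_rf(ntree = 50))) {
    cv <- cross_validated_accuracy(d, 1:2, clf, n_folds = 4, n_repeats = 2,
                                   seed = 3)
    expect_gt(cv$mean_accuracy, 0.9)
  }
})
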