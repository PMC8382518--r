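#' Stratified cross-validation folds
#'
#' Partitions sample indices into `n_folds` disjoint folds, preserving
#' class proportions to within one sample per class per fold. Classes with
#' fewer members than folds are spread over as many folds as they have
#' members, with a warning. Deterministic given the seed.
#'
#' @param labels Vector of class identifiers, one per sample.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return List of `n_folds` integer index vectors; their union is all
#'   samples and they are pairwise disjoint.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds > n)
    stop("n_folds (", n_folds, ") exceeds the number of samples (", n, ")",
         call. = FALSE)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  tab <- table(labels)
  if (any(tab < n_folds))
    warning("class(es) ", paste(names(tab)[tab < n_folds], collapse = ", "),
            " have fewer members than folds; folds will be uneven",
            call. = FALSE)
  folds <- vector("list", n_folds)
  with_seed(seed, {
    start <- 0L
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      # rotate the starting fold per class so fold sizes stay balanced
      f <- ((seq_along(idx) - 1L + start) %% n_folds) + 1L
      for (j in seq_len(n_folds))
        folds[[j]] <- c(folds[[j]], idx[f == j])
      start <- (start + length(idx)) %% n_folds
    }
  })
  lapply(folds, sort)
}

#' Classifier adapters
#'
#' Evaluation classifiers enter only through an opaque contract: a list
#' with a `name`, a `fit(x, y)` function returning a model, and a
#' `predict(model, x)` function returning labels, where `x` is a
#' samples x genes matrix. These constructors wrap the standard k-nearest
#' neighbour, support-vector-machine and random-forest learners.
#'
#' @param k Neighbour count for the k-NN classifier.
#' @param ... Passed through to the underlying learner.
#' @return A classifier contract list.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classifier_knn <- function(k = 1L) {
  if (!requireNamespace("class", quietly = TRUE))
    stop("package 'class' is required for classifier_knn", call. = FALSE)
  list(
    name = sprintf("%d-nn", k),
    fit = function(x, y) list(x = x, y = factor(y)),
    predict = function(model, x)
      as.character(class::knn(model$x, x, model$y, k = k)))
}

#' @rdname classifiers
#' @export
classifier_svm <- function(...) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("package 'e1071' is required for classifier_svm", call. = FALSE)
  list(
    name = "svm",
    fit = function(x, y) e1071::svm(x, factor(y), ...),
    predict = function(model, x) as.character(stats::predict(model, x)))
}

#' @rdname classifiers
#' @export
classifier_rf <- function(...) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("package 'randomForest' is required for classifier_rf",
         call. = FALSE)
  list(
    name = "rf",
    fit = function(x, y) randomForest::randomForest(x, factor(y), ...),
    predict = function(model, x) as.character(stats::predict(model, x)))
}

#' Repeated cross-validated classification accuracy of a gene subset
#'
#' Restricts the data to the selected genes, then runs `n_repeats` rounds
#' of stratified `n_folds`-fold cross-validation with the given classifier
#' contract. Note the genes are assumed to have been selected on the full
#' data before splitting (the package's evaluation protocol); for an
#' unbiased estimate nest the selection inside the folds yourself.
#'
#' @param data A labelled [expression_dataset()].
#' @param selected_genes Integer indices of the genes to evaluate.
#' @param classifier A classifier contract, see [classifiers].
#' @param n_folds Folds per round (default 5).
#' @param n_repeats Rounds, each with a fresh fold partition (default 5).
#' @param seed Integer seed.
#' @return A list of class `cv_result`: `mean_accuracy`, `sd_accuracy`
#'   (sd over the repeat-level mean accuracies), `per_fold` (all
#'   `n_folds * n_repeats` fold accuracies), `per_repeat`, `n_folds`,
#'   `n_repeats`, `classifier_name`.
#' @export
cross_validated_accuracy <- function(data, selected_genes, classifier,
                                     n_folds = 5L, n_repeats = 5L,
                                     seed = 1L) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(data$labels))
    stop("dataset has no labels; cannot evaluate classification",
         call. = FALSE)
  selected_genes <- as.integer(selected_genes)
  if (any(selected_genes < 1L | selected_genes > nrow(data$values)))
    stop("selected gene index out of range", call. = FALSE)
  xs <- t(data$values[selected_genes, , drop = FALSE])  # samples x genes
  y <- data$labels
  per_fold <- numeric(0)
  per_repeat <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(y, n_folds, seed = seed + r - 1L)
    acc <- vapply(folds, function(test) {
      train <- setdiff(seq_along(y), test)
      model <- classifier$fit(xs[train, , drop = FALSE], y[train])
      pred <- tryCatch(
        classifier$predict(model, xs[test, , drop = FALSE]),
        error = function(e)
          stop("classifier '", classifier$name, "' failed on a fold: ",
               conditionMessage(e), call. = FALSE))
      mean(pred == y[test])
    }, numeric(1))
    per_fold <- c(per_fold, acc)
    per_repeat[r] <- mean(acc)
  }
  structure(
    list(mean_accuracy = mean(per_fold),
         sd_accuracy = stats::sd(per_repeat),
         per_fold = per_fold, per_repeat = per_repeat,
         n_folds = n_folds, n_repeats = n_repeats,
         classifier_name = classifier$name),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: accuracy %.4f +/- %.4f (%d x %d-fold)\n",
              x$classifier_name, x$mean_accuracy, x$sd_accuracy,
              x$n_repeats, x$n_folds))
  invisible(x)
}

#' Default hyperparameter grid
#'
#' All combinations of `alpha`, `beta`, `gamma` over the given values
#' (default `10^(-3:3)`), as a list of [g3cs_config()] objects.
#'
#' @param n_clusters Cluster count passed to every configuration.
#' @param values Candidate values for each of the three weights.
#' @param ... Further arguments passed to [g3cs_config()].
#' @return List of `g3cs_config` objects.
#' @export
default_grid <- function(n_clusters, values = 10^(-3:3), ...) {
  gg <- expand.grid(alpha = values, beta = values, gamma = values)
  lapply(seq_len(nrow(gg)), function(i)
    g3cs_config(n_clusters = n_clusters, alpha = gg$alpha[i],
                beta = gg$beta[i], gamma = gg$gamma[i], ...))
}

#' Accuracy curve over numbers of selected genes
#'
#' For each gene count, fits the selection model at every configuration in
#' the grid, evaluates the cross-validated accuracy of the resulting gene
#' subset and keeps the best result over the grid (the best-over-grid
#' protocol: the reported accuracy at each count is the maximum over the
#' hyperparameter grid).
#'
#' @param data A labelled [expression_dataset()].
#' @param config_grid Nonempty list of [g3cs_config()] objects.
#' @param gene_counts Increasing integer vector of subset sizes
#'   (default `c(10, 20, 30, 40, 50)`).
#' @param classifier Classifier contract, see [classifiers].
#' @param n_folds,n_repeats,seed Passed to [cross_validated_accuracy()].
#' @return A list of class `selection_curve`: `gene_counts`, `results`
#'   (list of the best `cv_result` per count), `best_configs`, and a
#'   `summary` data frame with columns `n_genes`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
selection_curve <- function(data, config_grid,
                            gene_counts = c(10L, 20L, 30L, 40L, 50L),
                            classifier = classifier_knn(5L),
                            n_folds = 5L, n_repeats = 5L, seed = 1L) {
  if (length(config_grid) == 0L)
    stop("config_grid must be nonempty", call. = FALSE)
  gene_counts <- sort(unique(as.integer(gene_counts)))
  fits <- lapply(config_grid, function(cfg) g3cs_fit(data, cfg))
  results <- vector("list", length(gene_counts))
  best_configs <- vector("list", length(gene_counts))
  for (i in seq_along(gene_counts)) {
    d <- gene_counts[i]
    best <- NULL
    for (j in seq_along(fits)) {
      ranking <- rank_genes(fits[[j]], n_select = d)
      cv <- cross_validated_accuracy(data, ranking$selected, classifier,
                                     n_folds, n_repeats, seed)
      if (is.null(best) || cv$mean_accuracy > best$mean_accuracy) {
        best <- cv
        best_configs[[i]] <- config_grid[[j]]
      }
    }
    results[[i]] <- best
  }
  structure(
    list(gene_counts = gene_counts, results = results,
         best_configs = best_configs,
         summary = data.frame(
           n_genes = gene_counts,
           mean_accuracy = vapply(results, `[[`, numeric(1),
                                  "mean_accuracy"),
           sd_accuracy = vapply(results, `[[`, numeric(1),
                                "sd_accuracy"))),
    class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("selection_curve (best-over-grid accuracies):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
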