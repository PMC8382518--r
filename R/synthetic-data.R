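#' Specification of a synthetic expression dataset
#'
#' Describes the planted structure the selection model assumes: samples in
#' `n_clusters` near-equal groups, `n_informative` genes whose cluster means
#' differ, `n_redundant` genes that are noisy copies of informative genes,
#' and `n_noise` genes with no cluster dependence. The defaults give a
#' 200-gene x 60-sample matrix with 3 clusters, 10 informative, 20
#' redundant and 170 noise genes, an effect size of 2 noise standard
#' deviations and a redundancy perturbation of 0.1.
#'
#' @param n_samples Number of samples.
#' @param n_clusters Number of sample clusters (>= 2).
#' @param n_informative Number of cluster-informative genes
#'   (>= `n_clusters`).
#' @param n_redundant Number of genes copied (with noise) from informative
#'   parents.
#' @param n_noise Number of pure-noise genes.
#' @param effect_size Cluster mean shift in units of `noise_sd`.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param redundancy_sd Standard deviation of the perturbation added to
#'   copied genes.
#' @param seed Integer seed; the dataset is fully determined by the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60L, n_clusters = 3L,
                           n_informative = 10L, n_redundant = 20L,
                           n_noise = 170L, effect_size = 2.0,
                           noise_sd = 1.0, redundancy_sd = 0.1,
                           seed = 1L) {
  stopifnot(n_samples >= 2, n_clusters >= 2,
            n_informative >= n_clusters, n_redundant >= 0, n_noise >= 0,
            noise_sd > 0, redundancy_sd >= 0)
  if (n_redundant > 0 && n_informative < 1)
    stop("redundant genes need informative parents", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples),
         n_clusters = as.integer(n_clusters),
         n_informative = as.integer(n_informative),
         n_redundant = as.integer(n_redundant),
         n_noise = as.integer(n_noise),
         effect_size = effect_size, noise_sd = noise_sd,
         redundancy_sd = redundancy_sd, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# A +/-1 sign pattern over clusters with at least one between-cluster
# contrast (never all-equal), drawn uniformly from the admissible set.
draw_sign_pattern <- function(c) {
  repeat {
    s <- sample(c(-1, 1), c, replace = TRUE)
    if (length(unique(s)) > 1L) return(s)
  }
}

#' Generate a synthetic expression dataset with known truth
#'
#' Samples are assigned to clusters in near-equal contiguous blocks. Each
#' informative gene receives a per-cluster mean `effect_size * sign`, where
#' the +/-1 sign pattern over clusters is drawn once per gene and always
#' contains both signs, so every informative gene separates at least one
#' cluster pair; Gaussian noise of sd `noise_sd` is added. Each redundant
#' gene is its parent informative gene's row plus Gaussian noise of sd
#' `redundancy_sd` (parents are assigned round-robin). Noise genes are pure
#' `N(0, noise_sd^2)` with no cluster dependence.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `data` (an [expression_dataset()] carrying
#'   the cluster labels) and `truth` (class `synthetic_truth`: per-sample
#'   `cluster_labels`, per-gene `gene_roles` in
#'   informative/redundant/noise, and `parent_of`, the parent gene index
#'   for each redundant gene, `NA` elsewhere).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; c <- spec$n_clusters
  mi <- spec$n_informative; mr <- spec$n_redundant; mn <- spec$n_noise
  m <- mi + mr + mn
  cluster <- sort(rep_len(seq_len(c), n))

  with_seed(spec$seed, {
    X <- matrix(0, m, n)
    for (g in seq_len(mi)) {
      mu <- spec$effect_size * spec$noise_sd * draw_sign_pattern(c)
      X[g, ] <- mu[cluster] + stats::rnorm(n, sd = spec$noise_sd)
    }
    parent_of <- rep(NA_integer_, m)
    if (mr > 0) {
      parents <- rep_len(seq_len(mi), mr)
      for (j in seq_len(mr)) {
        g <- mi + j
        parent_of[g] <- parents[j]
        X[g, ] <- X[parents[j], ] +
          stats::rnorm(n, sd = spec$redundancy_sd)
      }
    }
    if (mn > 0) {
      X[mi + mr + seq_len(mn), ] <-
        matrix(stats::rnorm(mn * n, sd = spec$noise_sd), mn, n)
    }

    roles <- rep(c("informative", "redundant", "noise"), c(mi, mr, mn))
    gene_ids <- paste0(c("inf_", "red_", "noise_")[match(roles,
                         c("informative", "redundant", "noise"))],
                       unlist(lapply(c(mi, mr, mn), seq_len)))
    data <- expression_dataset(
      X, gene_ids = gene_ids,
      sample_ids = paste0("s", seq_len(n)),
      labels = paste0("c", cluster))
    truth <- structure(
      list(cluster_labels = cluster, gene_roles = roles,
           parent_of = parent_of),
      class = "synthetic_truth")
    list(data = data, truth = truth)
  })
}

#' Precision of a ranking at depth k
#'
#' Fraction of the top-k ranked genes whose planted role belongs to the
#' positive set.
#'
#' @param ranking A [select_top_genes()] result over the synthetic genes.
#' @param truth The `synthetic_truth` from [generate_dataset()].
#' @param k Depth, at most the number of genes.
#' @param positives Character vector of roles counted as positive
#'   (default `"informative"`).
#' @return A number in \[0, 1\].
#' @export
precision_at_k <- function(ranking, truth, k, positives = "informative") {
  stopifnot(inherits(ranking, "gene_ranking"),
            inherits(truth, "synthetic_truth"))
  m <- length(truth$gene_roles)
  if (k < 1L || k > m)
    stop("k must be between 1 and ", m, call. = FALSE)
  top <- ranking$order[seq_len(k)]
  mean(truth$gene_roles[top] %in% positives)
}

#' Rank shift of redundant genes between two rankings
#'
#' Mean rank of the planted redundant genes under `ranking_a` minus their
#' mean rank under `ranking_b`. Comparing a fit with the covariance penalty
#' active against one without it, a positive shift means the penalty pushed
#' redundant genes down the ranking (excluded them), which is the behaviour
#' the penalty exists to produce.
#'
#' @param ranking_a,ranking_b [select_top_genes()] results over the same
#'   gene set.
#' @param truth The `synthetic_truth` from [generate_dataset()].
#' @return Mean rank difference (positive: redundant genes rank worse under
#'   `ranking_a`).
#' @export
redundancy_rank_shift <- function(ranking_a, ranking_b, truth) {
  stopifnot(inherits(ranking_a, "gene_ranking"),
            inherits(ranking_b, "gene_ranking"),
            inherits(truth, "synthetic_truth"))
  if (length(ranking_a$order) != length(ranking_b$order))
    stop("rankings cover different gene sets", call. = FALSE)
  if (!is.null(ranking_a$gene_ids) && !is.null(ranking_b$gene_ids) &&
      !identical(ranking_a$gene_ids, ranking_b$gene_ids))
    stop("rankings cover different gene sets", call. = FALSE)
  red <- which(truth$gene_roles == "redundant")
  if (length(red) == 0L)
    stop("truth contains no redundant genes", call. = FALSE)
  mean(gene_ranks(ranking_a)[red]) - mean(gene_ranks(ranking_b)[red])
}
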