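#' Construct an expression dataset
#'
#' Bundles a genes-by-samples expression matrix with gene and sample
#' identifiers and, optionally, per-sample class labels. Labels are carried
#' for downstream classification evaluation only; gene selection itself never
#' looks at them.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. All
#'   entries must be finite.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param labels Optional vector of class identifiers, one per sample, with
#'   at least two distinct classes.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids` and `labels`.
#' @export
#'
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_dataset(x)
expression_dataset <- function(values,
                               gene_ids = rownames(values),
                               sample_ids = colnames(values),
                               labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (m < 2L || n < 2L)
    stop("expression matrix must have at least 2 genes and 2 samples, got ",
         m, " x ", n, call. = FALSE)
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene row ", bad[1L],
         ", sample column ", bad[2L], call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != m)
    stop("gene_ids length (", length(gene_ids), ") != number of genes (", m, ")",
         call. = FALSE)
  if (length(sample_ids) != n)
    stop("sample_ids length (", length(sample_ids), ") != number of samples (",
         n, ")", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("labels length (", length(labels),
           ") != number of samples (", n, ")", call. = FALSE)
    if (length(unique(labels)) < 2L)
      stop("labels must contain at least 2 distinct classes", call. = FALSE)
    labels <- as.character(labels)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", length(x$gene_ids), " genes x ",
      length(x$sample_ids), " samples",
      if (!is.null(x$labels))
        paste0(" (", length(unique(x$labels)), " labelled classes)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix from delimited text
#'
#' Reads a plain-text matrix with one identifier row and one identifier
#' column. Cells must all be numeric; missing or non-numeric values are
#' rejected rather than imputed, with the offending coordinate named.
#'
#' @param path Path to a delimited text file. The first row holds column
#'   identifiers, the first column row identifiers.
#' @param orientation Either `"genes-in-rows"` (default) or
#'   `"genes-in-columns"`. The returned dataset is always genes x samples.
#' @param delimiter Field delimiter, default tab.
#' @param labels Optional vector of class labels (one per sample, in file
#'   sample order) attached to the result.
#'
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, orientation = c("genes-in-rows",
                                                  "genes-in-columns"),
                            delimiter = "\t", labels = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = 1L, check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  mat <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                 dimnames = dimnames(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", mat[bad[1L], bad[2L]], "' at row '",
         rownames(mat)[bad[1L]], "', column '", colnames(mat)[bad[2L]], "'",
         call. = FALSE)
  }
  if (orientation == "genes-in-columns") num <- t(num)
  expression_dataset(num, gene_ids = rownames(num),
                     sample_ids = colnames(num), labels = labels)
}

#' Write an expression dataset as delimited text
#'
#' @param data An [expression_dataset()].
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @export
write_expression <- function(data, path, delimiter = "\t") {
  stopifnot(inherits(data, "expression_dataset"))
  df <- data.frame(gene_id = data$gene_ids,
                   format(data$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", data$sample_ids)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Standardize each gene to zero mean and unit variance
#'
#' Optional preprocessing: centres every gene (row) and scales it by its
#' sample standard deviation. Constant genes are centred but left unscaled.
#' Not applied by default anywhere in the package, since the covariance
#' penalty is deliberately scale-dependent.
#'
#' @param data An [expression_dataset()].
#' @return A standardized [expression_dataset()].
#' @export
standardize_genes <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  v <- data$values
  mu <- rowMeans(v)
  s <- apply(v, 1L, stats::sd)
  s[s == 0] <- 1
  data$values <- (v - mu) / s
  dimnames(data$values) <- list(data$gene_ids, data$sample_ids)
  data
}

#' Run configuration for the gene-selection solver
#'
#' Collects every tunable of the model and its optimizer. The three
#' regularization weights trade off row sparsity of the projection
#' (`alpha`), the gene-covariance redundancy penalty (`beta`) and the
#' sample-graph manifold term (`gamma`).
#'
#' @param n_clusters Number of sample clusters `c`; the projection maps genes
#'   onto `c` pseudo-label dimensions. Must satisfy `c <= min(m, n)`.
#' @param alpha,beta,gamma Nonnegative regularization weights.
#' @param k_neighbors Neighbour count for the sample similarity graph
#'   (default 5).
#' @param t_width Gaussian kernel width for the similarity graph
#'   (default 0.5).
#' @param rho Orthogonality penalty constant for the multiplicative F update
#'   (default 1e3). Unused by the default Procrustes update.
#' @param kappa Orthogonality penalty constant for the multiplicative Z
#'   update (default 1e3); larger values pull `Z` closer to column
#'   orthonormality.
#' @param max_iter Maximum number of alternating sweeps (default 200).
#' @param tol Relative objective-change stopping threshold (default 1e-5).
#' @param epsilon Row-norm floor in the l2,1 reweighting matrix
#'   (default 1e-8).
#' @param seed Integer seed controlling solver initialization.
#' @param n_select Number of genes to keep when ranking (default 50).
#' @param f_method F-update rule: exact `"procrustes"` (default) or the
#'   penalized `"multiplicative"` rule.
#' @param correlation_mode Reading of the covariance adjustment, see
#'   [adjust_correlation()].
#' @param psd_penalty Apply the covariance penalty through the
#'   positive-semidefinite part of the symmetrized adjusted correlation
#'   (default TRUE). The adjusted matrix is indefinite in general, which
#'   would leave the objective unbounded below and the projection
#'   subproblem non-convex; clipping its negative eigenvalues keeps every
#'   objective term nonnegative and the P step an exact convex minimizer
#'   while still penalizing genes with large aggregate covariance.
#'
#' @return A list of class `g3cs_config`.
#' @export
g3cs_config <- function(n_clusters,
                        alpha = 1, beta = 1, gamma = 1,
                        k_neighbors = 5L, t_width = 0.5,
                        rho = 1e3, kappa = 1e3,
                        max_iter = 200L, tol = 1e-5,
                        epsilon = 1e-8, seed = 1L,
                        n_select = 50L,
                        f_method = c("procrustes", "multiplicative"),
                        correlation_mode = c("printed", "diag-rowsum"),
                        psd_penalty = TRUE) {
  f_method <- match.arg(f_method)
  correlation_mode <- match.arg(correlation_mode)
  stopifnot(n_clusters >= 1, alpha >= 0, beta >= 0, gamma >= 0,
            k_neighbors >= 1, t_width > 0, rho > 0, kappa > 0,
            max_iter >= 1, tol > 0, epsilon > 0, n_select >= 1)
  structure(
    list(n_clusters = as.integer(n_clusters),
         alpha = alpha, beta = beta, gamma = gamma,
         k_neighbors = as.integer(k_neighbors), t_width = t_width,
         rho = rho, kappa = kappa,
         max_iter = as.integer(max_iter), tol = tol,
         epsilon = epsilon, seed = as.integer(seed),
         n_select = as.integer(n_select),
         f_method = f_method, correlation_mode = correlation_mode,
         psd_penalty = isTRUE(psd_penalty)),
    class = "g3cs_config")
}

#' Gene score table
#'
#' Pairs gene identifiers with nonnegative importance scores and the
#' descending-score ranking (ties broken toward the smaller index).
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param scores Nonnegative numeric vector, same length.
#' @return A `data.frame` of class `gene_score_table` with columns
#'   `gene_id`, `score`, `rank`, ordered by rank.
#' @export
gene_score_table <- function(gene_ids, scores) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != length(scores))
    stop("gene_ids and scores differ in length", call. = FALSE)
  if (any(!nzchar(gene_ids)))
    stop("empty-string gene_id not allowed", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  if (any(scores < 0))
    stop("scores must be nonnegative", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  rank <- integer(length(scores))
  rank[ord] <- seq_along(scores)
  out <- data.frame(gene_id = gene_ids[ord], score = scores[ord],
                    rank = seq_along(scores),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Write gene scores to delimited text
#'
#' Writes columns `gene_id`, `score`, `rank` in rank order with enough
#' precision (15 significant digits) to round-trip through
#' [read_scores()].
#'
#' @param table A [gene_score_table()].
#' @param path Output path.
#' @export
write_scores <- function(table, path) {
  if (!inherits(table, "gene_score_table"))
    stop("table must be a gene_score_table", call. = FALSE)
  out <- table
  out$score <- format(out$score, digits = 15, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene scores written by [write_scores()]
#'
#' @param path Path to a score TSV.
#' @return A [gene_score_table()].
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_score_table(df$gene_id, df$score)
}
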