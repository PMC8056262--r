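#' Build an expression matrix container
#'
#' A genes x samples matrix of normalized expression with a scale flag
#' recording whether values are on the linear or log2 scale. Upstream
#' platform normalization and batch correction are assumed done; this
#' stage consumes an already-normalized matrix.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param genes,samples Optional dimension names (taken from `values` if
#'   already set).
#' @param scale `"linear"` or `"log2"`.
#' @return The matrix with dimnames and a `scale_flag` attribute.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values),
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (anyNA(values)) stop_fmt("expression matrix contains missing values")
  if (is.null(genes) || is.null(samples)) {
    stop_fmt("gene and sample names are required")
  }
  if (length(genes) != nrow(values) || length(samples) != ncol(values)) {
    stop_fmt("dimension names do not match matrix dimensions")
  }
  dimnames(values) <- list(genes, samples)
  attr(values, "scale_flag") <- scale
  values
}

#' Read an expression matrix from CSV/TSV
#'
#' Genes as rows (first column holds gene symbols), samples as columns.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` vs tab otherwise).
#' @param scale Scale of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  expression_matrix(values, genes = genes, samples = colnames(values),
                    scale = scale)
}

expr_scale <- function(mat) attr(mat, "scale_flag") %||% "linear"

#' Log2-transform an expression matrix
#'
#' `value <- log2(value + pseudocount)`, applied once: transforming an
#' already log2-scale matrix is an error, as is negative input.
#'
#' @param mat An [expression_matrix()] on the linear scale.
#' @param pseudocount Added before the log (default 1, so zeros map to 0).
#' @return The transformed matrix with `scale_flag = "log2"`.
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  if (expr_scale(mat) == "log2") {
    stop_fmt("matrix is already log2-transformed")
  }
  if (any(mat < 0)) stop_fmt("negative expression values")
  out <- log2(mat + pseudocount)
  attr(out, "scale_flag") <- "log2"
  out
}

#' PCA followed by Ward hierarchical clustering of samples
#'
#' Samples are projected onto the top principal components of the
#' gene-wise-centered log2 matrix and clustered by Ward agglomeration
#' (`ward.D2`) on Euclidean distances between PC coordinates; the tree is
#' cut at `k` clusters. Cluster labels are renumbered by ascending mean
#' total expression, so cluster `k` is always the high-signature group
#' and the labeling is deterministic.
#'
#' @param mat Log2-scale [expression_matrix()].
#' @param n_pcs Number of PC coordinates to cluster on; default is the
#'   smallest number explaining 80% of the variance.
#' @param k Number of clusters (>= 2).
#' @return Object of class `cluster_assignment`: list with `labels`
#'   (named integer vector, one per sample), `k`, `n_pcs`,
#'   `linkage_method` (`"ward.D2"`), `variance_explained`, and the
#'   underlying `hclust` tree and PC `scores`.
#' @export
pca_cluster <- function(mat, n_pcs = NULL, k = 3L) {
  if (expr_scale(mat) != "log2") {
    stop_fmt("pca_cluster expects a log2-scale matrix")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 2L) {
    stop_fmt("k must be an integer >= 2")
  }
  if (k > ncol(mat)) stop_fmt("k = %d exceeds the %d samples", k,
                              ncol(mat))
  pr <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  if (is.null(n_pcs)) {
    n_pcs <- which(cumsum(ve) >= 0.8)[1]
  }
  n_pcs <- min(n_pcs, ncol(pr$x))
  if (n_pcs < 1L) stop_fmt("n_pcs must be >= 1")
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # deterministic labels: rank clusters by mean total expression
  totals <- colSums(mat)
  means <- tapply(totals, raw, mean)
  new_label <- rank(means, ties.method = "first")
  labels <- stats::setNames(as.integer(new_label[as.character(raw)]),
                            colnames(mat))
  structure(list(labels = labels, k = as.integer(k),
                 n_pcs = as.integer(n_pcs),
                 linkage_method = "ward.D2",
                 variance_explained = ve[seq_len(n_pcs)],
                 hclust = hc, scores = scores),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "Ward clustering of %d samples on %d PC coordinates, k = %d\n",
    length(x$labels), x$n_pcs, x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

# vectorised Welch two-sample t-test per gene row, target vs rest
welch_rows <- function(mat, in_target) {
  xa <- mat[, in_target, drop = FALSE]
  xb <- mat[, !in_target, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  # constant rows give 0/0; no evidence of difference
  degenerate <- !is.finite(t_stat)
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(gene = rownames(mat), mean_target = ma, mean_rest = mb,
             t = t_stat, df = df, p = p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select marker genes of a target cluster
#'
#' One-vs-rest test of the target cluster against all other samples, one
#' gene at a time; genes significant at `alpha` with a higher mean in the
#' target cluster are returned. The default test is Welch's
#' unequal-variance t-test (robust to unequal cluster sizes); a
#' Kruskal-Wallis rank alternative is available.
#'
#' @param mat Log2-scale [expression_matrix()].
#' @param clusters A [pca_cluster()] result (or named integer vector of
#'   labels).
#' @param target Cluster label whose markers are sought.
#' @param alpha Significance threshold (default 1e-4).
#' @param method `"welch"` (default) or `"kruskal"`.
#' @return Data frame of selected genes (`gene`, `mean_target`,
#'   `mean_rest`, statistic, `p`), sorted by p. Zero rows when nothing
#'   passes.
#' @export
select_markers <- function(mat, clusters, target, alpha = 1e-4,
                           method = c("welch", "kruskal")) {
  method <- match.arg(method)
  labels <- if (inherits(clusters, "cluster_assignment"))
    clusters$labels else clusters
  labels <- labels[colnames(mat)]
  if (anyNA(labels)) stop_fmt("cluster labels missing for some samples")
  in_target <- labels == target
  if (sum(in_target) < 2L) {
    stop_fmt("target cluster %s has fewer than 2 samples", target)
  }
  if (sum(!in_target) < 2L) {
    stop_fmt("fewer than 2 samples outside the target cluster")
  }
  if (method == "welch") {
    res <- welch_rows(mat, in_target)
  } else {
    p <- apply(mat, 1, function(row) {
      stats::kruskal.test(row, factor(in_target))$p.value
    })
    res <- data.frame(gene = rownames(mat),
                      mean_target = rowMeans(mat[, in_target, drop = FALSE]),
                      mean_rest = rowMeans(mat[, !in_target, drop = FALSE]),
                      t = NA_real_, df = NA_real_, p = p,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  keep <- res$p < alpha & res$mean_target > res$mean_rest
  out <- res[keep, , drop = FALSE]
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median-based modified z-scores
#'
#' Per gene row, \eqn{z = 0.6745 (x - \tilde x) / MAD} where
#' \eqn{\tilde x} is the row median and MAD the median absolute deviation
#' from it. Rows with zero MAD (more than half the values tied at the
#' median) fall back to mean-absolute-deviation scaling,
#' \eqn{z = (x - \tilde x) / (1.253314 \cdot meanAD)}; fully constant
#' rows are all zeros.
#'
#' @param mat Numeric matrix (typically log2 expression).
#' @return Matrix of modified z-scores, same dimensions.
#' @export
modified_z <- function(mat) {
  mat <- as.matrix(mat)
  t(apply(mat, 1, function(x) {
    med <- stats::median(x)
    dev <- x - med
    mad0 <- stats::median(abs(dev))
    if (mad0 > 0) return(0.6745 * dev / mad0)
    mean_ad <- mean(abs(dev))
    if (mean_ad > 0) return(dev / (1.253314 * mean_ad))
    rep(0, length(x))
  }))
}

#' Read a marker-set table (gene -> cell class)
#'
#' @param path TSV with columns `gene` and `class` (values such as
#'   `"T cell"`, `"microglia"`, `"macrophage"`, `"unassigned"`).
#' @return Named character vector mapping gene to class.
#' @export
read_marker_set <- function(path) {
  df <- read_tsv_plain(path)
  missing_cols <- setdiff(c("gene", "class"), names(df))
  if (length(missing_cols) > 0L) {
    stop_fmt("marker set %s is missing column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$gene)) stop_fmt("duplicate genes in %s", path)
  stats::setNames(as.character(df$class), df$gene)
}

#' Correlation between two cell-type expression signatures
#'
#' Each sample gets a signature score per gene set (unweighted mean log2
#' expression over the set's genes); Pearson correlation between the two
#' per-sample score vectors quantifies, e.g., whether T-cell and
#' microglia transcripts rise together across tissue samples.
#'
#' @param mat Log2-scale [expression_matrix()].
#' @param genes_a,genes_b Character vectors of gene symbols (genes absent
#'   from the matrix are dropped; a set with no genes present errors).
#' @return List with `r`, `p` (two-sided), `n`, and the per-sample score
#'   vectors `scores_a`, `scores_b`.
#' @export
signature_correlation <- function(mat, genes_a, genes_b) {
  genes_a <- intersect(genes_a, rownames(mat))
  genes_b <- intersect(genes_b, rownames(mat))
  if (length(genes_a) == 0L || length(genes_b) == 0L) {
    stop_fmt("a gene set has no genes present in the matrix")
  }
  scores_a <- colMeans(mat[genes_a, , drop = FALSE])
  scores_b <- colMeans(mat[genes_b, , drop = FALSE])
  ct <- stats::cor.test(scores_a, scores_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores_a),
       scores_a = scores_a, scores_b = scores_b)
}
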