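#' Transcripts-per-million normalisation
#'
#' Length-normalised expression: per sample, each gene's count is divided
#' by its length in kilobases to give a rate, and rates are scaled to sum
#' to one million. Columns of the result therefore sum to 1e6 and the
#' values are invariant to sequencing depth.
#'
#' @param x An `expression_set` ([generate_expression_matrix()]), or a
#'   numeric genes-by-samples matrix (then `gene_lengths` is required), or
#'   a data frame in the interchange layout (`gene`, `length_bp`, one
#'   column per sample).
#' @param gene_lengths Named numeric of lengths in bp (matrix input only).
#' @return Numeric matrix of TPM values, genes x samples.
#' @examples
#' counts_to_tpm(matrix(c(10, 20), 2, 1,
#'                      dimnames = list(c("a", "b"), "s1")),
#'               gene_lengths = c(a = 1000, b = 2000))
#' @export
counts_to_tpm <- function(x, gene_lengths = NULL) {
  m <- as_expr_matrix(x, gene_lengths)
  counts <- m$counts
  len_kb <- m$gene_lengths / 1000
  if (any(len_kb <= 0) || anyNA(len_kb)) abort("gene lengths must be positive")
  rates <- counts / len_kb
  totals <- colSums(rates)
  empty <- colnames(counts)[totals == 0]
  if (length(empty) > 0) {
    abort(paste0("sample(s) with all-zero counts: ", paste(empty, collapse = ", ")))
  }
  sweep(rates, 2, totals, "/") * 1e6
}

#' Gene-wise Z-score standardisation
#'
#' Standardises each gene's expression across samples to mean 0 and sample
#' SD 1, the transform used for clustering heatmaps. Genes with zero
#' variance across samples carry no ordering information and are dropped
#' with a message.
#'
#' @param tpm Numeric genes-by-samples matrix (TPM or any expression
#'   scale).
#' @return Standardised matrix; dropped gene names in attribute
#'   `dropped`.
#' @export
zscore_genes <- function(tpm) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (ncol(tpm) < 2) abort("zscore_genes needs at least 2 samples")
  sds <- apply(tpm, 1, sd)
  dropped <- rownames(tpm)[sds == 0]
  if (length(dropped) > 0) {
    inform(sprintf("dropping %d zero-variance gene(s)", length(dropped)))
  }
  keep <- sds > 0
  z <- (tpm[keep, , drop = FALSE] - rowMeans(tpm[keep, , drop = FALSE])) / sds[keep]
  attr(z, "dropped") <- dropped
  z
}

#' Pearson-distance hierarchical clustering
#'
#' Agglomerative clustering of samples (or genes) under the correlation
#' distance `d = 1 - Pearson r`, the metric used for expression heatmaps:
#' identical profiles are at distance 0, perfectly anti-correlated ones at
#' 2, and the distance is invariant to affine rescaling of any single
#' gene. When clustering samples, the genes entering the correlation are
#' restricted to the `top_n` most variable (by variance of log2(x + 1)),
#' which concentrates the signal on the regulated transcriptome;
#' `top_n = Inf` uses all genes.
#'
#' @param mat Numeric genes-by-samples matrix (Z-scores or TPM).
#' @param axis `"samples"` (cluster columns) or `"genes"` (cluster rows).
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"average"`.
#' @param top_n Most-variable-gene filter for sample clustering.
#'
#' @return A list of class `cluster_result`: `hclust` (the dendrogram),
#'   `cor_matrix` (pairwise Pearson r, unit diagonal), `dist_matrix`,
#'   `order` (leaf order), `axis`, `linkage`.
#' @export
correlation_cluster <- function(mat, axis = c("samples", "genes"),
                                linkage = "average", top_n = 500) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (axis == "samples" && is.finite(top_n) && nrow(mat) > top_n) {
    v <- apply(log2(pmax(mat, 0) + 1), 1, var)
    mat <- mat[order(v, decreasing = TRUE)[seq_len(top_n)], , drop = FALSE]
  }
  items <- if (axis == "samples") mat else t(mat)
  if (ncol(items) < 2) abort("need at least 2 items to cluster")
  sds <- apply(items, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance item(s), Pearson r undefined: ",
                 paste(colnames(items)[sds == 0], collapse = ", ")))
  }
  r <- cor(items)
  d <- as.dist(1 - r)
  hc <- hclust(d, method = linkage)
  structure(
    list(hclust = hc, cor_matrix = r, dist_matrix = 1 - r,
         order = hc$labels[hc$order], axis = axis, linkage = linkage),
    class = "cluster_result"
  )
}

#' @method print cluster_result
#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d %s, %s linkage, 1 - Pearson r distance\n",
              ncol(x$cor_matrix), x$axis, x$linkage))
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  r <- x$cor_matrix
  idx <- which(upper.tri(r), arr.ind = TRUE)
  tibble(
    item1 = rownames(r)[idx[, 1]],
    item2 = colnames(r)[idx[, 2]],
    pearson_r = r[idx],
    distance = 1 - r[idx]
  )
}

#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_items = ncol(x$cor_matrix), axis = x$axis, linkage = x$linkage,
         max_height = max(x$hclust$height))
}

#' Export a dendrogram as a newick string
#'
#' @param x A `cluster_result`.
#' @param file Optional path; when given the tree is written there.
#' @return The newick string, invisibly when writing to a file.
#' @export
cluster_newick <- function(x, file = NULL) {
  stopifnot(inherits(x, "cluster_result"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(file)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = file); invisible(ape::write.tree(phy)) }
}

#' Principal component analysis of samples
#'
#' PCA of samples on log2(TPM + 1), gene-centred and unscaled — the usual
#' first look at a small bulk design. Variance-explained fractions are
#' non-negative, non-increasing and sum to at most 1.
#'
#' @param tpm Numeric genes-by-samples matrix.
#' @param groups Optional named character vector `sample -> group`,
#'   carried into the scores table.
#' @param log_transform Apply `log2(x + 1)` first (default TRUE).
#' @return A list of class `pca_result`: `scores` (tibble `sample`,
#'   `group`, `PC1`, `PC2`, ...), `var_explained` (numeric), `prcomp`.
#' @export
pca_samples <- function(tpm, groups = NULL, log_transform = TRUE) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (ncol(tpm) < 2) abort("pca_samples needs at least 2 samples")
  x <- if (log_transform) log2(tpm + 1) else tpm
  fit <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x, rownames = "sample")
  scores$group <- if (is.null(groups)) NA_character_ else unname(groups[scores$sample])
  scores <- scores %>% select("sample", "group", dplyr::everything())
  structure(list(scores = scores, var_explained = ve, prcomp = fit),
            class = "pca_result")
}

#' @method print pca_result
#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * (x$var_explained[2] %+na% 0)))
  invisible(x)
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' Volcano statistics between two groups
#'
#' Per-gene effect and significance for a two-group contrast:
#' `log2FC = log2((mean TPM_b + eps) / (mean TPM_a + eps))` with a
#' pseudocount `eps = 1`, and a two-sided Welch t-test on log2(TPM + 1).
#' Genes constant in both groups have no defined test and get `NA`
#' p-values. Rows are sorted by p-value.
#'
#' @param tpm Numeric genes-by-samples matrix.
#' @param groups Named character vector `sample -> group`.
#' @param group_a,group_b The contrast; fold changes are b over a.
#' @param epsilon Pseudocount added to the group means, default 1.
#' @return A tibble of class `volcano_result`: `gene`, `mean_a`,
#'   `mean_b`, `log2_fc`, `p_value`.
#' @export
volcano_stats <- function(tpm, groups, group_a, group_b, epsilon = 1) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  sa <- intersect(sa, colnames(tpm)); sb <- intersect(sb, colnames(tpm))
  if (length(sa) < 2 || length(sb) < 2) {
    abort("each group needs at least 2 samples present in the matrix")
  }
  a <- tpm[, sa, drop = FALSE]
  b <- tpm[, sb, drop = FALSE]
  la <- log2(a + 1); lb <- log2(b + 1)
  p <- vapply(seq_len(nrow(tpm)), function(i) {
    if (sd(la[i, ]) == 0 && sd(lb[i, ]) == 0) return(NA_real_)
    t.test(lb[i, ], la[i, ])$p.value
  }, numeric(1))
  out <- tibble(
    gene = rownames(tpm),
    mean_a = unname(rowMeans(a)),
    mean_b = unname(rowMeans(b)),
    log2_fc = unname(log2((rowMeans(b) + epsilon) / (rowMeans(a) + epsilon))),
    p_value = p
  ) %>% arrange(.data$p_value)
  structure(out, contrast = c(a = group_a, b = group_b),
            class = c("volcano_result", class(out)))
}

#' @method tidy volcano_result
#' @export
tidy.volcano_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "volcano_result")
  out
}

#' @method glance volcano_result
#' @export
glance.volcano_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    contrast_a = attr(x, "contrast")[["a"]],
    contrast_b = attr(x, "contrast")[["b"]],
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE)
  )
}

as_expr_matrix <- function(x, gene_lengths = NULL) {
  if (inherits(x, "expression_set")) {
    list(counts = x$counts, gene_lengths = x$gene_lengths)
  } else if (is.matrix(x)) {
    if (is.null(gene_lengths)) abort("gene_lengths required with matrix input")
    list(counts = x, gene_lengths = gene_lengths[rownames(x)])
  } else if (is.data.frame(x)) {
    stopifnot(all(c("gene", "length_bp") %in% names(x)))
    m <- as.matrix(x[, setdiff(names(x), c("gene", "length_bp")), drop = FALSE])
    rownames(m) <- x$gene
    list(counts = m, gene_lengths = setNames(x$length_bp, x$gene))
  } else {
    abort("unsupported expression input")
  }
}
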