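# Sample-level global structure: hierarchical clustering, PCA embedding
# and the developmental-axis linearity statistic.

#' Hierarchically cluster samples
#'
#' Agglomerative clustering of samples under correlation or Euclidean
#' distance. Samples are ordered lexicographically before clustering so
#' the tree is deterministic and tie merges resolve by sample name.
#'
#' @param x ExpressionMatrix.
#' @param distance `"pearson"` (distance `1 - r`, default) or
#'   `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return object of class `Dendrogram`: the underlying `hclust` plus the
#'   distance/linkage used.
#' @export
cluster_samples <- function(x, distance = c("pearson", "euclidean"),
                            linkage = c("average", "complete")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (ncol(x$values) < 2L) stop("need at least 2 samples")
  v <- x$values[, order(colnames(x$values)), drop = FALSE]
  if (distance == "pearson") {
    sds <- apply(v, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant-expression sample(s) under correlation distance: ",
           paste(colnames(v)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(v))
  } else {
    d <- stats::dist(t(v))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, distance = distance, linkage = linkage),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram over %d samples (%s distance, %s linkage)\n",
              length(x$hclust$labels), x$distance, x$linkage))
  invisible(x)
}

#' Leaf labels of each subtree cut at k clusters
#'
#' @param dend Dendrogram.
#' @param k number of clusters.
#' @return list of character vectors of sample names per cluster.
#' @export
cut_dendrogram <- function(dend, k) {
  cl <- stats::cutree(dend$hclust, k = k)
  unname(split(names(cl), cl))
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences, so root-to-leaf path
#' lengths reproduce merge heights.
#'
#' @param dend Dendrogram.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' PCA embedding of samples
#'
#' Samples are embedded by principal components of the gene-centered
#' matrix, by default restricted to the most variable genes to stabilise
#' small-sample embeddings. Sign convention: each component's
#' largest-magnitude gene loading is positive.
#'
#' @param x ExpressionMatrix.
#' @param n_components number of components, `>= 2` and at most the
#'   matrix rank.
#' @param n_top_genes use only this many most-variable genes
#'   (`Inf` = all), default 2000.
#' @return object of class `PcaEmbedding`: sample `scores`, gene
#'   `loadings`, `explained` variance fractions, and `centroids` of each
#'   group on (PC1, PC2).
#' @export
pca_embed <- function(x, n_components = 2, n_top_genes = 2000) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (n_components < 2L) stop("`n_components` must be >= 2")
  if (ncol(x$values) < n_components)
    stop("more components than samples")
  v <- x$values
  if (is.finite(n_top_genes) && n_top_genes < nrow(v)) {
    vars <- apply(v, 1L, stats::var)
    keep <- order(-vars, rownames(v))[seq_len(n_top_genes)]
    v <- v[keep, , drop = FALSE]
  }
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  rank <- ncol(pc$x)
  if (n_components > rank)
    stop("`n_components` (", n_components, ") exceeds rank (", rank, ")")
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {     # sign convention
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  groups <- x$sample_groups[rownames(scores)]
  centroids <- t(vapply(x$group_levels, function(g)
    colMeans(scores[groups == g, 1:2, drop = FALSE]), numeric(2L)))
  colnames(centroids) <- c("PC1", "PC2")
  structure(list(scores = scores, loadings = loadings,
                 explained = explained[seq_len(n_components)],
                 centroids = centroids, center = pc$center),
            class = "PcaEmbedding")
}

#' @export
print.PcaEmbedding <- function(x, ...) {
  cat(sprintf("PcaEmbedding: %d samples x %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained[1L], 100 * x$explained[2L]))
  invisible(x)
}

#' Linearity of the developmental axis
#'
#' Pearson correlation between the PC1 and PC2 coordinates of three
#' group centroids: `|r| = 1` exactly when the centroids are collinear
#' (and neither axis is degenerate). This quantifies how closely the
#' three cardiomyocyte stages fall on a straight developmental axis in
#' the PCA plane.
#'
#' @param embedding PcaEmbedding (or any object with a `centroids`
#'   matrix).
#' @param ordered_groups exactly 3 group labels with centroids.
#' @return Pearson r in `[-1, 1]`.
#' @export
developmental_axis_linearity <- function(embedding, ordered_groups) {
  if (length(ordered_groups) != 3L) stop("exactly 3 groups required")
  cen <- embedding$centroids
  missing <- setdiff(ordered_groups, rownames(cen))
  if (length(missing)) stop("no centroid for group(s): ",
                            paste(missing, collapse = ", "))
  pts <- cen[ordered_groups, , drop = FALSE]
  if (anyDuplicated(pts)) stop("two group centroids coincide")
  if (stats::sd(pts[, 1L]) == 0 || stats::sd(pts[, 2L]) == 0)
    stop("zero variance on a principal-component axis across centroids")
  stats::cor(pts[, 1L], pts[, 2L])
}

#' Write a PCA embedding as TSV
#' @param embedding PcaEmbedding.
#' @param path output file.
#' @export
write_embedding_tsv <- function(embedding, path) {
  df <- data.frame(sample = rownames(embedding$scores),
                   signif(embedding$scores, 6L), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
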