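#' Expression matrix container
#'
#' Bundles a genes/probes-by-samples matrix of log2 abundances with the
#' sample-to-group assignment and, optionally, a matching matrix of
#' detection p-values (as produced by bead-array scanners). Group order is
#' preserved from the order of first appearance in `sample_groups` and is
#' treated as the developmental order throughout the package.
#'
#' @param values numeric matrix, rows = gene or probe identifiers,
#'   columns = sample names; both dimnames mandatory and unique.
#' @param sample_groups named character vector mapping every sample
#'   (column) to a group label.
#' @param detection_p optional numeric matrix in `[0, 1]`, same shape and
#'   dimnames as `values`.
#' @param id_space `"gene"` or `"probe"`; what the row identifiers are.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `sample_groups`, `detection_p`, `id_space`,
#'   `group_levels`.
#' @export
expression_matrix <- function(values, sample_groups, detection_p = NULL,
                              id_space = c("gene", "probe")) {
  id_space <- match.arg(id_space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("`values` must carry row and column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row identifier(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample name(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  missing_grp <- setdiff(colnames(values), names(sample_groups))
  if (length(missing_grp))
    stop("sample(s) without a group mapping: ",
         paste(missing_grp, collapse = ", "))
  sample_groups <- sample_groups[colnames(values)]
  if (anyNA(sample_groups)) stop("NA group label")
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values)))
      stop("`detection_p` must have the same shape as `values`")
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
      stop("`detection_p` values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(
    list(values = values,
         sample_groups = sample_groups,
         detection_p = detection_p,
         id_space = id_space,
         group_levels = unique(unname(sample_groups))),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %ss x %d samples (%s)\n",
              nrow(x$values), x$id_space, ncol(x$values),
              paste(x$group_levels, collapse = ", ")))
  if (!is.null(x$detection_p)) cat("  with detection p-values\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene and/or sample
#'
#' @param x ExpressionMatrix.
#' @param genes,samples character vectors of row/column names to keep
#'   (default: keep all).
#' @return ExpressionMatrix restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- if (is.null(genes)) rownames(x$values) else genes
  samples <- if (is.null(samples)) colnames(x$values) else samples
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  v <- x$values[genes, samples, drop = FALSE]
  d <- if (is.null(x$detection_p)) NULL else
    x$detection_p[genes, samples, drop = FALSE]
  out <- expression_matrix(v, x$sample_groups[samples], d, x$id_space)
  out$group_levels <- intersect(x$group_levels, out$group_levels)
  out
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample names and a first column of gene/probe
#' identifiers. Every sample must be covered by `group_map`; ragged rows,
#' duplicated identifiers and unmapped samples are rejected.
#'
#' @param path TSV file path.
#' @param group_map named character vector, sample -> group label.
#' @param id_space `"gene"` or `"probe"`.
#' @param detection_p_path optional TSV of identically shaped detection
#'   p-values.
#' @return ExpressionMatrix.
#' @export
read_expression_matrix <- function(path, group_map, id_space = "gene",
                                   detection_p_path = NULL) {
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1)
    stop("ragged TSV: rows have differing field counts in ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  dp <- NULL
  if (!is.null(detection_p_path)) {
    dtab <- utils::read.delim(detection_p_path, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
    dp <- as.matrix(dtab[, -1L, drop = FALSE])
    storage.mode(dp) <- "double"
    rownames(dp) <- as.character(dtab[[1L]])
    dp <- dp[rownames(m), colnames(m), drop = FALSE]
  }
  expression_matrix(m, group_map, detection_p = dp, id_space = id_space)
}

#' Write an expression matrix as TSV
#'
#' Numeric values are written with 6 significant digits by default;
#' `digits = NULL` writes full (`%.17g`) precision so the file
#' round-trips bit-exactly, as used for fixture bundles.
#'
#' @param x ExpressionMatrix or a plain numeric matrix with dimnames.
#' @param path output file.
#' @param id_col header of the identifier column.
#' @param digits significant digits, or `NULL` for full precision.
#' @export
write_expression_tsv <- function(x, path, id_col = "gene", digits = 6L) {
  m <- if (inherits(x, "ExpressionMatrix")) x$values else x
  fm <- if (is.null(digits))
    matrix(sprintf("%.17g", m), nrow = nrow(m), ncol = ncol(m),
           dimnames = dimnames(m))
  else signif(m, digits)
  ids <- rownames(m)
  if (is.null(ids)) ids <- character(0)
  colnames(fm) <- colnames(m)
  df <- data.frame(id = ids,
                   fm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a linear-scale matrix
#'
#' `value' = log2(value + offset)`; monotone and order preserving. Only
#' meaningful on non-negative linear-scale input.
#'
#' @param x ExpressionMatrix (linear scale).
#' @param offset positive stabilising offset, default 1.
#' @return ExpressionMatrix on the log2 scale.
#' @export
log2_transform <- function(x, offset = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (offset <= 0) stop("`offset` must be positive")
  if (any(x$values < 0)) stop("negative input values: already log scale?")
  x$values <- log2(x$values + offset)
  x
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) onto the common distribution given by the
#' row-wise mean of the sorted columns; ties within a column receive the
#' mean of their quantile values. At least two samples required.
#'
#' @param x ExpressionMatrix.
#' @return ExpressionMatrix with identical per-sample distributions.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2L)
    stop("quantile normalization needs at least 2 samples")
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  x$values <- v
  x
}

#' Collapse probes to genes
#'
#' Many-to-one probe-to-gene collapse. Under `max_mean` the probe with the
#' highest mean abundance across samples represents the gene (detection
#' p-values, if present, follow the chosen probe); under `mean` all probe
#' rows of a gene are averaged (detection p-values averaged likewise).
#'
#' @param x ExpressionMatrix with `id_space = "probe"`.
#' @param probe_map named character vector, probe -> gene symbol.
#' @param rule `"max_mean"` (default) or `"mean"`.
#' @return ExpressionMatrix with `id_space = "gene"`, one row per gene,
#'   rows in lexicographic gene order.
#' @export
collapse_probes <- function(x, probe_map, rule = c("max_mean", "mean")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  rule <- match.arg(rule)
  if (x$id_space != "probe")
    stop("collapse_probes expects a probe-space matrix")
  probes <- rownames(x$values)
  missing <- setdiff(probes, names(probe_map))
  if (length(missing))
    stop("probe(s) absent from probe_map: ", paste(missing, collapse = ", "))
  genes <- unname(probe_map[probes])
  out_genes <- sort(unique(genes))
  pick <- lapply(out_genes, function(g) probes[genes == g])
  if (rule == "max_mean") {
    chosen <- vapply(pick, function(p) {
      mu <- rowMeans(x$values[p, , drop = FALSE])
      p[order(-mu, p)][1L]   # deterministic: mean desc, then probe id
    }, character(1L))
    v <- x$values[chosen, , drop = FALSE]
    d <- if (is.null(x$detection_p)) NULL else
      x$detection_p[chosen, , drop = FALSE]
  } else {
    v <- t(vapply(pick, function(p)
      colMeans(x$values[p, , drop = FALSE]), numeric(ncol(x$values))))
    d <- if (is.null(x$detection_p)) NULL else
      t(vapply(pick, function(p)
        colMeans(x$detection_p[p, , drop = FALSE]), numeric(ncol(x$values))))
  }
  rownames(v) <- out_genes
  if (!is.null(d)) rownames(d) <- out_genes
  colnames(v) <- colnames(x$values)
  out <- expression_matrix(v, x$sample_groups, d, id_space = "gene")
  out$group_levels <- x$group_levels
  out
}

#' Presence call for one gene in one group
#'
#' A gene is called present in a group when its detection p-value falls
#' below `alpha` in a strict majority of that group's replicates.
#'
#' @param x ExpressionMatrix with detection p-values.
#' @param gene gene identifier.
#' @param group group label.
#' @param alpha detection p-value cutoff, default 0.01.
#' @return logical: `TRUE` = present.
#' @export
presence_call <- function(x, gene, group, alpha = 0.01) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$detection_p)) stop("no detection p-values available")
  if (!gene %in% rownames(x$values)) stop("unknown gene: ", gene)
  if (!group %in% x$group_levels) stop("unknown group: ", group)
  idx <- x$sample_groups == group
  p <- x$detection_p[gene, idx]
  sum(p < alpha) > length(p) / 2
}

#' Presence category of a gene across two groups
#'
#' @inheritParams presence_call
#' @param group_a,group_b the two groups to compare.
#' @return one of `"both"`, `"A_only"`, `"B_only"`, `"neither"`.
#' @export
presence_category <- function(x, gene, group_a, group_b, alpha = 0.01) {
  a <- presence_call(x, gene, group_a, alpha)
  b <- presence_call(x, gene, group_b, alpha)
  if (a && b) "both" else if (a) "A_only" else if (b) "B_only" else "neither"
}

#' Groups a gene is present in
#'
#' @inheritParams presence_call
#' @return character vector of group labels in which the gene is present.
#' @export
present_groups <- function(x, gene, alpha = 0.01) {
  x$group_levels[vapply(x$group_levels, function(g)
    presence_call(x, gene, g, alpha), logical(1L))]
}
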