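# Top-abundance ranking, three-way Venn partition, tissue-specificity
# filtering and marker classification.

#' Top-n most abundant genes in a group
#'
#' Ranks genes by group-mean abundance, descending; boundary ties break
#' lexicographically by gene symbol so the list is deterministic.
#'
#' @param x ExpressionMatrix.
#' @param group group label.
#' @param n list length (default 200), `0 < n <=` gene count.
#' @return ordered character vector of gene symbols.
#' @export
top_n_abundant <- function(x, group, n = 200) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!group %in% x$group_levels) stop("unknown group: ", group)
  if (n <= 0) stop("`n` must be positive")
  if (n > nrow(x$values)) stop("`n` exceeds gene count")
  mu <- rowMeans(x$values[, x$sample_groups == group, drop = FALSE])
  rownames(x$values)[order(-mu, rownames(x$values))][seq_len(n)]
}

#' Three-way Venn partition
#'
#' The 7 disjoint membership regions of three gene sets.
#'
#' @param set_a,set_b,set_c character vectors (duplicates ignored).
#' @return `VennPartition`: named list of the regions `A_only`,
#'   `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC` (each a sorted
#'   character vector).
#' @export
venn_partition <- function(set_a, set_b, set_c) {
  set_a <- unique(set_a); set_b <- unique(set_b); set_c <- unique(set_c)
  u <- union(union(set_a, set_b), set_c)
  ina <- u %in% set_a; inb <- u %in% set_b; inc_ <- u %in% set_c
  region <- function(a, b, c)
    sort(u[ina == a & inb == b & inc_ == c])
  structure(list(A_only = region(TRUE, FALSE, FALSE),
                 B_only = region(FALSE, TRUE, FALSE),
                 C_only = region(FALSE, FALSE, TRUE),
                 AB = region(TRUE, TRUE, FALSE),
                 AC = region(TRUE, FALSE, TRUE),
                 BC = region(FALSE, TRUE, TRUE),
                 ABC = region(TRUE, TRUE, TRUE)),
            class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  sizes <- vapply(x, length, integer(1L))
  cat("VennPartition:", paste(names(sizes), sizes, sep = "=",
                              collapse = " "), "\n")
  invisible(x)
}

#' Tissue-specificity enrichment ratio
#'
#' Mean expression over the designated target tissues divided by the
#' median over the remaining tissues. An all-zero non-target median
#' yields `Inf` (flagged by a warning) rather than an error.
#'
#' @param gene gene symbol present in the reference.
#' @param ref [tissue_reference()] table.
#' @return non-negative ratio (possibly `Inf`).
#' @export
tissue_specificity <- function(gene, ref) {
  stopifnot(inherits(ref, "TissueReference"))
  if (!gene %in% rownames(ref$values)) stop("gene not in reference: ", gene)
  v <- ref$values[gene, ]
  tgt <- mean(v[ref$target_tissues])
  rest <- stats::median(v[setdiff(colnames(ref$values), ref$target_tissues)])
  if (rest == 0) {
    warning("all-zero non-target expression for ", gene,
            "; ratio reported as Inf")
    return(Inf)
  }
  tgt / rest
}

#' Classify cardiac identity and maturation-depleted markers
#'
#' Identity markers: genes inside the top-`n` abundance list of all
#' three cardiomyocyte groups whose tissue-specificity ratio exceeds
#' `specificity_cut`. Depleted markers: cardiac-specific genes in the
#' union of the top-`n` lists whose fold change from the first
#' (stem-cell-derived) group to the fetal and/or adult group exceeds
#' `depletion_cut`.
#'
#' @param x ExpressionMatrix (log2 scale).
#' @param ref TissueReference.
#' @param groups exactly 3 cardiomyocyte group labels in developmental
#'   order (derived, fetal, adult).
#' @param n top-list length per group, default 200.
#' @param specificity_cut strict tissue-specificity bound, default 10.
#' @param depletion_cut strict fold-change bound, default 10.
#' @return `MarkerReport`: list with `identity_markers`,
#'   `depleted_markers`, `venn` (the top-list partition), and a
#'   per-candidate `table` of specificity ratios and fold changes.
#' @export
classify_markers <- function(x, ref, groups, n = 200,
                             specificity_cut = 10, depletion_cut = 10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (length(groups) != 3L) stop("exactly 3 cardiomyocyte groups required")
  missing <- setdiff(groups, x$group_levels)
  if (length(missing)) stop("missing group(s): ",
                            paste(missing, collapse = ", "))
  tops <- lapply(groups, function(g) top_n_abundant(x, g, n))
  names(tops) <- groups
  venn <- venn_partition(tops[[1L]], tops[[2L]], tops[[3L]])
  union_top <- sort(unique(unlist(tops)))
  in_ref <- union_top[union_top %in% rownames(ref$values)]
  spec <- vapply(in_ref, tissue_specificity, numeric(1L), ref = ref)
  cardiac <- in_ref[spec > specificity_cut]

  in_all <- Reduce(intersect, tops)
  identity_markers <- sort(intersect(in_all, cardiac))

  fc_f <- vapply(cardiac, fold_change, numeric(1L), x = x,
                 group_a = groups[1L], group_b = groups[2L])
  fc_a <- vapply(cardiac, fold_change, numeric(1L), x = x,
                 group_a = groups[1L], group_b = groups[3L])
  depleted_markers <- sort(cardiac[fc_f > depletion_cut |
                                   fc_a > depletion_cut])
  tab <- data.frame(gene = cardiac,
                    specificity = unname(spec[cardiac]),
                    fc_fetal = unname(fc_f), fc_adult = unname(fc_a),
                    identity = cardiac %in% identity_markers,
                    depleted = cardiac %in% depleted_markers,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(identity_markers = identity_markers,
                 depleted_markers = depleted_markers,
                 venn = venn, table = tab, groups = groups,
                 n = n, specificity_cut = specificity_cut,
                 depletion_cut = depletion_cut),
            class = "MarkerReport")
}

#' @export
print.MarkerReport <- function(x, ...) {
  cat(sprintf("MarkerReport: %d identity marker(s), %d depleted marker(s) (top %d per group)\n",
              length(x$identity_markers), length(x$depleted_markers), x$n))
  invisible(x)
}

#' Write a marker report (TSV table + JSON summary)
#' @param report MarkerReport.
#' @param tsv_path,json_path output files.
#' @export
write_marker_report <- function(report, tsv_path, json_path) {
  tab <- report$table
  for (col in c("specificity", "fc_fetal", "fc_adult"))
    tab[[col]] <- signif(tab[[col]], 6L)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(identity_markers = report$identity_markers,
         depleted_markers = report$depleted_markers,
         venn_sizes = lapply(report$venn, length),
         groups = report$groups, n = report$n,
         specificity_cut = report$specificity_cut,
         depletion_cut = report$depletion_cut),
    json_path, auto_unbox = FALSE, digits = NA)
  invisible(c(tsv_path, json_path))
}

#' Export Venn regions as a GMT collection
#' @param venn VennPartition.
#' @param path output GMT file.
#' @export
write_venn_gmt <- function(venn, path) {
  write_gmt(unclass(venn), path,
            descriptions = rep("venn_region", length(venn)))
}
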