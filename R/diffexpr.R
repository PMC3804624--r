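# Two-group fold-change and significance screen over log2 expression.

group_values <- function(x, gene, group) {
  if (!gene %in% rownames(x$values)) stop("unknown gene: ", gene)
  if (!group %in% x$group_levels) stop("unknown group: ", group)
  v <- x$values[gene, x$sample_groups == group]
  if (!length(v)) stop("empty group: ", group)
  v
}

#' Linear fold change between two groups
#'
#' `2 ^ (mean log2 in B - mean log2 in A)`; symmetric, so
#' `fold_change(A, B) = 1 / fold_change(B, A)`.
#'
#' @param x ExpressionMatrix (log2 scale).
#' @param gene gene identifier.
#' @param group_a,group_b reference and comparison groups.
#' @return positive linear fold change (B relative to A).
#' @export
fold_change <- function(x, gene, group_a, group_b) {
  a <- group_values(x, gene, group_a)
  b <- group_values(x, gene, group_b)
  2^(mean(b) - mean(a))
}

#' Welch's unequal-variance t-test for one gene
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom. When
#' both groups have zero variance and equal means the statistic is
#' undefined; by convention `t = 0, p = 1` is returned (and `t`
#' infinite, `p = 0` when such constant groups differ).
#'
#' @inheritParams fold_change
#' @return list with elements `t`, `p`, `df`.
#' @export
welch_test <- function(x, gene, group_a, group_b) {
  a <- group_values(x, gene, group_a)
  b <- group_values(x, gene, group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 replicates per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(b) - mean(a)) * Inf, p = 0, df = NA_real_))
  }
  ht <- stats::t.test(b, a, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control; `q >= p` elementwise after the
#' monotonicity enforcement, `q <= 1`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full two-group differential screen
#'
#' Per gene: linear fold change (B over A), Welch t and p, BH q,
#' direction at the fold threshold, and the presence category from
#' detection p-values when available.
#'
#' @param x ExpressionMatrix (log2 scale).
#' @param group_a,group_b reference and comparison groups.
#' @param fc_threshold strict linear fold-change bound for calling
#'   direction, default 2.
#' @param p_threshold strict p-value bound, default 0.05.
#' @param alpha detection-p cutoff for presence categories.
#' @return `DiffResult` data.frame with columns gene, fc, t, p, q,
#'   direction, presence.
#' @export
diff_table <- function(x, group_a, group_b, fc_threshold = 2,
                       p_threshold = 0.05, alpha = 0.01) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- rownames(x$values)
  ia <- x$sample_groups == group_a
  ib <- x$sample_groups == group_b
  if (!any(ia)) stop("empty group: ", group_a)
  if (!any(ib)) stop("empty group: ", group_b)
  fc <- 2^(rowMeans(x$values[, ib, drop = FALSE]) -
           rowMeans(x$values[, ia, drop = FALSE]))
  wt <- lapply(genes, function(g) welch_test(x, g, group_a, group_b))
  t_stat <- vapply(wt, `[[`, numeric(1L), "t")
  p <- vapply(wt, `[[`, numeric(1L), "p")
  q <- bh_adjust(p)
  direction <- ifelse(fc > fc_threshold & p < p_threshold, "up",
               ifelse(fc < 1 / fc_threshold & p < p_threshold, "down",
                      "unchanged"))
  presence <- if (is.null(x$detection_p)) rep("both", length(genes)) else
    vapply(genes, function(g)
      presence_category(x, g, group_a, group_b, alpha), character(1L))
  out <- data.frame(gene = genes, fc = fc, t = t_stat, p = p, q = q,
                    direction = direction, presence = unname(presence),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groups") <- c(A = group_a, B = group_b)
  class(out) <- c("DiffResult", "data.frame")
  out
}

#' Count regulated genes
#'
#' Strict thresholds, matching a "more than k-fold, p below alpha"
#' screen: up means `fc > fc_threshold`, down means
#' `fc < 1/fc_threshold`, both require `p < p_threshold`.
#'
#' @param diff a `DiffResult` from [diff_table()].
#' @param fc_threshold,p_threshold strict bounds (defaults 2, 0.05).
#' @return list with `n_up`, `n_down`, `fraction_up`, `fraction_down`
#'   (fractions of the gene universe).
#' @export
count_regulated <- function(diff, fc_threshold = 2, p_threshold = 0.05) {
  if (!nrow(diff)) stop("empty gene universe")
  up <- diff$fc > fc_threshold & diff$p < p_threshold
  down <- diff$fc < 1 / fc_threshold & diff$p < p_threshold
  list(n_up = sum(up), n_down = sum(down),
       fraction_up = sum(up) / nrow(diff),
       fraction_down = sum(down) / nrow(diff))
}

#' Write a differential-screen table as TSV
#' @param diff DiffResult.
#' @param path output file.
#' @export
write_diff_tsv <- function(diff, path) {
  out <- diff
  for (col in c("fc", "t", "p", "q")) out[[col]] <- signif(out[[col]], 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
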