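# Gene-set enrichment: weighted running-sum statistic with permutation
# FDR, plus a hypergeometric over-representation test.

#' Rank genes for enrichment analysis
#'
#' Scores every gene for group A versus group B and returns the list in
#' descending score order (ties broken by gene symbol). Metrics:
#' `signal2noise` = (meanA - meanB) / (sdA + sdB) with the denominator
#' floored at 1e-8 for zero-variance genes; `t_stat` = Welch t;
#' `log2fc` = difference of log2 group means.
#'
#' @param x ExpressionMatrix (log2 scale).
#' @param group_a,group_b groups to contrast (positive score = higher
#'   in A).
#' @param metric one of `"signal2noise"`, `"t_stat"`, `"log2fc"`.
#' @return data.frame (gene, score) in ranking order.
#' @export
rank_genes <- function(x, group_a, group_b,
                       metric = c("signal2noise", "t_stat", "log2fc")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  metric <- match.arg(metric)
  ia <- x$sample_groups == group_a
  ib <- x$sample_groups == group_b
  if (!any(ia) || !any(ib)) stop("empty group")
  va <- x$values[, ia, drop = FALSE]
  vb <- x$values[, ib, drop = FALSE]
  score <- switch(metric,
    signal2noise = {
      s <- apply(va, 1L, stats::sd) + apply(vb, 1L, stats::sd)
      s[s < 1e-8] <- 1e-8
      (rowMeans(va) - rowMeans(vb)) / s
    },
    t_stat = vapply(rownames(x$values), function(g)
      -welch_test(x, g, group_a, group_b)$t, numeric(1L)),
    log2fc = rowMeans(va) - rowMeans(vb))
  genes <- rownames(x$values)
  o <- order(-score, genes)
  data.frame(gene = genes[o], score = unname(score[o]),
             stringsAsFactors = FALSE)
}

# ES of a member-position set against weights; used for permutation
# nulls where only the extremum is needed.
es_from_positions <- function(idx, w_all, N) {
  idx <- sort(idx)
  Nh <- length(idx)
  if (Nh == N) return(1)
  w <- w_all[idx]
  sw <- sum(w)
  w <- if (sw == 0) rep(1 / Nh, Nh) else w / sw
  cumw <- cumsum(w)
  miss <- (idx - seq_len(Nh)) / (N - Nh)
  top <- cumw - miss                 # running sum just after each hit
  bottom <- c(0, cumw[-Nh]) - miss   # just before each hit
  hi <- max(top)
  lo <- min(bottom, cumw[Nh] - 1)    # tail decays to cumw[Nh] - 1 = 0
  if (hi >= -lo) hi else lo
}

#' Weighted running-sum enrichment score
#'
#' The running sum increases by `|score|^p / sum(|score|^p over members)`
#' at gene-set members and decreases by `1 / (N - Nh)` at non-members;
#' the enrichment score is the extremum of the running sum, so
#' `|ES| <= 1`. With the set equal to the whole list only increments
#' occur and `ES = 1`.
#'
#' @param ranked data.frame from [rank_genes()] (or any gene/score
#'   data.frame in ranking order).
#' @param gene_set character vector; must intersect the ranked list.
#' @param p weight exponent, default 1.
#' @return list with `es` and the full `running` sum vector.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  genes <- ranked$gene
  scores <- ranked$score
  member <- genes %in% gene_set
  N <- length(genes)
  Nh <- sum(member)
  if (Nh == 0L) stop("gene set is disjoint from the ranked list")
  w <- abs(scores)^p
  inc <- numeric(N)
  if (Nh == N) {
    sw <- sum(w)
    inc <- if (sw == 0) rep(1 / N, N) else w / sw
  } else {
    sw <- sum(w[member])
    inc[member] <- if (sw == 0) 1 / Nh else w[member] / sw
    inc[!member] <- -1 / (N - Nh)
  }
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Permutation-based enrichment over a gene-set collection
#'
#' Computes the observed enrichment score of every (size-filtered) set
#' against the A-vs-B ranking, a permutation null (`gene_set` mode:
#' random member positions of matching size; `phenotype` mode: group
#' labels permuted and the ranking recomputed), the normalized score
#' `NES = ES / mean(|null ES| of the same sign)`, the nominal p as the
#' same-sign null exceedance fraction, and the FDR as the ratio of
#' normalized null to observed exceedances (capped at 1).
#'
#' @param x ExpressionMatrix.
#' @param sets named list of gene sets.
#' @param group_a,group_b groups to contrast.
#' @param n_perm number of permutations, `>= 100`.
#' @param mode `"gene_set_permutation"` (default; preferred with few
#'   replicates) or `"phenotype_permutation"` (requires >= 3 replicates
#'   per group).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param metric ranking metric, see [rank_genes()].
#' @param p weight exponent, default 1.
#' @param min_size,max_size set-size window after restriction to
#'   measured genes (defaults 15 and 500).
#' @return `EnrichmentResult` data.frame (set, size, es, nes, p_nominal,
#'   fdr, direction) ordered by fdr; run metadata in attributes
#'   `seed`, `n_perm`, `mode`.
#' @export
permutation_fdr <- function(x, sets, group_a, group_b, n_perm = 1000,
                            mode = c("gene_set_permutation",
                                     "phenotype_permutation"),
                            seed = 1, metric = "signal2noise", p = 1,
                            min_size = 15, max_size = 500) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  mode <- match.arg(mode)
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (mode == "phenotype_permutation") {
    na <- sum(x$sample_groups == group_a)
    nb <- sum(x$sample_groups == group_b)
    if (min(na, nb) < 3L)
      stop("phenotype permutation needs >= 3 replicates per group; ",
           "use gene_set_permutation")
  }
  ranked <- rank_genes(x, group_a, group_b, metric)
  genes <- ranked$gene
  N <- length(genes)
  sets <- lapply(sets, function(s) intersect(s, genes))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene set within the size window")
  sets <- sets[keep]
  sizes <- sizes[keep]
  w_all <- abs(ranked$score)^p

  obs <- vapply(sets, function(s) enrichment_score(ranked, s, p)$es,
                numeric(1L))

  null_es <- with_seed(seed, {
    if (mode == "gene_set_permutation") {
      vapply(seq_along(sets), function(i) {
        vapply(seq_len(n_perm), function(.)
          es_from_positions(sample.int(N, sizes[i]), w_all, N),
          numeric(1L))
      }, numeric(n_perm))
    } else {
      labels <- x$sample_groups
      out <- matrix(NA_real_, nrow = n_perm, ncol = length(sets))
      xp <- x
      for (b in seq_len(n_perm)) {
        perm <- sample(unname(labels))
        xp$sample_groups <- stats::setNames(perm, names(labels))
        rp <- rank_genes(xp, group_a, group_b, metric)
        wp <- abs(rp$score)^p
        out[b, ] <- vapply(sets, function(s)
          es_from_positions(which(rp$gene %in% s), wp, N), numeric(1L))
      }
      out
    }
  })  # n_perm x n_sets

  mean_pos <- apply(null_es, 2L, function(v) mean(abs(v[v >= 0])))
  mean_neg <- apply(null_es, 2L, function(v) mean(abs(v[v < 0])))
  norm_of <- function(es, i) {
    if (es >= 0) es / mean_pos[i] else es / mean_neg[i]
  }
  nes <- vapply(seq_along(obs), function(i) norm_of(obs[i], i), numeric(1L))
  p_nom <- vapply(seq_along(obs), function(i) {
    v <- null_es[, i]
    same <- if (obs[i] >= 0) v[v >= 0] else v[v < 0]
    if (!length(same)) return(0)
    mean(abs(same) >= abs(obs[i]))
  }, numeric(1L))

  null_nes <- null_es
  for (i in seq_along(obs))
    null_nes[, i] <- ifelse(null_es[, i] >= 0,
                            null_es[, i] / mean_pos[i],
                            null_es[, i] / mean_neg[i])
  all_null <- as.vector(null_nes)
  fdr <- vapply(seq_along(obs), function(i) {
    s <- nes[i]
    if (s >= 0) {
      num_pool <- all_null[all_null >= 0]
      obs_pool <- nes[nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= s) else 0
      den <- mean(obs_pool >= s)
    } else {
      num_pool <- all_null[all_null < 0]
      obs_pool <- nes[nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= s) else 0
      den <- mean(obs_pool <= s)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1L))

  out <- data.frame(set = names(sets), size = as.integer(sizes),
                    es = unname(obs), nes = unname(nes),
                    p_nominal = unname(p_nom), fdr = unname(fdr),
                    direction = ifelse(obs >= 0, group_a, group_b),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$fdr, -abs(out$nes), out$set), ]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  attr(out, "mode") <- mode
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Write enrichment results (TSV + run-metadata JSON)
#' @param res EnrichmentResult.
#' @param tsv_path,json_path output files.
#' @export
write_enrichment <- function(res, tsv_path, json_path) {
  out <- as.data.frame(res)
  for (col in c("es", "nes", "p_nominal", "fdr"))
    out[[col]] <- signif(out[[col]], 6L)
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(seed = attr(res, "seed"),
                            n_perm = attr(res, "n_perm"),
                            mode = attr(res, "mode")),
                       json_path, auto_unbox = TRUE)
  invisible(c(tsv_path, json_path))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a region (e.g. a Venn region) and a gene set drawn from the
#' universe.
#'
#' @param region_genes,set_genes character vectors, both subsets of
#'   `universe`.
#' @param universe character vector of measured genes.
#' @return p-value `P(overlap >= observed)`.
#' @export
hypergeometric_test <- function(region_genes, set_genes, universe) {
  region_genes <- unique(region_genes)
  set_genes <- unique(set_genes)
  universe <- unique(universe)
  if (length(setdiff(region_genes, universe)))
    stop("region is not a subset of the universe")
  if (length(setdiff(set_genes, universe)))
    stop("gene set is not a subset of the universe")
  k <- length(intersect(region_genes, set_genes))
  stats::phyper(k - 1, length(set_genes),
                length(universe) - length(set_genes),
                length(region_genes), lower.tail = FALSE)
}
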