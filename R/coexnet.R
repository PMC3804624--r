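# Group-mean Pearson co-expression against a transcription-factor panel,
# core-cluster detection, joint-target counting and network assembly.

round_half_up <- function(x) floor(x + 0.5)

#' Per-group mean expression profiles
#'
#' Arithmetic mean of log2 values per group; columns follow the stored
#' developmental group order.
#'
#' @param x ExpressionMatrix.
#' @return gene x group numeric matrix.
#' @export
group_means <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  for (g in x$group_levels)
    if (!any(x$sample_groups == g)) stop("missing group: ", g)
  out <- matrix(NA_real_, nrow(x$values), length(x$group_levels),
                dimnames = list(rownames(x$values), x$group_levels))
  for (g in x$group_levels)
    out[, g] <- rowMeans(x$values[, x$sample_groups == g, drop = FALSE])
  out
}

#' Pearson correlation of two expression profiles
#'
#' @param profile_a,profile_b numeric vectors of equal length (here,
#'   4-point group-mean profiles); neither may be constant.
#' @return r in `[-1, 1]`.
#' @export
pcc <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) stop("length mismatch")
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0)
    stop("constant profile: correlation undefined")
  stats::cor(profile_a, profile_b)
}

#' Transcription-factor panel
#'
#' @param tfs ordered character vector of panel TF symbols (unique).
#' @param core character vector designating the core subset.
#' @return `TfPanel` list.
#' @export
tf_panel <- function(tfs, core = character(0)) {
  if (anyDuplicated(tfs)) stop("duplicate TF symbols")
  if (length(setdiff(core, tfs))) stop("core must be a subset of the panel")
  structure(list(tfs = tfs, core = core), class = "TfPanel")
}

#' Call co-expression edges against a TF panel
#'
#' An edge (tf, gene) is stored iff the Pearson correlation of their
#' group-mean profiles strictly exceeds `threshold` and `gene != tf`.
#' TF-TF edges are included (in both orientations). Constant-profile
#' TFs are dropped with a warning; constant-profile genes are excluded
#' from consideration with a message.
#'
#' @param gm gene x group mean matrix from [group_means()].
#' @param panel [tf_panel()] or character vector of TF symbols.
#' @param threshold strict lower PCC bound, default 0.95.
#' @return `CoexpressionEdges` data.frame (tf, gene, pcc).
#' @export
coexpression_edges <- function(gm, panel, threshold = 0.95) {
  tfs <- if (inherits(panel, "TfPanel")) panel$tfs else panel
  missing <- setdiff(tfs, rownames(gm))
  if (length(missing))
    stop("panel TF(s) absent from matrix: ", paste(missing, collapse = ", "))
  sds <- apply(gm, 1L, stats::sd)
  const_tfs <- intersect(tfs, rownames(gm)[sds == 0])
  if (length(const_tfs)) {
    warning("constant-profile TF(s) excluded: ",
            paste(const_tfs, collapse = ", "))
    tfs <- setdiff(tfs, const_tfs)
  }
  const_genes <- setdiff(rownames(gm)[sds == 0], tfs)
  if (length(const_genes))
    message(length(const_genes),
            " constant-profile gene(s) excluded from edge consideration")
  ok <- rownames(gm)[sds > 0]
  cm <- stats::cor(t(gm[tfs, , drop = FALSE]), t(gm[ok, , drop = FALSE]))
  hits <- which(cm > threshold, arr.ind = TRUE)
  out <- data.frame(tf = tfs[hits[, 1L]], gene = ok[hits[, 2L]],
                    pcc = cm[hits], stringsAsFactors = FALSE)
  out <- out[out$tf != out$gene, , drop = FALSE]
  out <- out[order(out$tf, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("CoexpressionEdges", "data.frame")
  out
}

#' Detect the core TF cluster
#'
#' The maximum clique of the TF-TF co-expression graph (panel is small,
#' so the exact clique search is cheap). Ties between maximum cliques
#' break by larger summed pairwise PCC, then lexicographically.
#'
#' @param edges CoexpressionEdges.
#' @param panel TfPanel or character vector of panel TFs.
#' @return sorted character vector of core-cluster TFs (empty, with a
#'   warning, when no TF-TF edge exists).
#' @export
core_tf_cluster <- function(edges, panel) {
  tfs <- if (inherits(panel, "TfPanel")) panel$tfs else panel
  tt <- edges[edges$tf %in% tfs & edges$gene %in% tfs, , drop = FALSE]
  if (!nrow(tt)) {
    warning("no TF-TF edge above threshold: empty core cluster")
    return(character(0))
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pcc_of <- tapply(tt$pcc, pair_key(tt$tf, tt$gene), max)
  g <- igraph::graph_from_data_frame(tt[, c("tf", "gene")],
                                     directed = FALSE,
                                     vertices = sort(tfs))
  g <- igraph::simplify(g)
  cliques <- igraph::max_cliques(g)
  sizes <- lengths(cliques)
  cliques <- cliques[sizes == max(sizes)]
  members <- lapply(cliques, function(cl) sort(names(cl)))
  if (length(members) > 1L) {
    score <- vapply(members, function(m) {
      if (length(m) < 2L) return(0)
      pairs <- utils::combn(m, 2L)
      sum(pcc_of[pair_key(pairs[1L, ], pairs[2L, ])])
    }, numeric(1L))
    keys <- vapply(members, paste, character(1L), collapse = "|")
    members <- members[order(-score, keys)]
  }
  members[[1L]]
}

#' Per-gene joint-target counts over the panel and core subset
#'
#' For every gene with at least one link: the number of distinct panel
#' TFs it co-expresses with, the number of core TFs among them, the
#' core fraction as a half-up-rounded integer percentage, and whether
#' the gene links exclusively to core TFs.
#'
#' @param edges CoexpressionEdges.
#' @param panel TfPanel or character vector.
#' @param core core TF subset (defaults to `panel$core`).
#' @return data.frame (gene, n_panel_links, n_core_links,
#'   core_fraction, exclusive_to_core), sorted by descending core
#'   links then gene symbol.
#' @export
joint_target_counts <- function(edges, panel, core = NULL) {
  tfs <- if (inherits(panel, "TfPanel")) panel$tfs else panel
  if (is.null(core))
    core <- if (inherits(panel, "TfPanel")) panel$core else
      stop("`core` required when panel carries no core subset")
  if (length(setdiff(core, tfs))) stop("core must be a subset of the panel")
  e <- edges[edges$tf %in% tfs, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(gene = character(0), n_panel_links = integer(0),
                      n_core_links = integer(0), core_fraction = integer(0),
                      exclusive_to_core = logical(0)))
  links <- split(e$tf, e$gene)
  gene <- names(links)
  n_panel <- vapply(links, function(l) length(unique(l)), integer(1L))
  n_core <- vapply(links, function(l)
    length(intersect(unique(l), core)), integer(1L))
  out <- data.frame(gene = gene, n_panel_links = n_panel,
                    n_core_links = n_core,
                    core_fraction = as.integer(
                      round_half_up(100 * n_core / n_panel)),
                    exclusive_to_core = n_panel == n_core & n_core > 0L,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_core_links, -out$n_panel_links, out$gene), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Assemble the co-expression network
#'
#' Nodes are the core TFs plus every gene linking to at least
#' `min_core_links` core TFs; edges are the core-TF edges among those
#' nodes. Optional user-supplied functional class labels annotate the
#' gene nodes.
#'
#' @param edges CoexpressionEdges.
#' @param counts output of [joint_target_counts()].
#' @param core core TF symbols.
#' @param min_core_links minimum core links for gene inclusion (3, 4 or
#'   5 in the intended use; any positive value accepted).
#' @param node_classes optional named character vector gene -> class
#'   label.
#' @return `CoexpressionNetwork`: list with `nodes` (node, role, class),
#'   `edges`, `counts`.
#' @export
build_network <- function(edges, counts, core, min_core_links = 4,
                          node_classes = NULL) {
  if (min_core_links < 1) stop("`min_core_links` must be positive")
  keep <- counts$gene[counts$n_core_links >= min_core_links]
  nodes <- sort(unique(c(core, keep)))
  e <- edges[edges$tf %in% core & edges$gene %in% nodes, , drop = FALSE]
  rownames(e) <- NULL
  cls <- rep(NA_character_, length(nodes))
  if (!is.null(node_classes))
    cls[nodes %in% names(node_classes)] <-
      node_classes[nodes[nodes %in% names(node_classes)]]
  node_df <- data.frame(node = nodes,
                        role = ifelse(nodes %in% core, "core_tf", "gene"),
                        class = cls, stringsAsFactors = FALSE)
  structure(list(nodes = node_df, edges = e,
                 counts = counts[counts$gene %in% nodes, , drop = FALSE],
                 min_core_links = min_core_links),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork: %d nodes (%d core TFs), %d edges (>= %d core links)\n",
              nrow(x$nodes), sum(x$nodes$role == "core_tf"),
              nrow(x$edges), x$min_core_links))
  invisible(x)
}

#' Export a network as TSV edge list and GraphML
#'
#' @param network CoexpressionNetwork.
#' @param tsv_path edge-list TSV (tf, gene, pcc); `NULL` to skip.
#' @param graphml_path GraphML file; `NULL` to skip.
#' @export
write_network <- function(network, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path)) {
    e <- network$edges
    e$pcc <- signif(e$pcc, 6L)
    utils::write.table(e, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = stats::setNames(network$nodes,
                                 c("name", "role", "class")))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(tsv_path, graphml_path))
}

#' Write a joint-target count table mirroring the panel/core summary
#' @param counts from [joint_target_counts()].
#' @param path TSV output with columns gene, panel_merged, core_merged,
#'   pct_core_tf, exclusive_to_core.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- data.frame(gene = counts$gene,
                    panel_merged = counts$n_panel_links,
                    core_merged = counts$n_core_links,
                    pct_core_tf = counts$core_fraction,
                    exclusive_to_core = counts$exclusive_to_core)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
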