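# Promoter extraction, information-weighted position-weight-matrix
# scanning, binding-site matrix construction and integration with the
# co-expression network into a regulatory hierarchy.
#
# Coordinates are 0-based half-open; the TSS is the first transcribed
# base. For a + strand gene the promoter window is
# [TSS - upstream, TSS + downstream) in genome coordinates; for a -
# strand gene it is the reverse complement of
# [TSS - downstream, TSS + upstream).

#' Extract promoter windows around annotated TSSs
#'
#' Windows are clipped to contig bounds; clipped genes are flagged in
#' the `"clipped"` attribute. Returned sequences read 5' to 3' of the
#' gene.
#'
#' @param annotation data.frame (gene, chrom, tss, strand), e.g. from
#'   [read_bed_annotation()].
#' @param genome named character vector of contig sequences (or a FASTA
#'   path).
#' @param upstream,downstream window extent in bases (defaults 1000 and
#'   300).
#' @return named character vector of promoter sequences; attribute
#'   `clipped` names genes whose window hit a contig edge.
#' @export
extract_promoters <- function(annotation, genome, upstream = 1000,
                              downstream = 300) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  missing <- setdiff(annotation$chrom, names(genome))
  if (length(missing))
    stop("contig(s) absent from genome: ", paste(missing, collapse = ", "))
  out <- character(nrow(annotation))
  clipped <- character(0)
  for (i in seq_len(nrow(annotation))) {
    chrom <- genome[[annotation$chrom[i]]]
    clen <- nchar(chrom)
    tss <- annotation$tss[i]
    if (tss < 0L || tss >= clen)
      stop("TSS outside contig for gene ", annotation$gene[i])
    if (annotation$strand[i] == "+") {
      from <- tss - upstream
      to <- tss + downstream          # half-open end
    } else {
      from <- tss - downstream        # mirrored window
      to <- tss + upstream
    }
    cfrom <- max(from, 0L)
    cto <- min(to, clen)
    if (cfrom > from || cto < to) clipped <- c(clipped, annotation$gene[i])
    s <- substr(chrom, cfrom + 1L, cto)     # 1-based substr
    if (annotation$strand[i] == "-") s <- revcomp(s)
    out[i] <- s
  }
  names(out) <- annotation$gene
  attr(out, "clipped") <- clipped
  out
}

#' Position weight matrix with information weights
#'
#' Builds per-position probabilities from base counts with a pseudocount
#' per cell and derives the per-position information weight
#' `w_i = 2 + sum_b p_ib * log2(p_ib)` (0 to 2 bits).
#'
#' @param counts 4 x L matrix of non-negative base counts, rows A, C,
#'   G, T.
#' @param name TF/motif name.
#' @param pseudocount added to every cell before normalisation, default
#'   0.1.
#' @return object of class `Pwm`: `name`, `counts`, `prob`, `weight`,
#'   `length`, `consensus`.
#' @export
pwm <- function(counts, name = "motif", pseudocount = 0.1) {
  if (!is.matrix(counts) || nrow(counts) != 4L)
    stop("`counts` must be a 4 x L matrix")
  if (any(counts < 0)) stop("negative counts")
  if (any(colSums(counts) == 0)) stop("empty count column")
  rownames(counts) <- c("A", "C", "G", "T")
  prob <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  weight <- 2 + colSums(prob * log2(prob))
  consensus <- paste(rownames(prob)[apply(prob, 2L, which.max)],
                     collapse = "")
  structure(list(name = name, counts = counts, prob = prob,
                 weight = weight, length = ncol(counts),
                 consensus = consensus), class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm %s: %d positions, %.2f total bits, consensus %s\n",
              x$name, x$length, sum(x$weight), x$consensus))
  invisible(x)
}

#' Load a JASPAR motif file as a list of Pwm objects
#' @param path JASPAR count-matrix text file.
#' @param pseudocount per-cell pseudocount, default 0.1.
#' @export
read_pwms <- function(path, pseudocount = 0.1) {
  counts <- read_jaspar(path)
  out <- lapply(names(counts), function(nm)
    pwm(counts[[nm]], name = nm, pseudocount = pseudocount))
  names(out) <- names(counts)
  out
}

.base_index <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# integer encoding of a sequence; non-ACGT become NA
encode_dna <- function(seq) {
  unname(.base_index[strsplit(toupper(seq), "")[[1L]]])
}

# Information-weighted similarity of every window of `pwm$length` along
# an encoded sequence. Windows containing non-ACGT score NA.
window_scores <- function(pw, enc, weight_mask = NULL) {
  L <- pw$length
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric(0))
  w <- if (is.null(weight_mask)) pw$weight else pw$weight * weight_mask
  denom <- sum(w * apply(pw$prob, 2L, max))
  if (denom == 0) return(rep(0, n))    # degenerate zero-information matrix
  acc <- numeric(n)
  na <- logical(n)
  for (j in seq_len(L)) {
    b <- enc[j:(j + n - 1L)]
    na <- na | is.na(b)
    p <- pw$prob[cbind(ifelse(is.na(b), 1L, b), j)]
    acc <- acc + w[j] * p
  }
  score <- acc / denom
  score[na] <- NA_real_
  score
}

#' Matrix similarity of a sequence window against a PWM
#'
#' `score = sum_i w_i * p_i(b_i) / sum_i w_i * max_b p_i(b)`; equals 1
#' iff the window takes the modal base at every informative position.
#' A zero-information (uniform) matrix scores 0 with a warning.
#'
#' @param pw a [pwm()].
#' @param window character string of length `pw$length` (ACGT only).
#' @return score in `[0, 1]`.
#' @export
matrix_similarity <- function(pw, window) {
  stopifnot(inherits(pw, "Pwm"))
  if (nchar(window) != pw$length)
    stop("window length must equal matrix length")
  enc <- encode_dna(window)
  if (anyNA(enc)) stop("ambiguity codes in window")
  if (all(pw$weight < 1e-12)) {
    warning("degenerate zero-information matrix: score 0")
    return(0)
  }
  window_scores(pw, enc)
}

#' Core positions of a PWM
#'
#' The 4 consecutive positions with maximal summed information weight
#' (leftmost window on ties).
#'
#' @param pw a [pwm()] of length >= 4.
#' @return integer vector of 4 consecutive position indices.
#' @export
pwm_core <- function(pw) {
  if (pw$length < 4L) stop("matrix shorter than the 4-position core")
  sums <- vapply(seq_len(pw$length - 3L), function(i)
    sum(pw$weight[i:(i + 3L)]), numeric(1L))
  i <- which.max(sums)    # leftmost on ties
  i:(i + 3L)
}

#' Core similarity of a window against a PWM
#'
#' Matrix similarity restricted to the 4-position core.
#'
#' @inheritParams matrix_similarity
#' @return score in `[0, 1]`.
#' @export
core_similarity <- function(pw, window) {
  stopifnot(inherits(pw, "Pwm"))
  if (nchar(window) != pw$length)
    stop("window length must equal matrix length")
  enc <- encode_dna(window)
  if (anyNA(enc)) stop("ambiguity codes in window")
  core <- pwm_core(pw)
  mask <- as.numeric(seq_len(pw$length) %in% core)
  if (all((pw$weight * mask) < 1e-12)) {
    warning("degenerate zero-information core: score 0")
    return(0)
  }
  window_scores(pw, enc, weight_mask = mask)
}

#' Scan a promoter for PWM hits
#'
#' Both strands are scanned at every offset; a hit is stored iff the
#' core similarity reaches `core_threshold` and the matrix similarity
#' reaches `matrix_threshold`. Overlapping hits on the same strand are
#' counted separately. Offsets are 0-based positions of the match start
#' on the forward (promoter) strand. Promoters shorter than the motif
#' yield zero hits without error; windows with ambiguity codes are
#' skipped.
#'
#' @param pw a [pwm()].
#' @param promoter promoter sequence (character string).
#' @param matrix_threshold,core_threshold inclusive lower bounds in
#'   (0, 1], defaults 0.85 and 0.90.
#' @param gene optional gene name carried into the hit table.
#' @return `MotifHit` data.frame (gene, tf, offset, strand,
#'   matrix_score, core_score).
#' @export
scan_promoter <- function(pw, promoter, matrix_threshold = 0.85,
                          core_threshold = 0.90, gene = NA_character_) {
  stopifnot(inherits(pw, "Pwm"))
  if (matrix_threshold <= 0 || matrix_threshold > 1 ||
      core_threshold <= 0 || core_threshold > 1)
    stop("thresholds must lie in (0, 1]")
  empty <- data.frame(gene = character(0), tf = character(0),
                      offset = integer(0), strand = character(0),
                      matrix_score = numeric(0), core_score = numeric(0),
                      stringsAsFactors = FALSE)
  n_win <- nchar(promoter) - pw$length + 1L
  if (n_win < 1L) return(empty)
  core_mask <- as.numeric(seq_len(pw$length) %in% pwm_core(pw))
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") promoter else revcomp(promoter)
    enc <- suppressWarnings(encode_dna(s))
    ms <- window_scores(pw, enc)
    cs <- window_scores(pw, enc, weight_mask = core_mask)
    ok <- which(!is.na(ms) & !is.na(cs) &
                cs >= core_threshold & ms >= matrix_threshold)
    if (length(ok)) {
      # report offsets on the forward strand of the promoter
      off <- if (strand == "+") ok - 1L else
        nchar(promoter) - (ok - 1L) - pw$length
      hits[[strand]] <- data.frame(gene = gene, tf = pw$name,
                                   offset = as.integer(off),
                                   strand = strand,
                                   matrix_score = ms[ok],
                                   core_score = cs[ok],
                                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan a promoter set against a motif library
#'
#' @param pwms named list of [pwm()] objects.
#' @param promoters named character vector of promoter sequences.
#' @param matrix_threshold,core_threshold see [scan_promoter()].
#' @param exclude TF names to skip (default `"PPARGC1A"`, which acts as
#'   a co-factor without defined binding sites).
#' @return combined MotifHit data.frame.
#' @export
scan_promoter_set <- function(pwms, promoters, matrix_threshold = 0.85,
                              core_threshold = 0.90,
                              exclude = "PPARGC1A") {
  pwms <- pwms[setdiff(names(pwms), exclude)]
  res <- list()
  for (g in names(promoters))
    for (tf in names(pwms))
      res[[paste(g, tf)]] <- scan_promoter(pwms[[tf]], promoters[[g]],
                                           matrix_threshold,
                                           core_threshold, gene = g)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tabulate hits into a gene x TF binding-site count matrix
#'
#' @param hits MotifHit data.frame.
#' @param genes,tfs row and column universes (zero cells explicit).
#' @return `BindingSiteMatrix`: integer matrix of hit counts.
#' @export
binding_site_matrix <- function(hits, genes, tfs) {
  m <- matrix(0L, nrow = length(genes), ncol = length(tfs),
              dimnames = list(genes, tfs))
  if (nrow(hits)) {
    keep <- hits$gene %in% genes & hits$tf %in% tfs
    tab <- table(factor(hits$gene[keep], levels = genes),
                 factor(hits$tf[keep], levels = tfs))
    m[] <- as.integer(tab)
  }
  class(m) <- c("BindingSiteMatrix", class(m))
  m
}

#' Read/write a binding-site count matrix as TSV
#'
#' Layout: first column `gene`, one column per TF.
#'
#' @param path TSV file.
#' @return BindingSiteMatrix.
#' @export
read_site_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tab[[1L]])
  class(m) <- c("BindingSiteMatrix", class(m))
  m
}

#' @rdname read_site_matrix
#' @param m BindingSiteMatrix.
#' @export
write_site_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a binding-site matrix
#'
#' @param m BindingSiteMatrix (gene x TF counts).
#' @return list with `genes_with_sites` (per TF: number of genes with
#'   >= 1 site), `per_gene_tfs` (per gene: number of TFs with >= 1
#'   site), and `k_or_more` (for k = 1..n TFs: number of genes with
#'   sites for at least k TFs).
#' @export
summarize_sites <- function(m) {
  if (!nrow(m) || !ncol(m)) stop("empty binding-site matrix")
  nonzero <- m >= 1L
  per_tf <- colSums(nonzero)
  per_gene <- rowSums(nonzero)
  k_or_more <- vapply(seq_len(ncol(m)), function(k)
    sum(per_gene >= k), integer(1L))
  names(k_or_more) <- paste0("k>=", seq_len(ncol(m)))
  list(genes_with_sites = per_tf, per_gene_tfs = per_gene,
       k_or_more = k_or_more)
}

#' Integrate co-expression and binding-site evidence
#'
#' Builds the directed TF -> gene regulatory hierarchy: an edge is
#' flagged `"both"` when a co-expression edge exists and the target's
#' promoter carries >= 1 predicted site for that TF; edges supported by
#' a single evidence source are flagged `"coexpression"` or
#' `"binding_site"`. TF self-regulation (TF -> its own promoter) enters
#' through the binding-site evidence.
#'
#' @param network CoexpressionNetwork (or a CoexpressionEdges
#'   data.frame).
#' @param site_matrix BindingSiteMatrix.
#' @return `RegulatoryHierarchy` data.frame (tf, gene, evidence).
#' @export
integrate_hierarchy <- function(network, site_matrix) {
  edges <- if (inherits(network, "CoexpressionNetwork")) network$edges
  else network
  coex <- unique(paste(edges$tf, edges$gene, sep = "\r"))
  site_pairs <- which(site_matrix >= 1L, arr.ind = TRUE)
  sites <- if (nrow(site_pairs))
    paste(colnames(site_matrix)[site_pairs[, 2L]],
          rownames(site_matrix)[site_pairs[, 1L]], sep = "\r")
  else character(0)
  all_pairs <- union(coex, sites)
  if (!length(all_pairs))
    return(structure(data.frame(tf = character(0), gene = character(0),
                                evidence = character(0),
                                stringsAsFactors = FALSE),
                     class = c("RegulatoryHierarchy", "data.frame")))
  parts <- do.call(rbind, strsplit(all_pairs, "\r", fixed = TRUE))
  evidence <- ifelse(all_pairs %in% coex & all_pairs %in% sites, "both",
                     ifelse(all_pairs %in% coex, "coexpression",
                            "binding_site"))
  out <- data.frame(tf = parts[, 1L], gene = parts[, 2L],
                    evidence = evidence, stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("RegulatoryHierarchy", "data.frame")
  out
}

#' Write a regulatory hierarchy as TSV and GraphML
#' @param hierarchy RegulatoryHierarchy.
#' @param tsv_path,graphml_path output files (`NULL` to skip either).
#' @export
write_hierarchy <- function(hierarchy, tsv_path = NULL,
                            graphml_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(hierarchy, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(hierarchy, directed = TRUE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(tsv_path, graphml_path))
}
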