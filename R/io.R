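# Readers/writers for the plain-text interchange formats used across the
# pipeline. Coordinates are 0-based half-open throughout.

#' Write gene annotation as BED
#'
#' One record per gene; the TSS occupies the single base
#' `[tss, tss + 1)`. Columns: chrom, start, end, name, score, strand.
#'
#' @param annotation data.frame with columns gene, chrom, tss, strand.
#' @param path output file.
#' @export
write_bed_annotation <- function(annotation, path) {
  bed <- data.frame(annotation$chrom, annotation$tss, annotation$tss + 1L,
                    annotation$gene, rep(0L, nrow(annotation)),
                    annotation$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED
#'
#' @param path BED file written by [write_bed_annotation()] (6 columns).
#' @return data.frame with columns gene, chrom, tss, strand.
#' @export
read_bed_annotation <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("expected 6-column BED: ", path)
  if (any(!bed[[6L]] %in% c("+", "-"))) stop("invalid strand in ", path)
  data.frame(gene = as.character(bed[[4L]]), chrom = as.character(bed[[1L]]),
             tss = as.integer(bed[[2L]]), strand = bed[[6L]],
             stringsAsFactors = FALSE)
}

#' Write named sequences as FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write motif count matrices in JASPAR text format
#'
#' Each motif is a `>name` header followed by four rows
#' `A [ n1 n2 ... ]` etc.
#'
#' @param motifs named list of 4 x L count matrices with rownames
#'   A, C, G, T.
#' @param path output file.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    writeLines(paste0(">", nm), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(path)
}

#' Read JASPAR-format motif count matrices
#'
#' @param path JASPAR text file.
#' @return named list of 4 x L numeric count matrices (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    nm <- sub("^>\\s*", "", lines[starts[i]])
    nm <- strsplit(nm, "\\s+")[[1L]][1L]
    block <- lines[(starts[i] + 1L):(starts[i] + 4L)]
    rows <- lapply(block, function(l) {
      nums <- regmatches(l, gregexpr("[0-9]+\\.?[0-9]*", l))[[1L]]
      as.numeric(nums)
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("ragged count rows for motif ", nm)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[nm]] <- m
  }
  out
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors; names are set names.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions
#'   (second GMT column), default `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: set name, description, then member genes,
#'   tab-separated.
#' @return named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nms)) stop("duplicate set names in ", path)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1L), 2L), nms)
  sets
}

#' Multi-tissue reference expression table
#'
#' @param values non-negative gene x tissue matrix (linear scale).
#' @param target_tissues character vector of target-tissue column names
#'   (e.g. heart and skeletal muscle); at least 3 non-target tissues must
#'   remain.
#' @return `TissueReference` object.
#' @export
tissue_reference <- function(values, target_tissues) {
  if (any(values < 0)) stop("tissue reference values must be >= 0")
  if (!all(target_tissues %in% colnames(values)))
    stop("target tissue(s) absent from table")
  if (ncol(values) - length(target_tissues) < 3L)
    stop("need at least 3 non-target tissues")
  structure(list(values = values, target_tissues = target_tissues),
            class = "TissueReference")
}

#' Write a tissue reference table as TSV
#' @param ref TissueReference.
#' @param path output file. Target tissues are recorded in a `#target:`
#'   comment line ahead of the header.
#' @param digits significant digits, or `NULL` for full (round-trip
#'   exact) precision.
#' @export
write_tissue_reference <- function(ref, path, digits = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#target:", paste(ref$target_tissues, collapse = ",")),
             con)
  v <- if (is.null(digits))
    matrix(sprintf("%.17g", ref$values), nrow = nrow(ref$values),
           dimnames = dimnames(ref$values))
  else signif(ref$values, digits)
  df <- data.frame(gene = rownames(ref$values), v,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tissue reference table
#' @param path TSV written by [write_tissue_reference()].
#' @export
read_tissue_reference <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#target:"))
    stop("missing #target: header line in ", path)
  targets <- strsplit(sub("^#target:", "", first), ",")[[1L]]
  tab <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  tissue_reference(m, targets)
}

#' Read a ground-truth JSON file written by [write_fixture_bundle()]
#' @param path ground_truth.json path.
#' @return list mirroring the in-memory `truth` element of a dataset.
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  gm <- truth$group_mean_of
  v <- gm$values
  if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
  m <- matrix(as.numeric(v), nrow = length(gm$genes),
              dimnames = list(gm$genes, gm$groups))
  truth$group_mean_of <- m
  truth$gene_class_of <- unlist(truth$gene_class_of)
  for (nm in c("true_edges", "planted_sites"))
    if (!is.data.frame(truth[[nm]]))
      truth[[nm]] <- as.data.frame(truth[[nm]], stringsAsFactors = FALSE)
  truth
}
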