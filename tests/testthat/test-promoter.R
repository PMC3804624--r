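test_that("promoter extraction honours strand, window bounds and clipping", {
  # + strand: [TSS - up, TSS + down) verbatim
  genome <- c(chrP = paste(rep("ACGT", 575), collapse = ""))  # 2300 bases
  ann <- data.frame(gene = "gp", chrom = "chrP", tss = 1000L,
                    strand = "+", stringsAsFactors = FALSE)
  prom <- extract_promoters(ann, genome)
  expect_identical(prom[["gp"]], unname(substr(genome, 1, 1300)))
  expect_length(attr(prom, "clipped"), 0L)

  # - strand on a 20-base toy contig, checked base by base
  toy <- c(chrM = "ACGTACGTAAGGCCTTACGT")
  annm <- data.frame(gene = "gm", chrom = "chrM", tss = 9L, strand = "-",
                     stringsAsFactors = FALSE)
  pm <- extract_promoters(annm, toy, upstream = 6, downstream = 3)
  # window [tss - 3, tss + 6) = 0-based 6..14: "GTAAGGCCT", then revcomp
  expect_identical(pm[["gm"]],
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString("GTAAGGCCT"))))

  # clipping: TSS at 10 leaves a 310-base flagged window
  annc <- data.frame(gene = "gc", chrom = "chrP", tss = 10L, strand = "+",
                     stringsAsFactors = FALSE)
  pc <- extract_promoters(annc, genome)
  expect_identical(nchar(pc[["gc"]]), 310L)
  expect_identical(attr(pc, "clipped"), "gc")
  expect_error(extract_promoters(
    data.frame(gene = "gx", chrom = "nope", tss = 1L, strand = "+"),
    genome), "nope")
  expect_error(extract_promoters(
    data.frame(gene = "gx", chrom = "chrP", tss = 5000L, strand = "+"),
    genome), "outside")
})

test_that("matrix similarity follows the information-weighted formula", {
  counts <- matrix(c(
    90, 2, 10, 60, 25, 1, 1, 85,
    4, 90, 30, 10, 25, 1, 97, 5,
    3, 4, 30, 20, 25, 97, 1, 5,
    3, 4, 30, 10, 25, 1, 1, 5), nrow = 4, byrow = TRUE)
  pw <- pwm(counts, name = "toy")
  expect_equal(colSums(pw$prob), rep(1, 8))
  expect_true(all(pw$weight >= 0 & pw$weight <= 2))
  # information weight definition
  expect_equal(pw$weight,
               2 + colSums(pw$prob * log2(pw$prob)))
  # consensus scores exactly 1
  expect_equal(matrix_similarity(pw, pw$consensus), 1)
  # random windows equal the naive hand evaluation
  set.seed(81)
  for (i in 1:25) {
    win <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
    expect_equal(matrix_similarity(pw, win), naive_window_score(pw, win),
                 tolerance = 1e-12)
  }
  expect_error(matrix_similarity(pw, "ACGTNACG"), "ambiguity")
  expect_error(matrix_similarity(pw, "ACGT"), "length")
  # uniform matrix scores 0 with a degeneracy warning
  uni <- pwm(matrix(25, 4, 6), name = "flat", pseudocount = 0)
  expect_warning(s <- matrix_similarity(uni, "ACGTAC"), "degenerate")
  expect_identical(s, 0)
})

test_that("core similarity restricts to the most informative 4-mer window", {
  counts <- matrix(1, 4, 10)
  counts[1, 4:7] <- 97   # AAAA core at positions 4-7
  counts[2, c(1, 10)] <- 5
  pw <- pwm(counts, name = "coretest")
  sums <- vapply(1:7, function(i) sum(pw$weight[i:(i + 3)]), numeric(1))
  expect_identical(pwm_core(pw), (which.max(sums)):(which.max(sums) + 3))
  expect_identical(pwm_core(pw), 4:7)
  expect_equal(core_similarity(pw, pw$consensus), 1)
  # window differing only outside the core still scores 1 on the core
  off_core <- paste0("GGG", "AAAA", "GGG")
  expect_equal(core_similarity(pw, off_core), 1)
  expect_lt(matrix_similarity(pw, off_core), 1)
  # mismatch inside the core drops the core score
  in_core <- paste0(substr(pw$consensus, 1, 4), "C",
                    substr(pw$consensus, 6, 10))
  expect_lt(core_similarity(pw, in_core), 0.8)
})

test_that("promoter scanning finds planted sites on both strands and matches a brute-force rescan", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  pw <- pwm(ds$motifs[["GATA4"]], name = "GATA4")
  gene <- "TGT001"
  hits <- scan_promoter(pw, ds$promoters[[gene]], gene = gene)
  planted <- ds$truth$planted_sites
  planted <- planted[planted$gene == gene & planted$tf == "GATA4", ]
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$offset, planted$offset)
  expect_identical(hits$strand, planted$strand)
  expect_equal(hits$matrix_score, 1)
  # brute-force rescan of every window on both strands
  prom <- ds$promoters[[gene]]
  L <- pw$length
  core_pos <- pwm_core(pw)
  brute <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") prom else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
    for (o in seq_len(nchar(s) - L + 1)) {
      win <- substr(s, o, o + L - 1)
      ms <- naive_window_score(pw, win)
      cs <- naive_window_score(pw, win, positions = core_pos)
      if (!is.na(ms) && ms >= 0.85 && cs >= 0.90) {
        fwd_off <- if (str == "+") o - 1 else nchar(prom) - (o - 1) - L
        brute[[length(brute) + 1]] <- data.frame(offset = fwd_off,
                                                 strand = str)
      }
    }
  }
  brute <- do.call(rbind, brute)
  expect_identical(nrow(hits), nrow(brute))
  expect_setequal(paste(hits$offset, hits$strand),
                  paste(brute$offset, brute$strand))
  # minus-strand plant reported with strand "-"
  minus <- ds$truth$planted_sites[ds$truth$planted_sites$strand == "-", ][1, ]
  pwm_minus <- pwm(ds$motifs[[minus$tf]], name = minus$tf)
  hm <- scan_promoter(pwm_minus, ds$promoters[[minus$gene]],
                      gene = minus$gene)
  expect_true(any(hm$offset == minus$offset & hm$strand == "-"))
  # thresholds = 1 on pure background: zero hits
  set.seed(82)
  bgseq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_identical(nrow(scan_promoter(pw, bgseq, 1, 1)), 0L)
  # promoter shorter than the motif: zero hits, no error
  expect_identical(nrow(scan_promoter(pw, "ACGT")), 0L)
  expect_error(scan_promoter(pw, bgseq, matrix_threshold = 0), "0, 1")
})

test_that("strand closure: scanning the reverse complement mirrors the hit set", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  pw <- pwm(ds$motifs[["TCF8"]], name = "TCF8")
  prom <- ds$promoters[["TGT002"]]
  fwd <- scan_promoter(pw, prom)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(prom)))
  rev_hits <- scan_promoter(pw, rc)
  expect_identical(nrow(fwd), nrow(rev_hits))
  mirrored <- nchar(prom) - rev_hits$offset - pw$length
  expect_setequal(paste(fwd$offset, fwd$strand),
                  paste(mirrored, ifelse(rev_hits$strand == "+", "-", "+")))
})

test_that("raising scan thresholds never adds hits", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  pw <- pwm(ds$motifs[["NKX2-5"]], name = "NKX2-5")
  prom <- ds$promoters[["TGT003"]]
  lo <- scan_promoter(pw, prom, 0.6, 0.6)
  hi <- scan_promoter(pw, prom, 0.9, 0.95)
  expect_true(all(paste(hi$offset, hi$strand) %in%
                  paste(lo$offset, lo$strand)))
  expect_gte(nrow(lo), nrow(hi))
})

test_that("binding-site matrix tallies planted sites and round-trips the printed table", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  pwms <- lapply(names(ds$motifs), function(n) pwm(ds$motifs[[n]], n))
  names(pwms) <- names(ds$motifs)
  cls <- ds$truth$gene_class_of
  members <- c(ds$truth$core_tfs, names(cls)[cls == "module_target"])
  hits <- scan_promoter_set(pwms, ds$promoters[members],
                            exclude = character(0))
  bsm <- binding_site_matrix(hits, genes = sort(members),
                             tfs = names(pwms))
  planted <- ds$truth$planted_sites
  oracle <- table(factor(planted$gene, levels = sort(members)),
                  factor(planted$tf, levels = names(pwms)))
  expect_equal(unclass(bsm), unclass(oracle), ignore_attr = TRUE)
  # empty hit set gives an explicit all-zero matrix
  zero <- binding_site_matrix(hits[0, ], genes = c("a", "b"),
                              tfs = c("X", "Y"))
  expect_true(all(zero == 0L))
  expect_identical(dim(zero), c(2L, 2L))
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_matrix(bsm, f)
  expect_equal(unclass(read_site_matrix(f)), unclass(bsm))
})

test_that("site summaries match the published promoter-analysis table", {
  m <- read_site_matrix(table4_path())
  expect_identical(dim(m), c(27L, 4L))
  s <- summarize_sites(m)
  expect_identical(unname(s$genes_with_sites),
                   c(9, 10, 23, 22))
  expect_identical(unname(s$k_or_more["k>=2"]), 22L)
  expect_identical(unname(s$per_gene_tfs["HAND1"]), 4)
  # random matrix equals the cell-by-cell tally
  set.seed(83)
  r <- matrix(stats::rpois(40, 0.8), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("T", 1:4)))
  sr <- summarize_sites(r)
  expect_equal(unname(sr$genes_with_sites),
               unname(apply(r, 2, function(col) sum(col >= 1))))
  expect_equal(unname(sr$per_gene_tfs),
               unname(apply(r, 1, function(row) sum(row >= 1))))
  for (k in 1:4)
    expect_identical(unname(sr$k_or_more[k]),
                     sum(apply(r, 1, function(row) sum(row >= 1)) >= k))
})

test_that("hierarchy integration flags joint evidence and recovers the planted network", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  gm <- group_means(ds$expression)
  panel <- c(ds$truth$core_tfs, ds$truth$distractor_tfs)
  edges <- coexpression_edges(gm, panel, 0.95)
  pwms <- lapply(names(ds$motifs), function(n) pwm(ds$motifs[[n]], n))
  names(pwms) <- names(ds$motifs)
  cls <- ds$truth$gene_class_of
  members <- c(ds$truth$core_tfs, names(cls)[cls == "module_target"])
  hits <- scan_promoter_set(pwms, ds$promoters[members],
                            exclude = character(0))
  bsm <- binding_site_matrix(hits, genes = sort(members),
                             tfs = names(pwms))
  hier <- integrate_hierarchy(edges, bsm)
  both <- hier[hier$evidence == "both", ]
  expect_setequal(paste(both$tf, both$gene),
                  paste(ds$truth$true_edges$tf, ds$truth$true_edges$gene))
  # empty site matrix: no "both" edges
  h0 <- integrate_hierarchy(edges, binding_site_matrix(hits[0, ],
                                                       sort(members),
                                                       names(pwms)))
  expect_false(any(h0$evidence == "both"))
  # self-regulation enters via binding evidence (planted TF promoters)
  selfs <- hier[hier$tf == hier$gene, ]
  expect_true(all(ds$truth$core_tfs %in% selfs$tf))
})
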