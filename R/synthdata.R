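# Synthetic-data generator: a seeded, fully self-contained emulation of a
# four-stage ventricular-cardiomyocyte expression study with planted gene
# classes, a planted core transcription-factor module with shared targets,
# and promoter motif instances consistent with the planted network.

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic dataset: four sample
#' groups in developmental order (undifferentiated stem cells, then
#' stem-cell-derived, fetal and adult ventricular cardiomyocytes),
#' replicate counts, log2-scale noise, the transcription-factor panel
#' (5 core + 12 distractors by default, 17 in total), planted gene-class
#' sizes and the maturation fold-change gradient.
#'
#' @param n_genes total number of genes (must cover all planted classes).
#' @param groups ordered character vector of exactly 4 distinct group
#'   labels (developmental order).
#' @param replicates_per_group replicates per group, `>= 2`.
#' @param noise_sd additive Gaussian noise on the log2 scale, `>= 0`.
#' @param n_core_tfs number of core (module) transcription factors.
#' @param n_distractor_tfs number of non-module panel TFs.
#' @param targets_per_module number of planted module target genes.
#' @param n_pluripotency,n_pan_cardiac,n_maturation,n_cell_cycle sizes of
#'   the other planted classes.
#' @param promoter_len promoter window length in bases.
#' @param fc_gradient linear fold changes of the maturation class in the
#'   three cardiomyocyte groups relative to the first of them; must be
#'   strictly increasing.
#' @param seed integer RNG seed; same seed, same dataset, bit for bit.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_genes = 500,
                       groups = c("hESC", "hESC-VCM", "hF-VCM", "hA-VCM"),
                       replicates_per_group = 3,
                       noise_sd = 0.1,
                       n_core_tfs = 5,
                       n_distractor_tfs = 12,
                       targets_per_module = 30,
                       n_pluripotency = 15,
                       n_pan_cardiac = 20,
                       n_maturation = 10,
                       n_cell_cycle = 15,
                       promoter_len = 1300,
                       fc_gradient = c(1, 16, 32),
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), groups = as.character(groups),
              replicates_per_group = as.integer(replicates_per_group),
              noise_sd = noise_sd, n_core_tfs = as.integer(n_core_tfs),
              n_distractor_tfs = as.integer(n_distractor_tfs),
              targets_per_module = as.integer(targets_per_module),
              n_pluripotency = as.integer(n_pluripotency),
              n_pan_cardiac = as.integer(n_pan_cardiac),
              n_maturation = as.integer(n_maturation),
              n_cell_cycle = as.integer(n_cell_cycle),
              promoter_len = as.integer(promoter_len),
              fc_gradient = fc_gradient, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$groups) != 4L || anyDuplicated(cfg$groups))
    stop("`groups` must hold exactly 4 distinct labels")
  if (cfg$n_genes <= 0L) stop("`n_genes` must be positive")
  if (cfg$replicates_per_group < 2L) stop("`replicates_per_group` must be >= 2")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (cfg$n_core_tfs < 1L || cfg$n_distractor_tfs < 0L)
    stop("TF panel counts invalid")
  if (cfg$targets_per_module < 1L || cfg$targets_per_module >= cfg$n_genes)
    stop("`targets_per_module` must be positive and below `n_genes`")
  n_planted <- cfg$n_core_tfs + cfg$n_distractor_tfs +
    cfg$targets_per_module + cfg$n_pluripotency + cfg$n_pan_cardiac +
    cfg$n_maturation + cfg$n_cell_cycle
  if (n_planted > cfg$n_genes)
    stop("planted classes (", n_planted, " genes) exceed `n_genes`")
  if (cfg$promoter_len < 50L) stop("`promoter_len` too short")
  if (length(cfg$fc_gradient) != 3L || any(diff(cfg$fc_gradient) <= 0))
    stop("`fc_gradient` must be 3 strictly increasing fold changes")
  invisible(cfg)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

# Fixed noiseless log2 group-profile shapes (4 values, developmental
# order). All pairwise Pearson correlations among these 17 shapes stay
# below 0.84, so the PCC > 0.95 edge rule sees planted structure only.
# The core/class/background shapes place every between-cardiomyocyte
# contrast on one gene-space direction (deltas proportional to (4, 5)
# relative to the derived-CM group): the planted developmental axis that
# makes the three CM group centroids collinear in noiseless data. The 12
# distractor-TF shapes are off-axis; their variance share is small.
.core_shape <- c(10, 5, 9, 10)
.class_shapes <- list(
  pluripotency    = c(12, 4, 4, 4),
  pan_cardiac     = c(4, 12, 12, 12),
  cell_cycle_down = c(10, 9, 5, 4))
.distractor_shapes <- matrix(c(
  4, 6, 4, 4,   4, 4, 6, 4,   4, 6, 6, 4,   6, 6, 6, 4,
  10, 4, 8, 4,  8, 6, 10, 4,  8, 10, 4, 6,  6, 4, 4, 8,
  10, 4, 4, 8,  10, 8, 4, 8,  8, 4, 10, 8,  6, 8, 6, 4),
  ncol = 4, byrow = TRUE)

.core_tf_names <- c("GATA4", "HAND1", "NKX2-5", "PPARGC1A", "TCF8")
.distractor_tf_names <- c("FOXP1", "GATA6", "HAND2", "IRX4", "IRX5", "ISL1",
                          "MEF2C", "MESP1", "PPARA", "SRF", "TBX20", "TBX5")

.tissue_names <- c("heart", "skeletal_muscle", "brain", "liver", "kidney",
                   "lung", "spleen", "pancreas", "intestine", "skin",
                   "testis", "blood")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Count matrix for one synthetic motif: 18 positions, 16 high-information
# positions (consensus count 97 vs 1) flanked by two soft positions.
make_motif_counts <- function(consensus) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  cc <- strsplit(consensus, "")[[1L]]
  m <- matrix(1, nrow = 4, ncol = L, dimnames = list(bases, NULL))
  for (j in seq_len(L)) m[cc[j], j] <- 97
  for (j in c(1L, L)) {            # soft flanks
    m[, j] <- 15
    m[cc[j], j] <- 55
  }
  m
}

#' Generate a complete synthetic dataset
#'
#' Emits an expression matrix (log2 scale, group means plus Gaussian
#' noise, with detection p-values), a gene annotation with per-gene
#' contigs, a genome and matching promoter set carrying planted motif
#' instances for the core TFs, a JASPAR-style motif library, a 12-tissue
#' reference table (cardiac classes heart/skeletal-muscle enriched), a
#' gene-set collection, and the `GroundTruth` oracle describing every
#' planted feature.
#'
#' Planted classes: `pluripotency` high only in group 1; `pan_cardiac`
#' high in all three cardiomyocyte groups; `maturation_up` strictly
#' increasing across groups 2-4 with the configured fold gradient;
#' `cell_cycle_down` decreasing; `tf_core` and `module_target` sharing
#' one profile shape up to affine per-gene transforms (noiseless
#' group-mean PCC exactly 1 within the module); `tf_distractor` on
#' mutually weakly-correlated shapes; `background` rejection-sampled so
#' no background gene correlates above 0.85 with any planted profile.
#'
#' @param config a [sim_config()] object.
#' @return list of class `vcm_dataset` with elements `expression`,
#'   `annotation`, `genome`, `promoters`, `motifs`, `tissue_ref`,
#'   `gene_sets`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(cfg) {
  groups <- cfg$groups
  reps <- cfg$replicates_per_group
  samples <- paste(rep(groups, each = reps), seq_len(reps), sep = "_r")
  sample_groups <- stats::setNames(rep(groups, each = reps), samples)

  core_tfs <- if (cfg$n_core_tfs <= length(.core_tf_names))
    .core_tf_names[seq_len(cfg$n_core_tfs)]
  else c(.core_tf_names, sprintf("CORETF%02d",
         seq_len(cfg$n_core_tfs - length(.core_tf_names))))
  distractors <- if (cfg$n_distractor_tfs <= length(.distractor_tf_names))
    .distractor_tf_names[seq_len(cfg$n_distractor_tfs)]
  else c(.distractor_tf_names, sprintf("DTF%02d",
         seq_len(cfg$n_distractor_tfs - length(.distractor_tf_names))))

  targets <- sprintf("TGT%03d", seq_len(cfg$targets_per_module))
  pluri  <- sprintf("PLURI%02d", seq_len(cfg$n_pluripotency))
  cardiac <- sprintf("CARD%02d", seq_len(cfg$n_pan_cardiac))
  matur  <- sprintf("MAT%02d", seq_len(cfg$n_maturation))
  ccyc   <- sprintf("CCYC%02d", seq_len(cfg$n_cell_cycle))
  n_bg <- cfg$n_genes - length(core_tfs) - length(distractors) -
    length(targets) - length(pluri) - length(cardiac) - length(matur) -
    length(ccyc)
  bg <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character(0)

  genes <- c(core_tfs, distractors, targets, pluri, cardiac, matur, ccyc, bg)
  gene_class <- stats::setNames(
    c(rep("tf_core", length(core_tfs)),
      rep("tf_distractor", length(distractors)),
      rep("module_target", length(targets)),
      rep("pluripotency", length(pluri)),
      rep("pan_cardiac", length(cardiac)),
      rep("maturation_up", length(matur)),
      rep("cell_cycle_down", length(ccyc)),
      rep("background", length(bg))), genes)

  # --- noiseless group means ---------------------------------------------
  # maturation genes are abundant in fetal/adult CMs (they surface in
  # top-abundance screens) but strongly depleted in derived CMs
  mat_base <- 6.5
  mat_shape <- c(4, mat_base,
                 mat_base + log2(cfg$fc_gradient[2] / cfg$fc_gradient[1]),
                 mat_base + log2(cfg$fc_gradient[3] / cfg$fc_gradient[1]))
  tf_shapes <- rbind(
    matrix(rep(.core_shape, length(core_tfs)), ncol = 4, byrow = TRUE),
    .distractor_shapes[rep_len(seq_len(nrow(.distractor_shapes)),
                               length(distractors)), , drop = FALSE])
  rownames(tf_shapes) <- c(core_tfs, distractors)

  planted_profiles <- rbind(tf_shapes, pluripotency = .class_shapes$pluripotency,
                            pan_cardiac = .class_shapes$pan_cardiac,
                            maturation = mat_shape,
                            cell_cycle = .class_shapes$cell_cycle_down)

  means <- matrix(NA_real_, nrow = length(genes), ncol = 4,
                  dimnames = list(genes, groups))
  affine <- function(shape, offset, scale = 1) offset + scale * shape
  for (g in core_tfs)
    means[g, ] <- affine(.core_shape, stats::runif(1, -1, 1))
  for (i in seq_along(distractors))
    means[distractors[i], ] <- affine(tf_shapes[distractors[i], ],
                                      stats::runif(1, -0.5, 0.5))
  for (g in targets)
    means[g, ] <- affine(.core_shape, stats::runif(1, -1, 1),
                         stats::runif(1, 0.8, 1.25))
  for (g in pluri) means[g, ] <- affine(.class_shapes$pluripotency,
                                        stats::runif(1, -0.5, 0.5))
  for (g in cardiac) means[g, ] <- affine(.class_shapes$pan_cardiac,
                                          stats::runif(1, -0.5, 0.5))
  for (g in matur) means[g, ] <- affine(mat_shape, stats::runif(1, -0.5, 0.5))
  for (g in ccyc) means[g, ] <- affine(.class_shapes$cell_cycle_down,
                                       stats::runif(1, -0.5, 0.5))
  for (g in bg) {
    repeat {                       # keep background uncorrelated with plants
      # background profiles lie on the planted developmental axis:
      # free stem-cell level, free CM baseline, CM deltas along (4, 5)
      a <- stats::rnorm(1, 8, 2)
      b <- stats::rnorm(1, 8, 2)
      s <- stats::rnorm(1, 0, 0.5)
      x <- c(a, b, b + 4 * s, b + 5 * s)
      r <- apply(planted_profiles, 1L, function(p) stats::cor(x, p))
      if (max(r) < 0.85 && stats::sd(x) > 0.5) break
    }
    means[g, ] <- x
  }

  # --- expression values and detection p ---------------------------------
  noise <- matrix(stats::rnorm(length(genes) * length(samples), 0,
                               cfg$noise_sd),
                  nrow = length(genes))
  values <- means[, sample_groups[samples], drop = FALSE] + noise
  dimnames(values) <- list(genes, samples)
  present <- means > 4.5          # noiseless call per gene x group
  dp <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  for (s in samples) {
    pres <- present[, sample_groups[s]]
    dp[pres, s] <- stats::runif(sum(pres), 0, 0.001)
    dp[!pres, s] <- stats::runif(sum(!pres), 0.5, 1)
  }
  expr <- expression_matrix(values, sample_groups, detection_p = dp,
                            id_space = "gene")

  # --- motifs -------------------------------------------------------------
  motif_len <- 18L
  repeat {                         # distinct consensi for the core TFs
    consensi <- vapply(core_tfs, function(.) random_dna(motif_len),
                       character(1L))
    hd <- utils::combn(consensi, 2L, function(p) {
      sum(strsplit(p[1L], "")[[1L]] != strsplit(p[2L], "")[[1L]])
    })
    if (length(consensi) < 2L || min(hd) >= 8L) break
  }
  motifs <- lapply(consensi, make_motif_counts)
  names(motifs) <- core_tfs

  # --- promoters with planted sites --------------------------------------
  site_genes <- c(core_tfs, targets)   # module members carry all core motifs
  promoters <- stats::setNames(vapply(genes, function(.)
    random_dna(cfg$promoter_len), character(1L)), genes)
  planted <- list()
  for (g in site_genes) {
    seqchars <- strsplit(promoters[[g]], "")[[1L]]
    used <- integer(0)
    for (tf in core_tfs) {
      repeat {
        off <- sample.int(cfg$promoter_len - motif_len + 1L, 1L) - 1L
        span <- (off + 1L):(off + motif_len)
        if (!length(intersect(span, used))) break
      }
      used <- c(used, span)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") consensi[[tf]] else revcomp(consensi[[tf]])
      seqchars[span] <- strsplit(ins, "")[[1L]]
      planted[[length(planted) + 1L]] <-
        data.frame(gene = g, tf = tf, offset = off, strand = strand,
                   stringsAsFactors = FALSE)
    }
    promoters[[g]] <- paste(seqchars, collapse = "")
  }
  planted_sites <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene = character(0), tf = character(0),
               offset = integer(0), strand = character(0))

  # --- genome + annotation (one contig per gene) --------------------------
  strands <- sample(c("+", "-"), length(genes), replace = TRUE)
  names(strands) <- genes
  genome <- character(length(genes))
  tss <- integer(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (strands[g] == "+") {
      genome[i] <- paste0(promoters[[g]], random_dna(1000L))
      tss[i] <- 1000L
    } else {
      genome[i] <- paste0(random_dna(1000L), revcomp(promoters[[g]]))
      tss[i] <- cfg$promoter_len
    }
  }
  names(genome) <- paste0("chr_", genes)
  annotation <- data.frame(gene = genes, chrom = paste0("chr_", genes),
                           tss = tss, strand = unname(strands),
                           stringsAsFactors = FALSE)

  # --- tissue reference ----------------------------------------------------
  tref <- matrix(10 * 2^stats::runif(length(genes) * length(.tissue_names),
                                     -1, 1),
                 nrow = length(genes),
                 dimnames = list(genes, .tissue_names))
  heartish <- c(cardiac, matur)
  tref[heartish, ] <- 2^stats::runif(length(heartish) * length(.tissue_names),
                                     -0.5, 0.5)
  tref[heartish, c("heart", "skeletal_muscle")] <-
    50 * 2^stats::runif(length(heartish) * 2L, -0.2, 0.2)
  tissue_ref <- tissue_reference(tref, c("heart", "skeletal_muscle"))

  # --- gene sets -----------------------------------------------------------
  gene_sets <- list(PLURIPOTENCY = pluri, PAN_CARDIAC = cardiac,
                    MATURATION = matur, CELL_CYCLE = ccyc,
                    CORE_MODULE = c(core_tfs, targets))
  for (k in seq_len(20L)) {
    gene_sets[[sprintf("RANDOM%02d", k)]] <-
      sort(sample(genes, sample(15:40, 1L)))
  }

  # --- ground truth --------------------------------------------------------
  members <- c(core_tfs, targets)
  true_edges <- do.call(rbind, lapply(core_tfs, function(tf)
    data.frame(tf = tf, gene = setdiff(members, tf),
               stringsAsFactors = FALSE)))
  truth <- list(gene_class_of = gene_class, true_edges = true_edges,
                planted_sites = planted_sites, group_mean_of = means,
                core_tfs = core_tfs, distractor_tfs = distractors)

  structure(list(expression = expr, annotation = annotation,
                 genome = genome, promoters = promoters, motifs = motifs,
                 tissue_ref = tissue_ref, gene_sets = gene_sets,
                 truth = truth, config = cfg),
            class = "vcm_dataset")
}

#' @export
print.vcm_dataset <- function(x, ...) {
  cat(sprintf("vcm_dataset: %d genes x %d samples, %d TFs (%d core), seed %d\n",
              nrow(x$expression$values), ncol(x$expression$values),
              length(x$truth$core_tfs) + length(x$truth$distractor_tfs),
              length(x$truth$core_tfs), x$config$seed))
  invisible(x)
}

#' Write a dataset to disk as plain-text fixture files
#'
#' Expression and tissue tables as TSV, annotation as BED, genome and
#' promoters as FASTA, motifs as JASPAR count matrices, gene sets as GMT,
#' ground truth as JSON, plus a `manifest.json` listing every written
#' file with its MD5 checksum. Writing the same seeded dataset twice
#' yields identical checksums.
#'
#' @param dataset a `vcm_dataset`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
write_fixture_bundle <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "vcm_dataset") || is.list(dataset))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)

  write_expression_tsv(dataset$expression, p("expression.tsv"),
                       digits = NULL)
  if (!is.null(dataset$expression$detection_p))
    write_expression_tsv(dataset$expression$detection_p,
                         p("detection_p.tsv"), digits = NULL)
  sg <- dataset$expression$sample_groups
  utils::write.table(data.frame(sample = names(sg), group = unname(sg)),
                     p("sample_groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed_annotation(dataset$annotation, p("annotation.bed"))
  write_fasta(dataset$genome, p("genome.fa"))
  write_fasta(dataset$promoters, p("promoters.fa"))
  write_jaspar(dataset$motifs, p("motifs.jaspar"))
  write_tissue_reference(dataset$tissue_ref, p("tissue_reference.tsv"))
  write_gmt(dataset$gene_sets, p("gene_sets.gmt"))
  truth <- dataset$truth
  truth$group_mean_of <- list(genes = rownames(truth$group_mean_of),
                              groups = colnames(truth$group_mean_of),
                              values = unname(truth$group_mean_of))
  truth$gene_class_of <- as.list(truth$gene_class_of)  # keep gene names
  jsonlite::write_json(truth, p("ground_truth.json"), digits = NA,
                       auto_unbox = FALSE)

  files <- c("expression.tsv",
             if (!is.null(dataset$expression$detection_p)) "detection_p.tsv",
             "sample_groups.tsv", "annotation.bed", "genome.fa",
             "promoters.fa", "motifs.jaspar", "tissue_reference.tsv",
             "gene_sets.gmt", "ground_truth.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA)
  invisible(manifest)
}
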