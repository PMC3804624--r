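# Pipeline orchestration: a single validated configuration drives the
# stages in dependency order with seeded reproducibility and a manifest
# of checksummed outputs.

#' Pipeline run configuration
#'
#' Collects input paths, stage toggles and every stage threshold. Any
#' field may be overridden; [validate_config()] reports violations
#' before a run starts.
#'
#' @param expression,sample_groups,detection_p,annotation,genome,motifs,tissue_ref,gene_sets
#'   input file paths (TSV / BED / FASTA / JASPAR / GMT as produced by
#'   [write_fixture_bundle()]). `detection_p` is optional.
#' @param out_dir output directory.
#' @param stages character vector of enabled stages, a subset of
#'   `c("structure", "diffexpr", "abundance", "enrichment", "coexnet",
#'   "promoter", "hierarchy")`.
#' @param tf_panel_tfs,core_tfs TF panel and designated core subset
#'   (`core_tfs = NULL` lets [core_tf_cluster()] decide).
#' @param vcm_groups the 3 cardiomyocyte groups in developmental order
#'   (defaults to groups 2:4 of the expression matrix).
#' @param diff_groups length-2 vector: reference and comparison group
#'   for the differential and enrichment stages (defaults to groups
#'   2:3).
#' @param fc_threshold,p_threshold,top_n,specificity_cut,depletion_cut,pcc_threshold,matrix_threshold,core_threshold,min_core_links,upstream,downstream,n_perm
#'   stage thresholds (defaults: 2, 0.05, 200, 10, 10, 0.95, 0.85,
#'   0.90, 4, 1000, 300, 1000).
#' @param scan_exclude TF names excluded from promoter scanning
#'   (default `"PPARGC1A"`).
#' @param seed integer seed governing all randomness in the run.
#' @return `RunConfig` list.
#' @export
run_config <- function(expression = NULL, sample_groups = NULL,
                       detection_p = NULL, annotation = NULL,
                       genome = NULL, motifs = NULL, tissue_ref = NULL,
                       gene_sets = NULL, out_dir = "vcmnet_out",
                       stages = c("structure", "diffexpr", "abundance",
                                  "enrichment", "coexnet", "promoter",
                                  "hierarchy"),
                       tf_panel_tfs = c(.core_tf_names,
                                        .distractor_tf_names),
                       core_tfs = NULL,
                       vcm_groups = NULL, diff_groups = NULL,
                       fc_threshold = 2, p_threshold = 0.05,
                       top_n = 200, specificity_cut = 10,
                       depletion_cut = 10, pcc_threshold = 0.95,
                       matrix_threshold = 0.85, core_threshold = 0.90,
                       min_core_links = 4, upstream = 1000,
                       downstream = 300, n_perm = 1000,
                       scan_exclude = "PPARGC1A", seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are a
#' validation violation. `overrides` (e.g. parsed command-line flags)
#' take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides named list applied after the file.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(raw, overrides)
  do.call(run_config, args)
}

.all_stages <- c("structure", "diffexpr", "abundance", "enrichment",
                 "coexnet", "promoter", "hierarchy")

#' Validate a run configuration
#'
#' @param config RunConfig.
#' @return character vector of violations (empty iff runnable); each
#'   entry names the offending field and rule.
#' @export
validate_config <- function(config) {
  v <- character(0)
  bad_stage <- setdiff(config$stages, .all_stages)
  if (length(bad_stage))
    v <- c(v, paste0("stages: unknown stage(s) ",
                     paste(bad_stage, collapse = ", ")))
  need_input <- function(field, for_stages) {
    if (any(for_stages %in% config$stages)) {
      p <- config[[field]]
      if (is.null(p))
        v <<- c(v, paste0(field, ": required for stage(s) ",
                          paste(intersect(for_stages, config$stages),
                                collapse = ", ")))
      else if (!file.exists(p))
        v <<- c(v, paste0(field, ": file not found (", p, ")"))
    }
  }
  if (length(config$stages)) {
    need_input("expression", .all_stages)
    need_input("sample_groups", .all_stages)
  }
  need_input("tissue_ref", "abundance")
  need_input("gene_sets", "enrichment")
  need_input("annotation", c("promoter", "hierarchy"))
  need_input("genome", c("promoter", "hierarchy"))
  need_input("motifs", c("promoter", "hierarchy"))
  if ("hierarchy" %in% config$stages &&
      !all(c("coexnet", "promoter") %in% config$stages))
    v <- c(v, "stages: hierarchy requires coexnet and promoter")
  chk_range <- function(field, lo, hi) {
    x <- config[[field]]
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi)
      v <<- c(v, sprintf("%s: must lie in [%s, %s]", field, lo, hi))
  }
  chk_range("pcc_threshold", -1, 1)
  chk_range("p_threshold", 0, 1)
  chk_range("matrix_threshold", 1e-9, 1)
  chk_range("core_threshold", 1e-9, 1)
  if (config$fc_threshold <= 0) v <- c(v, "fc_threshold: must be positive")
  if (config$top_n <= 0) v <- c(v, "top_n: must be positive")
  if (!config$min_core_links %in% 1:17)
    v <- c(v, "min_core_links: must be a small positive count")
  if (config$n_perm < 100) v <- c(v, "n_perm: must be >= 100")
  if (config$upstream < 0 || config$downstream < 0)
    v <- c(v, "upstream/downstream: must be non-negative")
  v
}

read_sample_groups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(tab$group), tab$sample)
}

#' Execute the pipeline
#'
#' Runs the enabled stages in dependency order (inputs -> structure /
#' diffexpr / abundance / enrichment -> coexnet -> promoter ->
#' hierarchy), writing every stage's outputs under `config$out_dir` and
#' returning a run report. All randomness flows from `config$seed`;
#' identical configuration and inputs give identical outputs, so two
#' runs produce byte-identical manifests.
#'
#' @param config validated [run_config()].
#' @return `RunReport`: list with `stages` (per-stage status), `manifest`
#'   (data.frame file, md5), `seed`, `versions`.
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  status <- stats::setNames(rep("skipped", length(.all_stages)), .all_stages)
  outputs <- character(0)
  emit <- function(f) outputs <<- c(outputs, f)

  if (!length(config$stages)) {
    manifest <- data.frame(file = character(0), md5 = character(0))
    jsonlite::write_json(manifest, p("manifest.json"), digits = NA)
    return(structure(list(stages = status, manifest = manifest,
                          seed = config$seed,
                          versions = list(
                            vcmnet = as.character(utils::packageVersion("vcmnet")),
                            R = paste(R.version$major, R.version$minor,
                                      sep = "."))),
                     class = "RunReport"))
  }

  groups_map <- read_sample_groups(config$sample_groups)
  expr <- read_expression_matrix(config$expression, groups_map,
                                 detection_p_path = config$detection_p)
  run_stage <- function(name, body) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch({
      body()
      status[name] <<- "ok"
    }, error = function(e) {
      status[name] <<- paste("failed:", conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    invisible(NULL)
  }

  run_stage("structure", function() {
    dend <- cluster_samples(expr)
    dendrogram_newick(dend, p("dendrogram.nwk")); emit("dendrogram.nwk")
    emb <- pca_embed(expr, n_components = 2)
    write_embedding_tsv(emb, p("pca_embedding.tsv")); emit("pca_embedding.tsv")
    vcm <- if (is.null(config$vcm_groups)) expr$group_levels[2:4]
           else config$vcm_groups
    r <- developmental_axis_linearity(emb, vcm)
    jsonlite::write_json(list(linearity_r = r, groups = vcm,
                              explained = emb$explained),
                         p("structure_summary.json"), digits = NA,
                         auto_unbox = TRUE)
    emit("structure_summary.json")
  })

  dgrp <- if (is.null(config$diff_groups)) expr$group_levels[2:3]
          else config$diff_groups
  diff <- NULL
  run_stage("diffexpr", function() {
    diff <<- diff_table(expr, dgrp[1L], dgrp[2L],
                        fc_threshold = config$fc_threshold,
                        p_threshold = config$p_threshold)
    write_diff_tsv(diff, p("diffexpr.tsv")); emit("diffexpr.tsv")
    counts <- count_regulated(diff, config$fc_threshold, config$p_threshold)
    jsonlite::write_json(counts, p("diffexpr_counts.json"), digits = NA,
                         auto_unbox = TRUE)
    emit("diffexpr_counts.json")
  })

  run_stage("abundance", function() {
    tref <- read_tissue_reference(config$tissue_ref)
    vcm <- if (is.null(config$vcm_groups)) expr$group_levels[2:4]
           else config$vcm_groups
    rep_ <- classify_markers(expr, tref, vcm, n = config$top_n,
                             specificity_cut = config$specificity_cut,
                             depletion_cut = config$depletion_cut)
    write_marker_report(rep_, p("markers.tsv"), p("markers.json"))
    emit("markers.tsv"); emit("markers.json")
    write_venn_gmt(rep_$venn, p("venn_regions.gmt")); emit("venn_regions.gmt")
  })

  run_stage("enrichment", function() {
    sets <- read_gmt(config$gene_sets)
    res <- permutation_fdr(expr, sets, dgrp[1L], dgrp[2L],
                           n_perm = config$n_perm, seed = config$seed)
    write_enrichment(res, p("enrichment.tsv"), p("enrichment_meta.json"))
    emit("enrichment.tsv"); emit("enrichment_meta.json")
  })

  edges <- NULL; core <- NULL; counts <- NULL
  run_stage("coexnet", function() {
    gm <- group_means(expr)
    panel_tfs <- intersect(config$tf_panel_tfs, rownames(gm))
    edges <<- coexpression_edges(gm, panel_tfs, config$pcc_threshold)
    core <<- if (is.null(config$core_tfs))
      core_tf_cluster(edges, panel_tfs) else config$core_tfs
    counts <<- joint_target_counts(edges, panel_tfs, core)
    net <- build_network(edges, counts, core,
                         min_core_links = config$min_core_links)
    write_network(net, p("coexpression_edges.tsv"),
                  p("coexpression_network.graphml"))
    emit("coexpression_edges.tsv"); emit("coexpression_network.graphml")
    write_counts_tsv(counts, p("joint_target_counts.tsv"))
    emit("joint_target_counts.tsv")
    jsonlite::write_json(list(core_tfs = core,
                              n_edges = nrow(edges)),
                         p("coexnet_summary.json"), auto_unbox = FALSE)
    emit("coexnet_summary.json")
  })

  sites <- NULL
  run_stage("promoter", function() {
    ann <- read_bed_annotation(config$annotation)
    genome <- read_fasta(config$genome)
    pwms <- read_pwms(config$motifs)
    scan_genes <- if (!is.null(counts) && nrow(counts))
      union(intersect(ann$gene, counts$gene),
            intersect(ann$gene, names(pwms)))
    else ann$gene
    ann <- ann[ann$gene %in% scan_genes, , drop = FALSE]
    prom <- extract_promoters(ann, genome, config$upstream,
                              config$downstream)
    hits <- scan_promoter_set(pwms, prom, config$matrix_threshold,
                              config$core_threshold,
                              exclude = config$scan_exclude)
    utils::write.table(
      within(hits, {matrix_score <- signif(matrix_score, 6L)
                    core_score <- signif(core_score, 6L)}),
      p("motif_hits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    emit("motif_hits.tsv")
    sites <<- binding_site_matrix(
      hits, genes = sort(names(prom)),
      tfs = setdiff(names(pwms), config$scan_exclude))
    write_site_matrix(sites, p("binding_sites.tsv")); emit("binding_sites.tsv")
    summ <- summarize_sites(sites)
    jsonlite::write_json(summ, p("site_summary.json"), digits = NA)
    emit("site_summary.json")
  })

  run_stage("hierarchy", function() {
    hier <- integrate_hierarchy(edges, sites)
    write_hierarchy(hier, p("hierarchy.tsv"), p("hierarchy.graphml"))
    emit("hierarchy.tsv"); emit("hierarchy.graphml")
  })

  outputs <- sort(unique(outputs))
  manifest <- data.frame(file = outputs,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              outputs))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA)
  structure(list(stages = status, manifest = manifest, seed = config$seed,
                 versions = list(
                   vcmnet = as.character(utils::packageVersion("vcmnet")),
                   R = paste(R.version$major, R.version$minor, sep = "."))),
            class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed", x$seed, ")\n")
  for (s in names(x$stages)) cat(sprintf("  %-10s %s\n", s, x$stages[[s]]))
  cat(" ", nrow(x$manifest), "output file(s)\n")
  invisible(x)
}
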