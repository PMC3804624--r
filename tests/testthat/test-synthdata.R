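test_that("config validation rejects degenerate study designs", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(replicates_per_group = 1), "replicates")
  expect_error(sim_config(groups = c("a", "b", "c")), "4 distinct")
  expect_error(sim_config(n_genes = 100, targets_per_module = 100),
               "targets_per_module")
  expect_error(sim_config(n_genes = 60, targets_per_module = 10),
               "planted classes")
})

test_that("default panel is 17 TFs with a 5-TF core", {
  cfg <- sim_config()
  expect_identical(cfg$n_core_tfs + cfg$n_distractor_tfs, 17L)
  ds <- cached_dataset(n_genes = 200, noise_sd = 0.05, seed = 5)
  expect_length(ds$truth$core_tfs, 5L)
  expect_setequal(ds$truth$core_tfs,
                  c("GATA4", "HAND1", "NKX2-5", "PPARGC1A", "TCF8"))
})

test_that("same seed gives bit-identical datasets and bundles", {
  cfg <- sim_config(n_genes = 120, targets_per_module = 10,
                    noise_sd = 0.1, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$promoters, d2$promoters)
  expect_identical(d1$truth, d2$truth)
  o1 <- withr::local_tempdir()
  o2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(d1, o1)
  m2 <- write_fixture_bundle(d2, o2)
  expect_identical(m1$md5, m2$md5)
  expect_true(all(file.exists(file.path(o1, m1$file))))
})

test_that("noiseless planted modules correlate perfectly and classes obey their shape constraints", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  gm <- group_means(ds$expression)
  te <- ds$truth$true_edges
  r <- mapply(function(tf, g) pcc(gm[tf, ], gm[g, ]), te$tf, te$gene)
  expect_equal(unname(r), rep(1, nrow(te)), tolerance = 1e-12)

  cls <- ds$truth$gene_class_of
  mu <- ds$truth$group_mean_of
  # pluripotency: maximal in group 1, absent-level elsewhere
  for (g in names(cls)[cls == "pluripotency"])
    expect_true(all(mu[g, 1] > mu[g, 2:4]))
  # maturation strictly increasing across the three CM stages
  for (g in names(cls)[cls == "maturation_up"])
    expect_true(all(diff(mu[g, 2:4]) > 0))
  # cell-cycle block depleted with maturation
  for (g in names(cls)[cls == "cell_cycle_down"])
    expect_true(all(diff(mu[g, 2:4]) < 0))
  # expression equals the noiseless means exactly at noise_sd = 0
  expect_equal(ds$expression$values[, 1],
               mu[, ds$expression$sample_groups[1]],
               ignore_attr = TRUE)
})

test_that("planted maturation gradient carries the configured fold changes", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  cls <- ds$truth$gene_class_of
  mat_genes <- names(cls)[cls == "maturation_up"]
  for (g in mat_genes) {
    expect_equal(fold_change(ds$expression, g, "hESC-VCM", "hF-VCM"), 16)
    expect_equal(fold_change(ds$expression, g, "hESC-VCM", "hA-VCM"), 32)
  }
})

test_that("module targets carry planted sites for every core TF inside the promoter", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  ps <- ds$truth$planted_sites
  cls <- ds$truth$gene_class_of
  targets <- names(cls)[cls == "module_target"]
  motif_len <- ncol(ds$motifs[[1]])
  for (g in targets)
    expect_setequal(ps$tf[ps$gene == g], ds$truth$core_tfs)
  expect_true(all(ps$offset >= 0 &
                  ps$offset <= ds$config$promoter_len - motif_len))
  # every module target takes part in at least one true edge
  expect_true(all(targets %in% ds$truth$true_edges$gene))
})

test_that("fixture bundle round-trips through the package readers exactly", {
  ds <- cached_dataset(n_genes = 120, targets_per_module = 10,
                       noise_sd = 0.1, seed = 7)
  out <- withr::local_tempdir()
  manifest <- write_fixture_bundle(ds, out)
  p <- function(f) file.path(out, f)

  groups <- ds$expression$sample_groups
  expr2 <- read_expression_matrix(p("expression.tsv"), groups,
                                  detection_p_path = p("detection_p.tsv"))
  expect_equal(expr2$values, ds$expression$values)
  expect_equal(expr2$detection_p, ds$expression$detection_p)

  ann2 <- read_bed_annotation(p("annotation.bed"))
  expect_equal(ann2, ds$annotation)
  expect_identical(read_fasta(p("genome.fa")), ds$genome)
  expect_identical(read_fasta(p("promoters.fa")), ds$promoters)
  expect_equal(read_jaspar(p("motifs.jaspar")), ds$motifs)
  tr2 <- read_tissue_reference(p("tissue_reference.tsv"))
  expect_equal(tr2$values, ds$tissue_ref$values)
  expect_identical(tr2$target_tissues, ds$tissue_ref$target_tissues)
  gs2 <- read_gmt(p("gene_sets.gmt"))
  expect_equal(gs2, ds$gene_sets, ignore_attr = TRUE)
  tru2 <- read_ground_truth(p("ground_truth.json"))
  expect_equal(tru2$group_mean_of, ds$truth$group_mean_of)
  expect_identical(tru2$gene_class_of, ds$truth$gene_class_of)
  expect_equal(tru2$true_edges, ds$truth$true_edges)
  expect_equal(tru2$planted_sites, ds$truth$planted_sites)
})

test_that("an empty dataset writes header-only files without error", {
  ds <- cached_dataset(n_genes = 120, targets_per_module = 10,
                       noise_sd = 0.1, seed = 7)
  empty <- ds
  empty$expression <- subset_expression(ds$expression, genes = character(0))
  empty$annotation <- ds$annotation[0, ]
  empty$genome <- character(0)
  empty$promoters <- character(0)
  empty$gene_sets <- list()
  empty$truth$planted_sites <- ds$truth$planted_sites[0, ]
  out <- withr::local_tempdir()
  expect_no_error(manifest <- write_fixture_bundle(empty, out))
  expect_true(all(file.exists(file.path(out, manifest$file))))
  expect_identical(readLines(file.path(out, "expression.tsv"))[1],
                   paste(c("gene", colnames(ds$expression$values)),
                         collapse = "\t"))
})

test_that("tissue reference plants >10-fold heart enrichment for cardiac classes only", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  cls <- ds$truth$gene_class_of
  hearty <- names(cls)[cls %in% c("pan_cardiac", "maturation_up")]
  other <- names(cls)[cls == "background"]
  spec_h <- vapply(hearty, tissue_specificity, numeric(1), ref = ds$tissue_ref)
  spec_o <- vapply(other, tissue_specificity, numeric(1), ref = ds$tissue_ref)
  expect_true(all(spec_h > 10))
  expect_true(all(spec_o < 10))
})
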