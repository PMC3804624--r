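test_that("group means average replicates in developmental order", {
  v <- matrix(c(1, 3,  2, 4,  5, 7,  6, 8), 1, 8)
  dimnames(v) <- list("g", paste0(rep(c("w", "x", "y", "z"), each = 2),
                                  "_r", 1:2))
  groups <- stats::setNames(rep(c("w", "x", "y", "z"), each = 2),
                            colnames(v))
  em <- expression_matrix(v, groups)
  gm <- group_means(em)
  expect_identical(colnames(gm), c("w", "x", "y", "z"))
  expect_equal(unname(gm["g", ]), c(2, 3, 6, 7))
  # single replicate per group: identity
  em1 <- subset_expression(em, samples = colnames(v)[c(1, 3, 5, 7)])
  expect_equal(unname(group_means(em1)["g", ]), c(1, 2, 5, 6))
  # random matrix equals per-cell recomputation
  em2 <- rand_expr(10, c("a", "b", "c", "d"), 3, seed = 71)
  gm2 <- group_means(em2)
  for (grp in c("a", "b", "c", "d"))
    expect_equal(gm2[, grp],
                 rowMeans(em2$values[, em2$sample_groups == grp]))
})

test_that("pcc matches the covariance formula and rejects constant profiles", {
  expect_equal(pcc(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(pcc(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pcc(a, b), manual, tolerance = 1e-14)
  expect_error(pcc(c(1, 1, 1, 1), a), "constant")
  expect_error(pcc(a, c(1, 2)), "length")
})

test_that("edge calling is strict, symmetric for TF pairs, and matches the all-pairs oracle", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  gm <- group_means(ds$expression)
  panel <- c(ds$truth$core_tfs, ds$truth$distractor_tfs)
  edges <- coexpression_edges(gm, panel, 0.95)
  # noiseless: exactly the planted module edges
  expect_setequal(paste(edges$tf, edges$gene),
                  paste(ds$truth$true_edges$tf, ds$truth$true_edges$gene))
  # brute-force oracle over a random submatrix
  sub <- gm[1:50, ]
  e50 <- coexpression_edges(sub, panel[panel %in% rownames(sub)], 0.9)
  for (tf in unique(e50$tf)) for (g in rownames(sub)) {
    r <- suppressWarnings(stats::cor(sub[tf, ], sub[g, ]))
    stored <- any(e50$tf == tf & e50$gene == g)
    expect_identical(stored, isTRUE(r > 0.9) && g != tf)
  }
  # TF-TF symmetry
  tt <- edges[edges$gene %in% panel, ]
  expect_setequal(paste(tt$tf, tt$gene), paste(tt$gene, tt$tf))
  # threshold monotonicity and boundary strictness
  e_hi <- coexpression_edges(gm, panel, 0.99)
  expect_true(all(paste(e_hi$tf, e_hi$gene) %in%
                  paste(edges$tf, edges$gene)))
  e_one <- coexpression_edges(gm, panel, 1)
  expect_identical(nrow(e_one), 0L)   # r > 1 impossible, even for r = 1
  # constant TF excluded with a warning
  gm_const <- gm
  gm_const["GATA4", ] <- 3
  expect_warning(ec <- coexpression_edges(gm_const, panel, 0.95), "GATA4")
  expect_false("GATA4" %in% ec$tf)
  expect_error(coexpression_edges(gm, c(panel, "NOPE")), "NOPE")
})

test_that("core TF cluster equals the exhaustive maximum-clique enumeration", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  gm <- group_means(ds$expression)
  panel <- c(ds$truth$core_tfs, ds$truth$distractor_tfs)
  edges <- coexpression_edges(gm, panel, 0.95)
  expect_identical(core_tf_cluster(edges, panel),
                   sort(ds$truth$core_tfs))
  # random 8-TF instance vs 2^8 subset enumeration
  set.seed(72)
  tfs <- paste0("T", 1:8)
  prof <- matrix(stats::rnorm(32), 8, 4, dimnames = list(tfs, NULL))
  e8 <- coexpression_edges(prof, tfs, 0.5)
  adj <- matrix(FALSE, 8, 8, dimnames = list(tfs, tfs))
  adj[cbind(e8$tf, e8$gene)] <- TRUE
  best <- character(0)
  for (mask in 1:(2^8 - 1)) {
    mem <- tfs[bitwAnd(mask, 2^(0:7)) > 0]
    if (length(mem) < 2) next
    pr <- utils::combn(mem, 2)
    if (all(adj[cbind(pr[1, ], pr[2, ])]) &&
        length(mem) > length(best))
      best <- mem
  }
  if (length(best) >= 2)
    expect_length(core_tf_cluster(e8, tfs), length(best))
  # no TF-TF edges: empty cluster with warning
  lone <- data.frame(tf = "T1", gene = "geneX", pcc = 0.99)
  expect_warning(cl <- core_tf_cluster(lone, tfs), "empty core")
  expect_length(cl, 0L)
})

test_that("joint-target counts reproduce the worked percentage example and a brute-force tally", {
  tfs <- sprintf("TF%02d", 1:17)
  core <- tfs[1:5]
  # a gene linked to 8 panel TFs, 5 of them core -> 63% core fraction
  e <- data.frame(tf = tfs[c(1:5, 10:12)], gene = "LAMA4",
                  pcc = 0.99, stringsAsFactors = FALSE)
  jc <- joint_target_counts(e, tfs, core)
  expect_identical(jc$n_panel_links, 8L)
  expect_identical(jc$n_core_links, 5L)
  expect_identical(jc$core_fraction, 63L)
  expect_false(jc$exclusive_to_core)
  # exclusively-core gene: 100%
  e2 <- data.frame(tf = core, gene = "SOLO", pcc = 0.99)
  jc2 <- joint_target_counts(e2, tfs, core)
  expect_identical(jc2$core_fraction, 100L)
  expect_true(jc2$exclusive_to_core)
  # random edge set vs per-gene brute-force tally
  set.seed(73)
  genes <- sprintf("G%02d", 1:40)
  re <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  re <- re[stats::runif(nrow(re)) < 0.15, ]
  re$pcc <- 0.96
  jc3 <- joint_target_counts(re, tfs, core)
  for (i in seq_len(nrow(jc3))) {
    g <- jc3$gene[i]
    linked <- unique(re$tf[re$gene == g])
    expect_identical(jc3$n_panel_links[i], length(linked))
    expect_identical(jc3$n_core_links[i], length(intersect(linked, core)))
    expect_identical(jc3$core_fraction[i],
                     as.integer(floor(100 * length(intersect(linked, core)) /
                                      length(linked) + 0.5)))
  }
  # zero-link genes never appear
  expect_true(all(jc3$n_panel_links >= 1))
})

test_that("network assembly filters by core links and is monotone in the threshold", {
  ds <- cached_dataset(n_genes = 150, targets_per_module = 12,
                       noise_sd = 0, seed = 3)
  gm <- group_means(ds$expression)
  panel <- c(ds$truth$core_tfs, ds$truth$distractor_tfs)
  edges <- coexpression_edges(gm, panel, 0.95)
  core <- core_tf_cluster(edges, panel)
  counts <- joint_target_counts(edges, panel, core)
  net5 <- build_network(edges, counts, core, min_core_links = 5)
  # noiseless: exactly the planted module members
  cls <- ds$truth$gene_class_of
  expected <- sort(c(core, names(cls)[cls == "module_target"]))
  expect_identical(net5$nodes$node, expected)
  net1 <- build_network(edges, counts, core, min_core_links = 1)
  expect_true(all(net5$nodes$node %in% net1$nodes$node))
  # node set equals the filter oracle over counts
  net3 <- build_network(edges, counts, core, min_core_links = 3)
  oracle <- sort(unique(c(core, counts$gene[counts$n_core_links >= 3])))
  expect_identical(net3$nodes$node, oracle)
  expect_true(all(net3$edges$tf %in% core))
})
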