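# Shared fixtures, built in code. Datasets are cached per configuration
# so expensive generation runs once per test session.

.ds_cache <- new.env(parent = emptyenv())

cached_dataset <- function(...) {
  cfg <- sim_config(...)
  key <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  key <- substr(digest_key(key), 1, 32)
  if (is.null(.ds_cache[[key]]))
    .ds_cache[[key]] <- generate_dataset(cfg)
  .ds_cache[[key]]
}

digest_key <- function(s) {
  f <- tempfile()
  writeLines(s, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

# tiny hand-built expression matrix: genes x samples with two groups
tiny_expr <- function(values, groups = NULL) {
  if (is.null(groups))
    groups <- stats::setNames(rep(c("A", "B"), each = ncol(values) / 2),
                              colnames(values))
  expression_matrix(values, groups)
}

rand_expr <- function(n_genes, groups, reps, seed = 1, mean = 8, sd = 1) {
  set.seed(seed)
  samples <- paste(rep(groups, each = reps), seq_len(reps), sep = "_r")
  v <- matrix(stats::rnorm(n_genes * length(samples), mean, sd),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  expression_matrix(v, stats::setNames(rep(groups, each = reps), samples))
}

table4_path <- function() {
  system.file("extdata", "table4_binding_sites.tsv", package = "vcmnet")
}

# brute-force agglomerative clustering oracle: returns the cophenetic
# distance matrix implied by exhaustively recomputing every merge
brute_agglomeration_cophenetic <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(labels)
  coph <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(coph) <- 0
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      pairs <- expand.grid(clusters[[i]], clusters[[j]],
                           stringsAsFactors = FALSE)
      dv <- mapply(function(a, b) d[a, b], pairs[[1]], pairs[[2]])
      h <- if (linkage == "average") mean(dv) else max(dv)
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h; coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# naive window scorer used as the PWM-scanning oracle
naive_window_score <- function(pw, window, positions = NULL) {
  enc <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(enc)) return(NA_real_)
  w <- pw$weight
  if (!is.null(positions)) w <- w * (seq_len(pw$length) %in% positions)
  num <- sum(w * pw$prob[cbind(enc, seq_len(pw$length))])
  den <- sum(w * apply(pw$prob, 2, max))
  if (den == 0) 0 else num / den
}
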