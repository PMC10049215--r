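# Shared fixtures, built once per test run.

suppressPackageStartupMessages(library(GenomicRanges))

.cache <- new.env(parent = emptyenv())

# Full pipeline run on the default configuration (2 chrom x 1 Mb, 2000
# genes, 9 samples, 20 planted DMRs, 150 planted DM-DEGs).
default_run <- function() {
  if (is.null(.cache$run)) {
    .cache$run <- suppressWarnings(suppressMessages(run_pipeline(sim_config())))
  }
  .cache$run
}

# Sparse genome (60 genes on 2 Mb) where genomic feature classes are
# spatially separated.
sparse_config <- function(seed = 11) {
  sim_config(
    n_genes = 60, chrom_length = 1e6, n_chromosomes = 2,
    n_planted_dmr = 6, n_planted_dmdeg = 10, n_deg_per_stage = 5, seed = seed
  )
}

sparse_dataset <- function() {
  if (is.null(.cache$sparse)) .cache$sparse <- simulate_dataset(sparse_config())
  .cache$sparse
}

sparse_mm <- function() {
  if (is.null(.cache$sparse_mm)) {
    sim <- sparse_dataset()
    .cache$sparse_mm <- merge_samples(
      lapply(sim$methylomes, compute_levels), sim$config$design
    )
  }
  .cache$sparse_mm
}

# hand-built cytosine-report table
cyt_table <- function(chrom, pos, C, T, context = "CpG", strand = "+") {
  data.frame(
    chrom = chrom, pos = pos, strand = strand,
    count_methylated = C, count_unmethylated = T, context = context,
    stringsAsFactors = FALSE
  )
}

# build a meth_matrix directly from per-sample level/coverage vectors
mm_from_levels <- function(levels, coverage = NULL, stages = NULL) {
  n <- nrow(levels)
  if (is.null(coverage)) coverage <- matrix(10, n, ncol(levels))
  design <- data.frame(
    sample = colnames(levels),
    stage = stages %||% rep("p21", ncol(levels)),
    replicate = seq_len(ncol(levels)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      sites = data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
        stringsAsFactors = FALSE),
      level = levels, coverage = coverage, design = design
    ),
    class = "meth_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-sided conditional test oracle: enumerate the whole
# conditional support via log-binomial coefficients
oracle_exact_p <- function(m1, u1, m2, u2) {
  k <- m1 + u1
  K <- m1 + m2
  N <- m1 + u1 + m2 + u2
  if (N == 0 || K == 0 || K == N || k == 0 || k == N) return(1)
  i <- max(0, k - (N - K)):min(k, K)
  logp <- lchoose(K, i) + lchoose(N - K, k - i) - lchoose(N, k)
  p <- exp(logp)
  min(1, sum(p[p <= p[i == m1] * (1 + 1e-7)]))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

# mean silhouette of a 2-D embedding under integer/character labels
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(unique(labels[!own]), function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
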