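test_that("cytosine reports round-trip through parsing and validation", {
  tab <- cyt_table("chr1", c(101L, 205L), C = c(3L, 0L), T = c(2L, 7L),
    context = c("CpG", "CHH"))
  p <- tempfile(fileext = ".tsv")
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  got <- read_cytosine_report(p)
  expect_equal(got, tab)

  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w")
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  expect_equal(read_cytosine_report(gz), tab)

  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(got <- read_cytosine_report(empty), "empty")
  expect_equal(nrow(got), 0)
})

test_that("malformed report rows are rejected with their line number", {
  bad <- cyt_table("chr1", c(10L, 20L), C = c(1L, -1L), T = c(1L, 1L))
  p <- tempfile(fileext = ".tsv")
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_cytosine_report(p), "line\\(s\\) 2")

  badctx <- cyt_table("chr1", 10L, C = 1L, T = 1L, context = "CPGX")
  write.table(badctx, p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_cytosine_report(p), "line")
})

test_that("methylation level is C/(C+T) with a five-read coverage floor", {
  tab <- cyt_table("chr1", c(100L, 200L, 300L), C = c(3L, 4L, 0L), T = c(2L, 0L, 5L))
  lv <- compute_levels(tab, min_coverage = 5)
  expect_equal(lv$pos, c(100L, 300L)) # coverage-4 site dropped
  expect_equal(lv$level, c(0.6, 0))
  expect_equal(lv$coverage, c(5, 5))
  expect_true(all(lv$level * lv$coverage == c(3, 0)))
  expect_error(compute_levels(tab, min_coverage = 0), "min_coverage")
})

test_that("non-CpG contexts are excluded and strand merging pools dinucleotide counts", {
  tab <- rbind(
    cyt_table("chr1", 100L, C = 3L, T = 2L, strand = "+"),
    cyt_table("chr1", 101L, C = 2L, T = 3L, strand = "-"),
    cyt_table("chr1", 150L, C = 9L, T = 0L, context = "CHG")
  )
  sep <- compute_levels(tab)
  expect_equal(nrow(sep), 2) # CHG removed, strands separate
  mrg <- compute_levels(tab, merge_strands = TRUE)
  expect_equal(nrow(mrg), 1)
  expect_equal(mrg$level, 0.5)
  expect_equal(mrg$coverage, 10)
})

test_that("coverage filtering is monotone in the threshold", {
  set.seed(4)
  tab <- cyt_table("chr1", seq_len(200) * 3L,
    C = rbinom(200, 10, 0.5), T = rbinom(200, 10, 0.5))
  n <- sapply(1:12, function(mc) nrow(compute_levels(tab, min_coverage = mc)))
  expect_true(all(diff(n) <= 0))
})

test_that("context composition counts methylated sites per context", {
  tab <- cyt_table("chr1", seq_len(10) * 10L,
    C = rep(5L, 10), T = rep(5L, 10),
    context = c(rep("CpG", 6), rep("CHG", 2), rep("CHH", 2)))
  expect_equal(context_composition(tab, min_coverage = 5),
    c(CpG = 0.6, CHG = 0.2, CHH = 0.2))
  allcpg <- cyt_table("chr1", c(10L, 20L), C = c(1L, 2L), T = c(9L, 8L))
  expect_equal(context_composition(allcpg), c(CpG = 1, CHG = 0, CHH = 0))
  expect_error(context_composition(allcpg[0, ]), "empty")
})

test_that("on synthetic data most methylated cytosines are in CpG context", {
  sim <- sparse_dataset()
  comp <- context_composition(sim$methylomes[[1]])
  expect_gt(comp[["CpG"]], 0.9)
  expect_equal(sum(comp), 1)
})

test_that("sample merging outer-joins sites and ignores input order", {
  a <- data.frame(chrom = "chr1", pos = c(10L, 30L), level = c(0.2, 0.4),
    coverage = c(10, 10), stringsAsFactors = FALSE)
  b <- data.frame(chrom = "chr1", pos = c(30L, 50L), level = c(0.6, 0.8),
    coverage = c(5, 5), stringsAsFactors = FALSE)
  design <- data.frame(sample = c("s1", "s2"), stage = c("p21", "p28"),
    replicate = c(1, 1), stringsAsFactors = FALSE)
  mm <- merge_samples(list(s1 = a, s2 = b), design)
  expect_equal(mm$sites$pos, c(10L, 30L, 50L))
  expect_equal(mm$level[, "s1"], c(0.2, 0.4, NA))
  expect_equal(mm$level[, "s2"], c(NA, 0.6, 0.8))
  mm2 <- merge_samples(list(s2 = b, s1 = a), design)
  expect_identical(mm, mm2)
  expect_error(merge_samples(list(s1 = rbind(a, a), s2 = b), design), "duplicate site")
})

test_that("level histogram partitions [0,1] and preserves totals", {
  lev <- matrix(c(0, 0, 0, seq(0.025, 0.975, by = 0.05)), ncol = 1,
    dimnames = list(NULL, "s1"))
  mm0 <- mm_from_levels(lev[1:3, , drop = FALSE])
  expect_equal(level_histogram(mm0)[, 1], c(3, rep(0, 19)))
  mmu <- mm_from_levels(lev[4:23, , drop = FALSE])
  expect_equal(level_histogram(mmu)[, 1], rep(1, 20))
  run <- default_run()
  h <- level_histogram(run$meth_matrix)
  expect_equal(colSums(h), colSums(!is.na(run$meth_matrix$level)),
    ignore_attr = TRUE)
})

test_that("low/medium/high classification uses closed boundaries", {
  mm <- mm_from_levels(matrix(c(0.25, 0.5, 0.75), ncol = 1,
    dimnames = list(NULL, "s1")))
  expect_equal(classify_sites(mm)[, 1],
    c(low = 1 / 3, medium = 1 / 3, high = 1 / 3))
  mm9 <- mm_from_levels(matrix(rep(0.9, 4), ncol = 1, dimnames = list(NULL, "s1")))
  expect_equal(classify_sites(mm9)[, 1], c(low = 0, medium = 0, high = 1))
  run <- default_run()
  cls <- classify_sites(run$meth_matrix)
  expect_equal(colSums(cls), rep(1, ncol(cls)), ignore_attr = TRUE)
  expect_true(all(cls["high", ] > cls["medium", ]))
})

test_that("histogram low bins agree with the low class under a shared convention", {
  run <- default_run()
  h <- level_histogram(run$meth_matrix)
  lev <- run$meth_matrix$level
  for (j in seq_len(ncol(h))) {
    expect_equal(sum(h[1:5, j]), sum(lev[, j] < 0.25, na.rm = TRUE))
  }
})

test_that("pairwise sample correlations behave on constructed inputs", {
  set.seed(2)
  v <- runif(50)
  mm <- mm_from_levels(cbind(s1 = v, s2 = v, s3 = 1 - v))
  pc <- pairwise_sample_correlation(mm)
  expect_equal(diag(pc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(pc["s1", "s2"], 1)
  expect_equal(pc["s1", "s3"], -1)
  expect_equal(pc, t(pc))
  # fewer than 2 common sites -> flagged NA
  lv <- cbind(s1 = c(0.1, NA, NA), s2 = c(NA, 0.5, 0.6))
  expect_warning(pc2 <- pairwise_sample_correlation(mm_from_levels(lv)), "common sites")
  expect_true(is.na(pc2["s1", "s2"]))
})

test_that("replicates correlate more strongly within a stage than across stages", {
  run <- default_run()
  pc <- pairwise_sample_correlation(run$meth_matrix)
  st <- run$meth_matrix$design$stage
  within <- across <- c()
  for (i in 1:(length(st) - 1)) {
    for (j in (i + 1):length(st)) {
      if (st[i] == st[j]) within <- c(within, pc[i, j]) else across <- c(across, pc[i, j])
    }
  }
  expect_gt(mean(within), mean(across))
})

test_that("methylation PCA separates stages and reports bounded variances", {
  mm2 <- mm_from_levels(cbind(s1 = runif(30), s2 = runif(30)))
  mm2$level[, 2] <- mm2$level[, 1]
  p <- methylation_pca(mm2, 1)
  expect_lt(p$explained_variance[1], 1e-20)
  run <- default_run()
  p <- methylation_pca(run$meth_matrix, 3)
  expect_true(all(diff(p$explained_variance) <= 1e-8))
  expect_lte(sum(p$explained_variance), p$total_variance + 1e-8)
  sil <- mean_silhouette(p$scores[, 1:2], run$meth_matrix$design$stage)
  expect_gt(sil, 0)
  expect_error(methylation_pca(mm_from_levels(cbind(s1 = 0.5, s2 = 0.1)), 5),
    "complete-case")
})
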