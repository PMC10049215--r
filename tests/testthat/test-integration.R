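test_that("expression strata form a deterministic tertile partition", {
  design <- default_design()
  tpm <- matrix(rep(c(9, 5, 1, 8, 4, 2, 7, 6, 3), 9), 9, 9, byrow = FALSE,
    dimnames = list(paste0("g", 1:9), design$sample))
  st <- expression_strata(tpm, design, "p21")
  expect_equal(sort(unname(table(st))), c(3, 3, 3), ignore_attr = TRUE)
  expect_equal(unname(st["g3"]), "low")
  expect_equal(unname(st["g1"]), "high")
  # ties resolve deterministically and still partition
  tie <- matrix(1, 6, 9, dimnames = list(paste0("g", 1:6), design$sample))
  stt <- expression_strata(tie, design, "p21")
  expect_equal(unname(table(stt)), c(2, 2, 2), ignore_attr = TRUE)
})

test_that("metagene bins map sites to the 20/100/20 layout by strand", {
  gene <- data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = 10001L, end = 11000L, tss = 10001L, tes = 11000L,
    length = 1000L, stringsAsFactors = FALSE
  )
  lv <- matrix(c(0.1, 0.9, 0.5), 3, 1, dimnames = list(NULL, "s1"))
  mm <- mm_from_levels(lv)
  mm$sites <- data.frame(
    chrom = "chr1",
    pos = c(10006L, 9999L, 11200L), # body bin 1, upstream bin 20, downstream bin 1
    stringsAsFactors = FALSE
  )
  prof <- metagene_profile(mm, gene, c(g1 = "high"), flank = 5000)
  expect_equal(dim(prof)[1], 140)
  expect_equal(prof[21, "high", "s1"], 0.1) # TSS+5 -> first body bin
  expect_equal(prof[20, "high", "s1"], 0.9) # 2 bp upstream -> last upstream bin
  expect_equal(prof[121, "high", "s1"], 0.5) # just past TES -> first downstream bin

  # minus-strand gene: same sites mirror to the symmetric bins
  gene$strand <- "-"; gene$tss <- 11000L; gene$tes <- 10001L
  prof2 <- metagene_profile(mm, gene, c(g1 = "high"), flank = 5000)
  expect_equal(prof2[120, "high", "s1"], 0.1) # now last body bin
  expect_equal(prof2[121, "high", "s1"], 0.9) # now just downstream
  expect_equal(prof2[20, "high", "s1"], 0.5) # now closest upstream bin
})

test_that("highly expressed genes show the TSS methylation dip", {
  run <- default_run()
  prof <- run$metagene
  expect_equal(dim(prof)[1], 140)
  tss_bins <- 15:25
  hi <- mean(prof[tss_bins, "high", ], na.rm = TRUE)
  lo <- mean(prof[tss_bins, "low", ], na.rm = TRUE)
  expect_lt(hi, lo)
})

test_that("promoter methylation pools counts within the promoter window", {
  gene <- data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+", start = 5000L, end = 6000L,
    tss = 5000L, tes = 6000L, length = 1001L, stringsAsFactors = FALSE
  )
  mm <- mm_from_levels(
    matrix(c(0.6, 1, 0), 3, 1, dimnames = list(NULL, "s1")),
    coverage = matrix(c(5, 10, 10), 3, 1)
  )
  mm$sites <- data.frame(chrom = "chr1", pos = c(4000L, 5500L, 6500L),
    stringsAsFactors = FALSE)
  pm1 <- promoter_methylation(mm, gene, min_sites = 1)
  # pooled: (3 + 10 + 0) / (5 + 10 + 10)
  expect_equal(unname(pm1["g1", "s1"]), 13 / 25)
  pm4 <- promoter_methylation(mm, gene, min_sites = 4)
  expect_true(is.na(pm4["g1", "s1"]))
})

test_that("gene correlations handle perfect, constant, and mismatched inputs", {
  design <- default_design()
  prom <- matrix(seq(0.9, 0.1, length.out = 9), 1, 9,
    dimnames = list("g1", design$sample))
  tpm <- matrix(2^seq(1, 9), 1, 9, dimnames = list("g1", design$sample))
  rec <- correlate_genes(prom, tpm, design, log2_expr = FALSE)
  expect_lt(rec$pearson_r, -0.475)
  expect_equal(rec$n_points, 9)
  # perfectly anti-monotone linear pair on the log scale
  lin <- matrix(2^(1:9) - 1, 1, 9, dimnames = list("g1", design$sample))
  lin_rec <- correlate_genes(prom, lin, design)
  expect_equal(lin_rec$pearson_r, -1)
  # constant methylation excluded
  prom2 <- rbind(prom, g2 = rep(0.5, 9))
  tpm2 <- rbind(tpm, g2 = 2^seq(1, 9))
  rec2 <- correlate_genes(prom2, tpm2, design)
  expect_false("g2" %in% rec2$gene_id)
  expect_equal(attr(rec2, "n_excluded"), 1)
  # stage-mean unit uses three points
  rec3 <- correlate_genes(prom, tpm, design, unit = "stage_means")
  expect_equal(rec3$n_points, 3)
  colnames(tpm) <- paste0("x", 1:9)
  expect_error(correlate_genes(prom, tpm, design), "different samples")
})

test_that("the PNG cutoff is strict", {
  rec <- data.frame(
    gene_id = c("a", "b", "c"),
    pearson_r = c(-0.475, -0.476, 0.2),
    n_points = 9, stringsAsFactors = FALSE
  )
  expect_equal(identify_pngs(rec), "b")
  expect_equal(identify_pngs(rec, cutoff = 0), c("a", "b"))
  # PNG count non-increasing as the cutoff moves toward -1
  run <- default_run()
  cuts <- seq(-0.2, -0.9, by = -0.1)
  n <- sapply(cuts, function(ct) length(identify_pngs(run$correlation, ct)))
  expect_true(all(diff(n) <= 0))
})

test_that("DM-DEGs are the PNG/DEG intersection", {
  expect_equal(identify_dm_degs(c("a", "b"), c("c", "d")), character())
  expect_equal(identify_dm_degs(c("a", "b"), c("b", "a", "z")), c("a", "b"))
})

test_that("planted DM-DEG promoters correlate strongly negatively", {
  run <- default_run()
  rec <- run$correlation
  planted <- run$dataset$truth$planted_dmdegs$gene_id
  r <- rec$pearson_r[match(planted, rec$gene_id)]
  expect_gte(mean(r < -0.475, na.rm = TRUE), 0.9)
})

test_that("hierarchical clustering of trajectories is stable and recovers archetypes", {
  design <- default_design()
  set.seed(12)
  up <- matrix(rnbinom(25 * 9, mu = rep(rep(c(10, 40, 160), each = 3), each = 25), size = 50), 25, 9)
  dn <- matrix(rnbinom(25 * 9, mu = rep(rep(c(160, 40, 10), each = 3), each = 25), size = 50), 25, 9)
  tpm <- rbind(up, dn)
  dimnames(tpm) <- list(paste0("g", 1:50), design$sample)
  cl <- cluster_dm_degs(tpm, design, rownames(tpm), k = 2)
  expect_gte(ari(cl, rep(1:2, each = 25)), 0.95)
  # order invariance
  perm <- sample(rownames(tpm))
  cl2 <- cluster_dm_degs(tpm, design, perm, k = 2)
  expect_equal(cl2[names(cl)], cl)
  # k = n gives singletons; k > n errors
  cl3 <- cluster_dm_degs(tpm, design, paste0("g", 1:6), k = 6)
  expect_equal(length(unique(cl3)), 6)
  expect_error(cluster_dm_degs(tpm, design, paste0("g", 1:3), k = 6), "exceeds")
})

test_that("recovery evaluation scores perfect and empty predictions correctly", {
  truth <- sparse_dataset()$truth
  perfect <- list(
    dmrs = truth$planted_dmrs[, c("chrom", "start", "end", "direction", "contrast")],
    degs = truth$planted_degs$gene_id,
    dmdegs = truth$planted_dmdegs$gene_id
  )
  rec <- evaluate_recovery(perfect, truth)
  expect_equal(rec$precision, rep(1, 3))
  expect_equal(rec$recall, rep(1, 3))
  expect_equal(rec$f1, rep(1, 3))
  empty <- list(dmrs = perfect$dmrs[0, ], degs = character(), dmdegs = character())
  rec0 <- evaluate_recovery(empty, truth)
  expect_equal(rec0$recall, rep(0, 3))
  expect_equal(rec0$precision, rep(0, 3))
  expect_true(attr(rec0, "empty_prediction"))
})

test_that("the end-to-end pipeline meets its planted-recovery bars", {
  run <- default_run()
  rec <- run$recovery
  expect_gte(rec$f1[rec$category == "dmdeg"], 0.8)
  expect_gte(rec$recall[rec$category == "dmr"], 0.9)
  expect_gte(rec$precision[rec$category == "deg"], 0.9)
})
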