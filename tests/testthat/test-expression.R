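test_that("TPM normalization matches hand arithmetic and sums to 1e6", {
  counts <- matrix(c(10, 30), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- counts_to_tpm(counts, c(g1 = 1000, g2 = 1000))
  expect_equal(tpm[, 1], c(g1 = 250000, g2 = 750000))
  counts2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm2 <- counts_to_tpm(counts2, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm2[1, 1] / tpm2[2, 1]), 2)
  single <- counts_to_tpm(matrix(5, 1, 1, dimnames = list("g1", "s1")), c(g1 = 500))
  expect_equal(unname(single[1, 1]), 1e6)
  set.seed(9)
  cm <- matrix(rpois(300, 40), 30, 10,
    dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  tt <- counts_to_tpm(cm, setNames(sample(200:3000, 30), paste0("g", 1:30)))
  expect_equal(colSums(tt), rep(1e6, 10), ignore_attr = TRUE)
  expect_error(counts_to_tpm(cm * 0, setNames(rep(1000, 30), paste0("g", 1:30))),
    "zero total")
})

test_that("expressed genes are those reaching TPM 0.5 in any sample", {
  tpm <- matrix(c(0.5, 0, 0.2, 0.4), 2, 2,
    dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(define_expressed(tpm), "g1") # boundary 0.5 kept
  expect_equal(define_expressed(tpm, threshold = 0), c("g1", "g2"))
})

test_that("identical groups yield no DEG and flags are pure functions of the stats", {
  design <- default_design()
  set.seed(5)
  base <- matrix(rpois(200 * 3, 100), 200, 3)
  counts <- cbind(base, base, base)
  dimnames(counts) <- list(paste0("g", 1:200), design$sample)
  res <- deg_test(counts, design, c("p21", "p28"))
  expect_equal(res$log2fc, rep(0, 200))
  expect_false(any(res$is_deg))
  run_res <- default_run()$deg_results[[1]]
  expect_equal(run_res$is_deg,
    run_res$padj < 0.05 & abs(run_res$log2fc) >= 1)
})

test_that("the DEG test is powered for 4-fold changes and calibrated under the null", {
  design <- default_design()[1:6, ]
  set.seed(17)
  n_null <- 3000; n_alt <- 200
  mu <- exp(rnorm(n_null + n_alt, log(150), 0.8))
  fc <- c(rep(1, n_null), rep(4, n_alt))
  counts <- cbind(
    matrix(rnbinom(3 * (n_null + n_alt), mu = mu, size = 20), ncol = 3),
    matrix(rnbinom(3 * (n_null + n_alt), mu = mu * fc, size = 20), ncol = 3)
  )
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_null + n_alt)), design$sample)
  res <- deg_test(counts, design, c("p21", "p28"))
  alt <- res$gene_id %in% sprintf("g%04d", n_null + seq_len(n_alt))
  expect_gte(mean(res$is_deg[alt]), 0.95) # power at 4-fold
  typeI <- mean(res$p_value[!alt] < 0.05)
  expect_lt(abs(typeI - 0.05), 0.01) # raw p calibration
  expect_equal(res$log2fc[alt], rep(2, n_alt), tolerance = 0.75)
})

test_that("all-zero genes are excluded from testing", {
  design <- default_design()
  counts <- matrix(10, 4, 9, dimnames = list(paste0("g", 1:4), design$sample))
  counts[2, ] <- 0
  res <- deg_test(counts, design, c("p21", "p28"))
  expect_false("g2" %in% res$gene_id)
})

test_that("peak stages follow the stage-mean argmax with earliest-stage ties", {
  design <- default_design()
  tpm <- rbind(
    g1 = rep(c(5, 1, 1), each = 3),
    g2 = rep(c(1, 1, 1), each = 3),
    g3 = rep(c(1, 2, 9), each = 3)
  )
  colnames(tpm) <- design$sample
  suppressMessages(pk <- assign_peak_stage(c("g1", "g2", "g3"), tpm, design))
  expect_equal(pk$peak_stage, c("p21", "p21", "p35"))
  expect_equal(pk$tie, c(FALSE, TRUE, FALSE))
  run <- default_run()
  truth <- run$dataset$truth$planted_degs
  p28_true <- truth$gene_id[truth$peak_stage == "p28"]
  got <- run$peak_stages
  recovered <- got$peak_stage[match(p28_true, got$gene_id)]
  expect_gte(mean(recovered == "p28", na.rm = TRUE), 0.95)
})

test_that("quartile classes use closed quartile boundaries", {
  design <- default_design()
  tpm <- matrix(rep(1:9, 9), 9, 9, dimnames = list(paste0("g", 1:9), design$sample))
  cls <- quartile_classes(tpm, design, "p21")
  q <- quantile(1:9, c(0.25, 0.75))
  expect_equal(unname(cls[paste0("g", q[2])]), "high") # exactly upper quartile
  expect_equal(unname(cls[paste0("g", q[1])]), "low") # exactly lower quartile
  flat <- matrix(3, 4, 9, dimnames = list(paste0("g", 1:4), design$sample))
  expect_message(cf <- quartile_classes(flat, design, "p21"), "degenerate")
  expect_true(all(cf %in% c("low", "medium", "high")))
})

test_that("fuzzy c-means satisfies its invariants and recovers planted groups", {
  set.seed(3)
  g1 <- matrix(rnorm(60 * 3, mean = rep(c(-1, 0, 1), each = 60), sd = 0.1), 60, 3)
  g2 <- matrix(rnorm(60 * 3, mean = rep(c(1, 0, -1), each = 60), sd = 0.1), 60, 3)
  traj <- rbind(g1, g2)
  rownames(traj) <- paste0("g", seq_len(nrow(traj)))
  fit <- soft_cluster(traj, c = 2, m = 1.25, seed = 42)
  expect_equal(rowSums(fit$membership), rep(1, 120), ignore_attr = TRUE)
  expect_true(all(diff(fit$objective) <= 1e-8))
  hard <- max.col(fit$membership)
  truth <- rep(1:2, each = 60)
  expect_gte(ari(hard, truth), 0.95)
  # determinism under a fixed seed
  expect_identical(fit, soft_cluster(traj, c = 2, m = 1.25, seed = 42))
  # single cluster: all memberships 1
  one <- soft_cluster(traj, c = 1, m = 1.25, seed = 1)
  expect_equal(unname(one$membership[, 1]), rep(1, 120))
  # zero-variance genes are excluded and reported
  traj2 <- rbind(traj, gflat = c(2, 2, 2))
  fit2 <- soft_cluster(traj2, c = 2, m = 1.25, seed = 1)
  expect_equal(fit2$excluded, "gflat")
})

test_that("our c-means partition agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  traj <- rbind(
    matrix(rnorm(150, rep(c(-1, 0, 1), each = 50), 0.15), 50, 3),
    matrix(rnorm(150, rep(c(1, -1, 0), each = 50), 0.15), 50, 3)
  )
  rownames(traj) <- paste0("g", 1:100)
  z <- t(scale(t(traj)))
  ours <- soft_cluster(z, c = 2, m = 1.25, seed = 4, standardize = FALSE)
  ref <- e1071::cmeans(z, centers = 2, m = 1.25)
  expect_gte(ari(max.col(ours$membership), ref$cluster), 0.95)
})
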