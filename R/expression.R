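#' Convert raw counts to TPM
#'
#' TPM_gs = 1e6 * (counts_gs / length_g) / sum_g (counts_gs / length_g);
#' every column sums to 1e6 over genes with a defined length.
#'
#' @param counts genes x samples non-negative matrix.
#' @param gene_lengths named vector of gene lengths (bp), matching rows.
#' @return TPM matrix with the same dimnames.
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  lens <- gene_lengths[rownames(counts)]
  if (any(is.na(lens))) stop("missing gene length for some rows")
  if (any(lens <= 0)) stop("gene lengths must be > 0")
  rate <- counts / lens
  tot <- colSums(rate)
  if (any(tot == 0)) stop("zero total rate in sample(s): ",
    paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(rate, 2, tot, "/") * 1e6
}

#' Expressed-gene filter
#'
#' A gene is expressed when its TPM reaches `threshold` in at least one
#' sample.
#'
#' @param tpm TPM matrix.
#' @param threshold TPM cutoff (default 0.5).
#' @return character vector of expressed gene ids.
#' @export
define_expressed <- function(tpm, threshold = 0.5) {
  rownames(tpm)[apply(tpm, 1, max) >= threshold]
}

# median-of-ratios size factors (reference = geometric mean over samples,
# computed on genes positive in all samples)
estimate_size_factors <- function(counts) {
  lg <- log(counts)
  ok <- is.finite(rowSums(lg))
  if (!any(ok)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
  ref <- rowMeans(lg[ok, , drop = FALSE])
  sf <- apply(lg[ok, , drop = FALSE], 2, function(c) exp(median(c - ref)))
  sf / exp(mean(log(sf)))
}

#' Differential expression test between two stages
#'
#' Per-gene negative-binomial Wald test on median-of-ratios-normalized
#' counts: log2 fold change of stage means with pseudocount 0.5, and a
#' method-of-moments dispersion estimate moderated toward the across-gene
#' mean dispersion (weight `1 - dispersion_shrink` on the gene-wise
#' estimate, floored at a small constant). With few replicates the raw
#' gene-wise estimate is too noisy for a calibrated Wald test; moderation
#' restores near-nominal type-I error while leaving small p-values
#' attainable for strong effects. P-values are BH-adjusted across all
#' tested genes; a gene is flagged as a DEG when padj < `alpha` and
#' |log2FC| >= `lfc_cutoff`. Genes with zero counts in every sample of
#' both groups are excluded from testing.
#'
#' @param counts genes x samples matrix.
#' @param design data frame sample/stage/replicate.
#' @param contrast `c(A, B)`; log2FC is B relative to A.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_cutoff |log2FC| cutoff (default 1).
#' @param dispersion_shrink weight of the across-gene mean in the moderated
#'   dispersion (default 0.75; 0 = pure gene-wise).
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @return data frame gene_id, base_mean, log2fc, p_value, padj, is_deg.
#' @export
deg_test <- function(counts, design, contrast, alpha = 0.05, lfc_cutoff = 1,
                     dispersion_shrink = 0.75, dispersion_floor = 1e-8) {
  stopifnot(length(contrast) == 2, all(contrast %in% design$stage))
  sa <- design$sample[design$stage == contrast[1]]
  sb <- design$sample[design$stage == contrast[2]]
  if (length(sa) < 2 || length(sb) < 2) stop("need >= 2 replicates per stage")
  sub <- counts[, c(sa, sb), drop = FALSE]
  keep <- rowSums(sub) > 0
  x <- sub[keep, , drop = FALSE]
  sf <- estimate_size_factors(x)
  nx <- sweep(x, 2, sf, "/")
  A <- nx[, sa, drop = FALSE]
  B <- nx[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, var); vB <- apply(B, 1, var)
  alpha_gene <- pmax(((vA - mA) / mA^2 + (vB - mB) / mB^2) / 2, 0)
  alpha_gene[!is.finite(alpha_gene)] <- NA_real_
  alpha_bar <- mean(alpha_gene, na.rm = TRUE)
  if (!is.finite(alpha_bar)) alpha_bar <- 0
  alpha_gene[is.na(alpha_gene)] <- alpha_bar
  alpha_hat <- pmax(
    (1 - dispersion_shrink) * alpha_gene + dispersion_shrink * alpha_bar,
    dispersion_floor
  )
  ps <- 0.5
  lfc <- log2(mB + ps) - log2(mA + ps)
  se_nat <- sqrt(
    1 / (na * (mA + ps)) + alpha_hat / na +
      1 / (nb * (mB + ps)) + alpha_hat / nb
  )
  zstat <- (lfc * log(2)) / se_nat
  p <- 2 * pnorm(-abs(zstat))
  padj <- p.adjust(p, method = "BH")
  res <- data.frame(
    gene_id = rownames(x), base_mean = (mA + mB) / 2, log2fc = lfc,
    p_value = p, padj = padj,
    is_deg = padj < alpha & abs(lfc) >= lfc_cutoff,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Stage of peak expression for DEGs
#'
#' The peak stage is the argmax of stage-mean TPM; exact ties resolve to the
#' earliest stage and are flagged.
#'
#' @param gene_ids genes to assign (typically the DEG union across
#'   successive contrasts).
#' @param tpm TPM matrix.
#' @param design design data frame.
#' @return data frame gene_id, peak_stage, tie (logical).
#' @export
assign_peak_stage <- function(gene_ids, tpm, design) {
  sm <- stage_means(tpm[gene_ids, , drop = FALSE], design)
  peak <- stage_levels()[apply(sm, 1, which.max)]
  tie <- apply(sm, 1, function(v) sum(v == max(v)) > 1)
  if (any(tie)) message(sum(tie), " gene(s) with tied stage means; earliest stage used")
  data.frame(gene_id = gene_ids, peak_stage = peak, tie = tie,
    stringsAsFactors = FALSE, row.names = NULL)
}

# genes x stages matrix of mean TPM per stage
stage_means <- function(tpm, design) {
  stages <- intersect(stage_levels(), unique(design$stage))
  out <- sapply(stages, function(s) {
    rowMeans(tpm[, design$sample[design$stage == s], drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(tpm), dimnames = list(rownames(tpm), stages))
  out
}

#' Quartile expression classes at a stage
#'
#' High: stage-mean TPM >= upper quartile; low: <= lower quartile; medium:
#' strictly between. With degenerate quartiles (upper == lower) the high
#' rule wins and a message is emitted.
#'
#' @param tpm TPM matrix (expressed genes).
#' @param design design data frame.
#' @param stage stage id.
#' @return named character vector of classes per gene.
#' @export
quartile_classes <- function(tpm, design, stage) {
  sm <- stage_means(tpm, design)[, stage]
  q <- quantile(sm, c(0.25, 0.75))
  if (q[1] == q[2]) message("degenerate quartiles at stage ", stage)
  cls <- ifelse(sm >= q[2], "high", ifelse(sm <= q[1], "low", "medium"))
  setNames(cls, rownames(tpm))
}

# squared euclidean distances between rows of x and rows of centers
sq_dist <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
}

#' Fuzzy c-means clustering of expression trajectories
#'
#' Standard fuzzy c-means on z-standardized stage-mean trajectories:
#' memberships u_gk proportional to (1/d_gk^2)^(1/(m-1)), centers the
#' u^m-weighted means, iterated until the largest center shift falls below
#' `tol` or `max_iter` iterations. Centers are initialized by k-means++
#' style seeded sampling, so a fixed seed reproduces the clustering exactly.
#' Genes with zero variance across stages cannot be standardized and are
#' excluded (reported via the `excluded` element).
#'
#' @param traj genes x stages numeric matrix of trajectories.
#' @param c number of clusters.
#' @param m fuzzifier (> 1); default 1.25.
#' @param seed integer seed for center initialization.
#' @param standardize z-score each row first (default TRUE).
#' @param max_iter,tol iteration controls.
#' @return list of class `soft_clustering`: `membership` (genes x c, rows
#'   sum to 1), `centers` (c x stages), `objective` (per-iteration trace,
#'   non-increasing), `excluded` (gene ids dropped).
#' @export
soft_cluster <- function(traj, c = 6, m = 1.25, seed = 1, standardize = TRUE,
                         max_iter = 500, tol = 1e-6) {
  stopifnot(c >= 1, m > 1)
  x <- as.matrix(traj)
  sds <- apply(x, 1, sd)
  excluded <- rownames(x)[sds == 0 | is.na(sds)]
  x <- x[sds > 0 & !is.na(sds), , drop = FALSE]
  if (nrow(x) < c) stop("fewer usable genes than clusters")
  if (standardize) x <- t(scale(t(x)))
  with_seed(seed, {
    # k-means++ seeding
    centers <- x[sample.int(nrow(x), 1), , drop = FALSE]
    while (nrow(centers) < c) {
      d2 <- apply(sq_dist(x, centers), 1, min)
      d2 <- pmax(d2, 0)
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / nrow(x), nrow(x))
      centers <- rbind(centers, x[sample.int(nrow(x), 1, prob = prob), ])
    }
    obj <- numeric()
    for (it in seq_len(max_iter)) {
      d2 <- pmax(sq_dist(x, centers), 0)
      u <- matrix(0, nrow(x), c)
      zero <- d2 < 1e-12
      has_zero <- rowSums(zero) > 0
      w <- (1 / pmax(d2, 1e-300))^(1 / (m - 1))
      u <- w / rowSums(w)
      if (any(has_zero)) {
        u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
          rowSums(zero[has_zero, , drop = FALSE])
      }
      obj <- c(obj, sum(u^m * d2))
      um <- u^m
      new_centers <- (t(um) %*% x) / colSums(um)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol) break
    }
    rownames(u) <- rownames(x)
    rownames(centers) <- paste0("cluster", seq_len(c))
    colnames(centers) <- colnames(x)
    structure(
      list(membership = u, centers = centers, objective = obj,
        excluded = excluded, m = m, iterations = it),
      class = "soft_clustering"
    )
  })
}
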