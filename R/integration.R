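#' Expression strata at a stage
#'
#' Rank-based tertile split (or `n_strata`-tile) of stage-mean TPM; ties are
#' resolved deterministically by rank order, so the groups always partition
#' the genes.
#'
#' @param tpm TPM matrix of expressed genes.
#' @param design design data frame.
#' @param stage stage id.
#' @param n_strata number of strata (default 3: low/medium/high).
#' @return named character vector (`low` ... `high`) per gene.
#' @export
expression_strata <- function(tpm, design, stage, n_strata = 3) {
  sm <- stage_means(tpm, design)[, stage]
  r <- rank(sm, ties.method = "first")
  idx <- ceiling(r / (length(r) / n_strata))
  labels <- if (n_strata == 3) c("low", "medium", "high") else paste0("stratum", seq_len(n_strata))
  setNames(labels[idx], rownames(tpm))
}

#' Metagene methylation profile stratified by expression
#'
#' Averages CpG methylation over 140 ordered bins spanning the upstream
#' flank (20 bins of `flank`/20 bp), the gene body (100 bins of length/100
#' bp each, so short genes use fractional spans), and the downstream flank
#' (20 bins), oriented 5' to 3' by gene strand. Within each expression
#' stratum and sample, a bin's value is the mean level of all CpGs of all
#' genes falling in it; bins with no covered CpG are NA. A CpG overlapping
#' several genes' spans contributes once per gene context.
#'
#' @param mm a `meth_matrix`.
#' @param genes gene data frame.
#' @param strata named vector from [expression_strata()].
#' @param flank flank size in bp (default 5000).
#' @param n_flank,n_body bin counts (defaults 20/100/20).
#' @return array `[bin, stratum, sample]` with 140 rows; bin spans attached
#'   as attribute `bin_class` (upstream/body/downstream).
#' @export
metagene_profile <- function(mm, genes, strata, flank = 5000,
                             n_flank = 20, n_body = 100) {
  genes <- genes[genes$gene_id %in% names(strata), , drop = FALSE]
  n_bins <- 2 * n_flank + n_body
  flank_w <- flank / n_flank
  strata_levels <- intersect(c("low", "medium", "high"), unique(strata))
  if (!length(strata_levels)) strata_levels <- sort(unique(strata))
  samples <- colnames(mm$level)

  span_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - flank), genes$end + flank)
  )
  site_gr <- GenomicRanges::GRanges(mm$sites$chrom, IRanges::IRanges(mm$sites$pos, mm$sites$pos))
  ov <- GenomicRanges::findOverlaps(site_gr, span_gr)
  si <- queryHits(ov)
  gi <- subjectHits(ov)
  pos <- mm$sites$pos[si]
  gstart <- genes$start[gi]
  gend <- genes$end[gi]
  glen <- gend - gstart + 1
  plus <- genes$strand[gi] == "+"

  # offset from the 5' end of the profiled span, in three segments
  upstream <- ifelse(plus, pos < gstart, pos > gend)
  downstream <- ifelse(plus, pos > gend, pos < gstart)
  bin <- integer(length(si))
  updist <- ifelse(plus, gstart - pos, pos - gend) # 1..flank when upstream
  bin[upstream] <- n_flank - pmin(floor((updist[upstream] - 1) / flank_w), n_flank - 1)
  body_off <- ifelse(plus, pos - gstart, gend - pos) # 0..len-1 in body
  inbody <- !upstream & !downstream
  bin[inbody] <- n_flank + pmin(floor(body_off[inbody] / glen[inbody] * n_body), n_body - 1) + 1
  dndist <- ifelse(plus, pos - gend, gstart - pos) # 1..flank when downstream
  bin[downstream] <- n_flank + n_body +
    pmin(floor((dndist[downstream] - 1) / flank_w), n_flank - 1) + 1

  strat <- strata[genes$gene_id[gi]]
  out <- array(NA_real_, dim = c(n_bins, length(strata_levels), length(samples)),
    dimnames = list(NULL, strata_levels, samples))
  for (s in strata_levels) {
    sel <- strat == s
    if (!any(sel)) next
    b <- bin[sel]
    lv <- mm$level[si[sel], , drop = FALSE]
    for (j in seq_along(samples)) {
      v <- lv[, j]
      ok <- !is.na(v)
      if (!any(ok)) next
      sums <- rowsum(v[ok], b[ok])
      cnts <- rowsum(rep(1, sum(ok)), b[ok])
      out[as.integer(rownames(sums)), s, j] <- sums[, 1] / cnts[, 1]
    }
  }
  attr(out, "bin_class") <- rep(c("upstream", "body", "downstream"),
    c(n_flank, n_body, n_flank))
  out
}

#' Per-gene promoter methylation
#'
#' Coverage-weighted promoter mean: pooled methylated reads over pooled
#' total reads (sum C / sum (C+T)) across retained CpGs in TSS +/-
#' `promoter_window`. Samples covering fewer than `min_sites` CpGs in the
#' window get NA.
#'
#' @param mm a `meth_matrix`.
#' @param genes gene data frame.
#' @param promoter_window half-width of the promoter around the TSS (bp).
#' @param min_sites minimum covered CpGs per sample (default 3).
#' @return genes x samples matrix of promoter levels.
#' @export
promoter_methylation <- function(mm, genes, promoter_window = 3000, min_sites = 3) {
  prom_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - promoter_window), genes$tss + promoter_window)
  )
  site_gr <- GenomicRanges::GRanges(mm$sites$chrom, IRanges::IRanges(mm$sites$pos, mm$sites$pos))
  ov <- GenomicRanges::findOverlaps(site_gr, prom_gr)
  si <- queryHits(ov)
  gi <- subjectHits(ov)
  C <- mm$level * mm$coverage
  Tt <- mm$coverage
  out <- matrix(NA_real_, nrow(genes), ncol(mm$level),
    dimnames = list(genes$gene_id, colnames(mm$level)))
  if (!length(si)) return(out)
  for (j in seq_len(ncol(out))) {
    cj <- C[si, j]
    tj <- Tt[si, j]
    ok <- !is.na(cj)
    if (!any(ok)) next
    csum <- rowsum(cj[ok], gi[ok])
    tsum <- rowsum(tj[ok], gi[ok])
    nsit <- rowsum(rep(1, sum(ok)), gi[ok])
    g <- as.integer(rownames(csum))
    val <- csum[, 1] / tsum[, 1]
    val[nsit[, 1] < min_sites] <- NA_real_
    out[g, j] <- val
  }
  out
}

#' Promoter methylation / expression correlation per gene
#'
#' Pearson correlation between promoter methylation and (log2-transformed)
#' expression, either over all samples or over stage means. Genes with
#' fewer than `min_points` defined pairs or zero variance on either axis
#' are excluded (counted in attribute `n_excluded`).
#'
#' @param prom genes x samples promoter-methylation matrix.
#' @param tpm TPM matrix (same samples).
#' @param design design data frame.
#' @param unit `"samples"` (default, one point per sample) or
#'   `"stage_means"` (one point per stage).
#' @param log2_expr correlate against log2(TPM + 1) (default TRUE).
#' @param min_points minimum paired points (default 3).
#' @return data frame gene_id, pearson_r, n_points.
#' @export
correlate_genes <- function(prom, tpm, design, unit = c("samples", "stage_means"),
                            log2_expr = TRUE, min_points = 3) {
  unit <- match.arg(unit)
  common <- intersect(rownames(prom), rownames(tpm))
  if (!setequal(colnames(prom), colnames(tpm))) {
    stop("promoter and expression matrices cover different samples")
  }
  e <- tpm[common, colnames(prom), drop = FALSE]
  if (log2_expr) e <- log2(e + 1)
  p <- prom[common, , drop = FALSE]
  if (unit == "stage_means") {
    p <- stage_means(p, design)
    e <- stage_means(e, design)
  }
  n_excluded <- 0L
  res <- lapply(seq_along(common), function(i) {
    ok <- !is.na(p[i, ]) & !is.na(e[i, ])
    if (sum(ok) < min_points) return(NULL)
    if (sd(p[i, ok]) == 0 || sd(e[i, ok]) == 0) return(NULL)
    data.frame(
      gene_id = common[i], pearson_r = cor(p[i, ok], e[i, ok]),
      n_points = sum(ok), stringsAsFactors = FALSE
    )
  })
  kept <- !vapply(res, is.null, TRUE)
  out <- if (any(kept)) do.call(rbind, res[kept]) else data.frame(
    gene_id = character(), pearson_r = numeric(), n_points = integer(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(common) - nrow(out)
  out
}

#' Promoter-negative genes
#'
#' Genes whose promoter methylation / expression Pearson r is strictly below
#' the cutoff (default -0.475); r equal to the cutoff is not a PNG.
#'
#' @param records data frame from [correlate_genes()].
#' @param cutoff correlation cutoff.
#' @return character vector of PNG gene ids.
#' @export
identify_pngs <- function(records, cutoff = -0.475) {
  records$gene_id[!is.na(records$pearson_r) & records$pearson_r < cutoff]
}

#' DM-DEGs: DEGs under promoter methylation control
#'
#' @param pngs PNG gene ids.
#' @param degs DEG gene ids.
#' @return intersection, in `pngs` order.
#' @export
identify_dm_degs <- function(pngs, degs) {
  intersect(pngs, degs)
}

#' Hierarchical clustering of DM-DEG trajectories
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of
#' z-standardized stage-mean TPM trajectories, cut into `k` clusters
#' labelled C1..Ck. Labels are ordered by the cluster mean trajectory
#' (peak stage, then descending first-stage level) for stable naming.
#'
#' @param tpm TPM matrix.
#' @param design design data frame.
#' @param gene_ids DM-DEG ids to cluster.
#' @param k number of clusters (default 6).
#' @return named character vector of cluster labels per gene.
#' @export
cluster_dm_degs <- function(tpm, design, gene_ids, k = 6) {
  if (length(gene_ids) < k) stop("k exceeds the number of genes")
  sm <- stage_means(tpm[gene_ids, , drop = FALSE], design)
  z <- t(scale(t(sm)))
  z[is.na(z)] <- 0 # flat trajectories: centered zeros
  hc <- hclust(dist(z), method = "average")
  raw <- cutree(hc, k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(i) {
    colMeans(z[raw == i, , drop = FALSE])
  }))
  ord <- order(apply(centers, 1, which.max), -centers[, 1])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  setNames(paste0("C", relabel[raw]), gene_ids)
}

# reciprocal-overlap matching of called vs planted intervals (same contrast)
match_dmrs <- function(called, truth_dmrs, min_reciprocal = 0.5) {
  if (nrow(called) == 0 || nrow(truth_dmrs) == 0) {
    return(list(call_hit = logical(nrow(called)), truth_hit = logical(nrow(truth_dmrs)),
      dir_match = logical(0)))
  }
  cg <- GenomicRanges::GRanges(called$chrom, IRanges::IRanges(called$start, called$end))
  tg <- GenomicRanges::GRanges(truth_dmrs$chrom, IRanges::IRanges(truth_dmrs$start, truth_dmrs$end))
  ov <- GenomicRanges::findOverlaps(cg, tg)
  ci <- queryHits(ov)
  ti <- subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(cg)[ci], IRanges::ranges(tg)[ti]))
  ok <- w >= min_reciprocal * IRanges::width(cg)[ci] &
    w >= min_reciprocal * IRanges::width(tg)[ti]
  same_contrast <- if ("contrast" %in% names(called)) {
    called$contrast[ci] == truth_dmrs$contrast[ti]
  } else TRUE
  ok <- ok & same_contrast
  list(
    call_hit = seq_len(nrow(called)) %in% ci[ok],
    truth_hit = seq_len(nrow(truth_dmrs)) %in% ti[ok],
    dir_match = called$direction[ci[ok]] == truth_dmrs$direction[ti[ok]]
  )
}

#' Precision / recall / F1 of recovered calls against planted truth
#'
#' DMRs match a planted interval by >= 50% reciprocal overlap (and matching
#' contrast when available); gene sets match by identity. Empty predictions
#' give recall 0 and precision reported as 0 with a flag.
#'
#' Planted DM-DEG promoters also carry genuine stage-directed methylation
#' change; when `annotation` is supplied, called DMRs overlapping such a
#' promoter are excluded from the DMR precision denominator rather than
#' counted as false positives.
#'
#' @param predicted list with elements `dmrs` (data frame, optionally with a
#'   `contrast` column), `degs`, `dmdegs` (character vectors).
#' @param truth a `sim_truth`.
#' @param annotation optional [simulate_annotation()] result used to locate
#'   planted DM-DEG promoter windows.
#' @return data frame with one row per category (dmr, deg, dmdeg):
#'   precision, recall, f1, n_predicted, n_truth, plus `dmr_direction_accuracy`
#'   as an attribute.
#' @export
evaluate_recovery <- function(predicted, truth, annotation = NULL) {
  set_metrics <- function(pred, tr) {
    tp <- length(intersect(pred, tr))
    precision <- if (length(pred)) tp / length(pred) else 0
    recall <- if (length(tr)) tp / length(tr) else NA_real_
    f1 <- if (is.na(recall) || precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1,
      n_predicted = length(pred), n_truth = length(tr))
  }
  mt <- match_dmrs(predicted$dmrs, truth$planted_dmrs)
  in_prec <- rep(TRUE, nrow(predicted$dmrs))
  if (!is.null(annotation) && nrow(truth$planted_dmdegs) > 0 && nrow(predicted$dmrs) > 0) {
    g <- annotation$genes[annotation$genes$gene_id %in% truth$planted_dmdegs$gene_id, ]
    win <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(pmax(1L, g$tss - DMDEG_HALF), g$tss + DMDEG_HALF)
    )
    cg <- GenomicRanges::GRanges(
      predicted$dmrs$chrom,
      IRanges::IRanges(predicted$dmrs$start, predicted$dmrs$end)
    )
    in_prec <- mt$call_hit | !IRanges::overlapsAny(cg, win)
  }
  dmr_precision <- if (any(in_prec)) mean(mt$call_hit[in_prec]) else 0
  dmr_recall <- if (nrow(truth$planted_dmrs)) mean(mt$truth_hit) else NA_real_
  dmr_f1 <- if (is.na(dmr_recall) || dmr_precision + dmr_recall == 0) 0 else
    2 * dmr_precision * dmr_recall / (dmr_precision + dmr_recall)
  out <- rbind(
    dmr = c(dmr_precision, dmr_recall, dmr_f1, nrow(predicted$dmrs), nrow(truth$planted_dmrs)),
    deg = set_metrics(predicted$degs, truth$planted_degs$gene_id),
    dmdeg = set_metrics(predicted$dmdegs, truth$planted_dmdegs$gene_id)
  )
  out <- data.frame(
    category = rownames(out), precision = out[, 1], recall = out[, 2],
    f1 = out[, 3], n_predicted = out[, 4], n_truth = out[, 5],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "dmr_direction_accuracy") <-
    if (length(mt$dir_match)) mean(mt$dir_match) else NA_real_
  attr(out, "empty_prediction") <- nrow(predicted$dmrs) == 0 ||
    length(predicted$degs) == 0 || length(predicted$dmdegs) == 0
  out
}
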