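#' Run the full pipeline on a synthetic dataset
#'
#' Generates (or accepts) a synthetic dataset, then runs every analysis
#' stage: per-sample methylation levels with coverage filtering, sample
#' merging, feature index and site assignment, DMR calling for both
#' successive stage contrasts, TPM normalization, DEG calling, peak-stage
#' assignment, soft clustering of DEG trajectories, expression strata and
#' metagene profiles, promoter-methylation/expression correlation, PNG and
#' DM-DEG identification, DM-DEG clustering, and recovery evaluation
#' against the planted truth.
#'
#' @param config a [sim_config()].
#' @param dataset optionally, a pre-built [simulate_dataset()] result.
#' @param min_coverage coverage filter for CpG levels.
#' @param promoter_window promoter half-width (bp) for correlation.
#' @param png_cutoff PNG correlation cutoff.
#' @param dmr_args list of extra arguments for [call_dmrs()].
#' @param cluster_c,cluster_m fuzzy c-means cluster count and fuzzifier.
#' @return list with all intermediate and final results, including
#'   `recovery`.
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         min_coverage = 5, promoter_window = 3000,
                         png_cutoff = -0.475, dmr_args = list(),
                         cluster_c = 6, cluster_m = 1.25) {
  sim <- dataset %||% simulate_dataset(config)
  design <- sim$expression$design

  levels_by_sample <- lapply(sim$methylomes, compute_levels, min_coverage = min_coverage)
  mm <- merge_samples(levels_by_sample, design)

  index <- build_feature_index(sim$annotation$genes, sim$annotation$cgis,
    promoter_up = promoter_window, promoter_down = promoter_window)
  site_labels <- assign_sites(mm, index)
  feature_means <- feature_mean_levels(mm, site_labels)

  contrasts <- list(c("p21", "p28"), c("p28", "p35"))
  dmrs <- do.call(rbind, lapply(contrasts, function(ct) {
    d <- do.call(call_dmrs, c(
      list(mm = mm, contrast = ct, chrom_sizes = sim$annotation$chrom_sizes),
      dmr_args
    ))
    if (nrow(d)) d$contrast <- paste(ct, collapse = "_")
    else d$contrast <- character()
    d
  }))

  counts <- sim$expression$counts
  tpm <- counts_to_tpm(counts, sim$expression$gene_lengths)
  expressed <- define_expressed(tpm)
  deg_results <- lapply(contrasts, function(ct) deg_test(counts, design, ct))
  names(deg_results) <- vapply(contrasts, paste, "", collapse = "_")
  degs <- unique(unlist(lapply(deg_results, function(d) d$gene_id[d$is_deg])))
  peaks <- if (length(degs)) assign_peak_stage(degs, tpm, design) else NULL

  clustering <- if (length(degs) >= cluster_c) {
    soft_cluster(stage_means(tpm[degs, , drop = FALSE], design),
      c = cluster_c, m = cluster_m, seed = config$seed)
  } else NULL

  expr_tpm <- tpm[intersect(expressed, rownames(tpm)), , drop = FALSE]
  strata <- expression_strata(expr_tpm, design, "p21")
  metagene <- metagene_profile(mm, sim$annotation$genes, strata)

  prom <- promoter_methylation(mm, sim$annotation$genes,
    promoter_window = promoter_window)
  records <- correlate_genes(prom[expressed, , drop = FALSE], tpm, design)
  pngs <- identify_pngs(records, cutoff = png_cutoff)
  dmdegs <- identify_dm_degs(pngs, degs)
  dmdeg_clusters <- if (length(dmdegs) >= 6) {
    cluster_dm_degs(tpm, design, dmdegs, k = 6)
  } else NULL

  recovery <- evaluate_recovery(
    list(dmrs = dmrs, degs = degs, dmdegs = dmdegs), sim$truth, sim$annotation
  )

  list(
    dataset = sim, meth_matrix = mm, feature_index = index,
    site_labels = site_labels, feature_means = feature_means, dmrs = dmrs,
    tpm = tpm, expressed = expressed, deg_results = deg_results,
    degs = degs, peak_stages = peaks, deg_clustering = clustering,
    strata = strata, metagene = metagene, promoter_meth = prom,
    correlation = records, pngs = pngs, dmdegs = dmdegs,
    dmdeg_clusters = dmdeg_clusters, recovery = recovery
  )
}
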