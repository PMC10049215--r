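#' Simulation configuration for the synthetic WGBS + RNA-seq dataset
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults describe a miniature two-chromosome genome carrying 2000 genes
#' under a three-stage (p21/p28/p35) by three-replicate design, with planted
#' differentially methylated regions (DMRs), differentially expressed genes
#' (DEGs), and genes whose promoter methylation is anti-correlated with
#' expression across stages (DM-DEGs).
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes total number of genes placed on the genome.
#' @param n_cpg_per_kb baseline CpG density (sites per kb).
#' @param cgi_cpg_per_kb CpG density inside CpG islands; must be at least the
#'   baseline density.
#' @param design data frame with columns `sample`, `stage`, `replicate`.
#'   Defaults to 3 stages x 3 replicates.
#' @param mean_coverage mean of the per-site, per-sample Poisson read
#'   coverage.
#' @param dispersion_expression shared negative-binomial dispersion of the
#'   RNA-seq counts.
#' @param n_deg_per_stage number of planted DEGs peaking at each stage, in
#'   addition to the planted DM-DEGs.
#' @param n_planted_dmr number of planted DMRs.
#' @param dmr_length length of each planted DMR in bp.
#' @param dmr_effect methylation-level shift of planted DMRs, in (0, 1].
#' @param n_planted_dmdeg number of planted DM-DEGs.
#' @param dmdeg_meth_drop total promoter methylation change of planted
#'   DM-DEGs across the stage series, in (0, 1].
#' @param dmdeg_lfc log2 expression change of planted DM-DEGs per successive
#'   stage step (their extreme-stage change is twice this); also the peak
#'   log2 change of the extra planted DEGs.
#' @param frac_non_cpg fraction of emitted cytosine-report records in
#'   non-CpG (CHG/CHH) context.
#' @param cgi_promoter_frac fraction of gene promoters overlapped by a CpG
#'   island.
#' @param seed integer seed; the same seed and configuration reproduce the
#'   dataset exactly.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 1e6,
                       n_genes = 2000,
                       n_cpg_per_kb = 6,
                       cgi_cpg_per_kb = 12,
                       design = default_design(),
                       mean_coverage = 15,
                       dispersion_expression = 0.05,
                       n_deg_per_stage = 50,
                       n_planted_dmr = 20,
                       dmr_length = 2000,
                       dmr_effect = 0.4,
                       n_planted_dmdeg = 150,
                       dmdeg_meth_drop = 0.6,
                       dmdeg_lfc = 2,
                       frac_non_cpg = 0.05,
                       cgi_promoter_frac = 0.7,
                       seed = 1) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes), chrom_length = chrom_length,
    n_genes = as.integer(n_genes), n_cpg_per_kb = n_cpg_per_kb,
    cgi_cpg_per_kb = cgi_cpg_per_kb, design = design,
    mean_coverage = mean_coverage,
    dispersion_expression = dispersion_expression,
    n_deg_per_stage = as.integer(n_deg_per_stage),
    n_planted_dmr = as.integer(n_planted_dmr), dmr_length = dmr_length,
    dmr_effect = dmr_effect, n_planted_dmdeg = as.integer(n_planted_dmdeg),
    dmdeg_meth_drop = dmdeg_meth_drop, dmdeg_lfc = dmdeg_lfc,
    frac_non_cpg = frac_non_cpg, cgi_promoter_frac = cgi_promoter_frac,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chromosomes >= 1, cfg$chrom_length >= 1000, cfg$n_genes >= 0,
    cfg$n_cpg_per_kb > 0, cfg$cgi_cpg_per_kb >= cfg$n_cpg_per_kb,
    cfg$mean_coverage > 0, cfg$dispersion_expression >= 0,
    cfg$n_deg_per_stage >= 0, cfg$n_planted_dmr >= 0, cfg$dmr_length >= 100,
    cfg$dmr_effect > 0, cfg$dmr_effect <= 1,
    cfg$n_planted_dmdeg >= 0,
    cfg$dmdeg_meth_drop > 0, cfg$dmdeg_meth_drop <= 1,
    cfg$frac_non_cpg >= 0, cfg$frac_non_cpg < 1,
    cfg$cgi_promoter_frac >= 0, cfg$cgi_promoter_frac <= 1
  )
  if (!all(c("sample", "stage", "replicate") %in% names(cfg$design))) {
    stop("design must have columns sample, stage, replicate")
  }
  if (!all(cfg$design$stage %in% stage_levels())) {
    stop("design stages must be among ", paste(stage_levels(), collapse = ", "))
  }
  if (anyDuplicated(cfg$design$sample)) stop("duplicate sample ids in design")
  if (cfg$n_planted_dmdeg + 3L * cfg$n_deg_per_stage > cfg$n_genes) {
    stop("more planted DEGs than genes")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_design <- function() {
  stages <- stage_levels()
  data.frame(
    sample = paste0(rep(stages, each = 3), "_r", 1:3),
    stage = rep(stages, each = 3),
    replicate = rep(1:3, times = 3),
    stringsAsFactors = FALSE
  )
}

# half-width of the constitutively hypomethylated core around each TSS (bp)
CORE_HALF <- 150
# half-width of the promoter region carrying planted DM-DEG methylation (bp)
DMDEG_HALF <- 500
# beta concentration of per-site true levels around the gene core mean
CORE_BETA_K <- 30

#' Simulate gene and CpG-island annotation
#'
#' Places non-overlapping genes evenly along each chromosome (one gene per
#' slot, random strand), with a simple two-exon model (5'UTR, exon, intron,
#' exon, 3'UTR) for genes long enough, and centers a CpG island on a
#' configurable fraction of promoters. With `n_genes = 0`, genes are absent
#' but CpG islands are still emitted at random positions.
#'
#' @param config a [sim_config()].
#' @return list with elements `genes` (data frame: gene_id, chrom, strand,
#'   start, end, tss, tes, length, utr5_len, utr3_len, intron_start,
#'   intron_end), `cgis` (data frame: chrom, start, end, gene_id or NA), and
#'   `chrom_sizes` (named vector). Coordinates are 1-based inclusive.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    chrom_sizes <- setNames(rep(config$chrom_length, config$n_chromosomes), chroms)

    if (config$n_genes > 0) {
      n_per <- rep(config$n_genes %/% config$n_chromosomes, config$n_chromosomes)
      extra <- config$n_genes %% config$n_chromosomes
      if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
      slot <- floor(config$chrom_length / max(n_per))
      if (slot < 300) {
        stop(sprintf(
          "genome too small to place %d genes: slot of %d bp per gene < 300 bp; increase chrom_length or n_chromosomes",
          config$n_genes, slot
        ))
      }
      rows <- vector("list", config$n_chromosomes)
      idx0 <- 0L
      for (ci in seq_len(config$n_chromosomes)) {
        n <- n_per[ci]
        slot_start <- (seq_len(n) - 1L) * slot + 1L
        len <- pmin(round(runif(n, 0.4, 0.6) * slot), slot - 100L)
        offset <- round(runif(n, 0.05, 0.15) * slot)
        start <- slot_start + offset
        end <- pmin(start + len - 1L, config$chrom_length)
        len <- end - start + 1L
        strand <- sample(c("+", "-"), n, replace = TRUE)
        rows[[ci]] <- data.frame(
          gene_id = sprintf("g%05d", idx0 + seq_len(n)),
          chrom = chroms[ci], strand = strand,
          start = start, end = end,
          tss = ifelse(strand == "+", start, end),
          tes = ifelse(strand == "+", end, start),
          length = len,
          stringsAsFactors = FALSE
        )
        idx0 <- idx0 + n
      }
      genes <- do.call(rbind, rows)
      genes$utr5_len <- pmax(20L, round(0.12 * genes$length))
      genes$utr3_len <- pmax(20L, round(0.12 * genes$length))
      has_intron <- genes$length >= 300L
      genes$intron_start <- ifelse(has_intron, genes$start + round(0.4 * genes$length), NA_integer_)
      genes$intron_end <- ifelse(has_intron, genes$start + round(0.6 * genes$length) - 1L, NA_integer_)

      n_cgi <- round(config$cgi_promoter_frac * nrow(genes))
      cgi_genes <- sort(sample(nrow(genes), n_cgi))
      w <- round(runif(n_cgi, 150, 400))
      cs <- pmax(1L, genes$tss[cgi_genes] - w %/% 2L)
      ce <- pmin(config$chrom_length, cs + w - 1L)
      cgis <- data.frame(
        chrom = genes$chrom[cgi_genes], start = cs, end = ce,
        gene_id = genes$gene_id[cgi_genes], stringsAsFactors = FALSE
      )
    } else {
      genes <- data.frame(
        gene_id = character(), chrom = character(), strand = character(),
        start = integer(), end = integer(), tss = integer(), tes = integer(),
        length = integer(), utr5_len = integer(), utr3_len = integer(),
        intron_start = integer(), intron_end = integer(),
        stringsAsFactors = FALSE
      )
      n_cgi <- max(1L, round(config$n_chromosomes * config$chrom_length / 5e4))
      chrom <- sample(chroms, n_cgi, replace = TRUE)
      w <- round(runif(n_cgi, 300, 800))
      cs <- pmax(1L, floor(runif(n_cgi, 1, config$chrom_length - w)))
      cgis <- data.frame(
        chrom = chrom, start = cs, end = cs + w - 1L,
        gene_id = NA_character_, stringsAsFactors = FALSE
      )
      cgis <- cgis[order_sites(cgis$chrom, cgis$start), , drop = FALSE]
      rownames(cgis) <- NULL
    }
    list(genes = genes, cgis = cgis, chrom_sizes = chrom_sizes)
  })
}

#' Simulate the planted ground truth
#'
#' Draws per-gene baseline expression and a matched core-promoter methylation
#' level (anti-coupled: highly expressed genes get the least methylated
#' cores), then plants (i) DM-DEG genes with per-stage promoter methylation
#' targets and anti-correlated expression multipliers, (ii) extra DEGs
#' peaking at each stage, and (iii) DMR intervals with a stage-directed
#' hyper- or hypomethylation shift, placed away from planted DM-DEG
#' promoters.
#'
#' @param annotation result of [simulate_annotation()].
#' @param config a [sim_config()].
#' @return list of class `sim_truth` with elements `gene_params`,
#'   `planted_dmdegs`, `planted_degs`, `planted_dmrs`.
#' @export
simulate_truth <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation$genes
  with_seed(config$seed + 2L, {
    n <- nrow(genes)
    base_mean <- if (n > 0) rlnorm(n, meanlog = log(200), sdlog = 1.2) else numeric()
    pct <- if (n > 0) (rank(base_mean, ties.method = "first") - 0.5) / n else numeric()
    core_mu <- 0.03 + 0.30 * (1 - pct)^3
    gene_params <- data.frame(
      gene_id = genes$gene_id, base_mean = base_mean, core_mu = core_mu,
      stringsAsFactors = FALSE
    )

    # planted genes drawn from the clearly-expressed majority so that both
    # the expression and the promoter-methylation signal are measurable
    eligible <- if (n > 0) which(base_mean >= quantile(base_mean, 0.3)) else integer()
    need <- config$n_planted_dmdeg + 3L * config$n_deg_per_stage
    if (need > length(eligible) && need > 0) {
      stop("not enough expressed genes to plant the requested DEG/DM-DEG sets")
    }
    # DM-DEG genes are spaced >= 4 kb apart so one gene's planted promoter
    # signal cannot dominate a neighbour's promoter window
    shuffled <- if (length(eligible)) sample(eligible) else integer()
    dmdeg_idx <- integer()
    for (i in shuffled) {
      if (length(dmdeg_idx) >= config$n_planted_dmdeg) break
      near <- genes$chrom[dmdeg_idx] == genes$chrom[i] &
        abs(genes$tss[dmdeg_idx] - genes$tss[i]) < 4000
      if (!any(near)) dmdeg_idx <- c(dmdeg_idx, i)
    }
    if (length(dmdeg_idx) < config$n_planted_dmdeg) {
      stop("could not place the planted DM-DEGs with 4 kb spacing; genome too crowded")
    }
    deg_idx <- head(setdiff(shuffled, dmdeg_idx), 3L * config$n_deg_per_stage)

    drop <- config$dmdeg_meth_drop
    lfc <- config$dmdeg_lfc
    ndm <- length(dmdeg_idx)
    dir_dm <- rep(c("up", "down"), length.out = ndm)
    lowm <- 0.15
    planted_dmdegs <- data.frame(
      gene_id = genes$gene_id[dmdeg_idx],
      direction = dir_dm,
      meth_p21 = ifelse(dir_dm == "up", lowm + drop, lowm),
      meth_p28 = rep(lowm + drop / 2, ndm),
      meth_p35 = ifelse(dir_dm == "up", lowm, lowm + drop),
      expr_mult_p21 = ifelse(dir_dm == "up", 1, 2^(2 * lfc)),
      expr_mult_p28 = rep(2^lfc, ndm),
      expr_mult_p35 = ifelse(dir_dm == "up", 2^(2 * lfc), 1),
      peak_stage = ifelse(dir_dm == "up", "p35", "p21"),
      stringsAsFactors = FALSE
    )

    peak <- rep(stage_levels(), length.out = 3L * config$n_deg_per_stage)
    peak <- peak[seq_along(deg_idx)]
    extra_degs <- data.frame(
      gene_id = genes$gene_id[deg_idx], peak_stage = peak,
      stringsAsFactors = FALSE
    )
    planted_degs <- rbind(
      extra_degs,
      planted_dmdegs[, c("gene_id", "peak_stage")]
    )
    rownames(planted_degs) <- NULL

    # planted DMRs: rejection-sample intervals that avoid each other and all
    # planted DM-DEG promoter windows
    avoid <- GenomicRanges::GRanges()
    if (ndm > 0) {
      g <- genes[dmdeg_idx, ]
      avoid <- GenomicRanges::GRanges(
        g$chrom,
        IRanges::IRanges(pmax(1, g$tss - 3500), g$tss + 3500)
      )
    }
    chroms <- names(annotation$chrom_sizes)
    placed <- GenomicRanges::GRanges()
    recs <- vector("list", config$n_planted_dmr)
    k <- 0L; tries <- 0L
    while (k < config$n_planted_dmr && tries < 20000L) {
      tries <- tries + 1L
      chrom <- sample(chroms, 1L)
      start <- as.integer(floor(runif(1, 1, annotation$chrom_sizes[[chrom]] - config$dmr_length)))
      cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + config$dmr_length - 1L))
      if (length(placed) && length(suppressWarnings(GenomicRanges::findOverlaps(cand, placed)))) next
      if (length(avoid) && length(suppressWarnings(GenomicRanges::findOverlaps(cand, avoid)))) next
      k <- k + 1L
      placed <- suppressWarnings(c(placed, cand))
      recs[[k]] <- data.frame(
        dmr_id = sprintf("dmr%03d", k), chrom = chrom,
        start = start, end = start + config$dmr_length - 1L,
        direction = if (k %% 2L == 1L) "hyper" else "hypo",
        contrast = if ((k - 1L) %/% 2L %% 2L == 0L) "p21_p28" else "p28_p35",
        stringsAsFactors = FALSE
      )
    }
    if (k < config$n_planted_dmr) {
      stop("could not place all planted DMRs without overlap; genome too crowded")
    }
    planted_dmrs <- if (k > 0) do.call(rbind, recs) else data.frame(
      dmr_id = character(), chrom = character(), start = integer(),
      end = integer(), direction = character(), contrast = character(),
      stringsAsFactors = FALSE
    )

    structure(
      list(
        gene_params = gene_params, planted_dmdegs = planted_dmdegs,
        planted_degs = planted_degs, planted_dmrs = planted_dmrs
      ),
      class = "sim_truth"
    )
  })
}

# stage-wise true methylation targets of a planted DMR, relative to its
# per-site baseline b and effect e
dmr_stage_levels <- function(base, effect, direction, contrast) {
  shift <- if (direction == "hyper") effect else -effect
  out <- cbind(p21 = base, p28 = base, p35 = base)
  if (contrast == "p21_p28") {
    out[, "p28"] <- base + shift
    out[, "p35"] <- base + shift
  } else {
    out[, "p35"] <- base + shift
  }
  out
}

#' Simulate per-sample cytosine report tables
#'
#' Draws CpG positions (denser inside CpG islands), assigns each site a true
#' methylation level from a feature-conditioned beta mixture (hypomethylated
#' promoter cores and CpG islands; heavily methylated gene bodies and
#' intergenic territory), applies the planted DMR shifts and DM-DEG per-stage
#' promoter targets, and emits observed counts as binomial draws under
#' per-site Poisson coverage. A small fraction of CHG/CHH records is added so
#' context filtering is exercised; zero-coverage sites are emitted with 0/0
#' counts.
#'
#' @param annotation result of [simulate_annotation()].
#' @param truth result of [simulate_truth()].
#' @param config a [sim_config()].
#' @return named list (one element per design sample) of cytosine-report
#'   data frames with columns chrom, pos, strand, count_methylated,
#'   count_unmethylated, context, sorted by (chrom, pos). The per-stage true
#'   level matrix is attached as attribute `true_levels` alongside the site
#'   table `sites`.
#' @export
simulate_methylome <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  genes <- annotation$genes
  cgis <- annotation$cgis
  with_seed(config$seed + 3L, {
    chroms <- names(annotation$chrom_sizes)
    pos_l <- lapply(chroms, function(ch) {
      L <- annotation$chrom_sizes[[ch]]
      base <- sample.int(L, round(L * config$n_cpg_per_kb / 1000))
      ci <- cgis[cgis$chrom == ch, , drop = FALSE]
      extra <- integer()
      if (nrow(ci) > 0 && config$cgi_cpg_per_kb > config$n_cpg_per_kb) {
        dens <- (config$cgi_cpg_per_kb - config$n_cpg_per_kb) / 1000
        for (i in seq_len(nrow(ci))) {
          w <- ci$end[i] - ci$start[i] + 1L
          n_e <- round(w * dens)
          if (n_e > 0) extra <- c(extra, ci$start[i] + sample.int(w, min(n_e, w)) - 1L)
        }
      }
      sort(unique(c(base, extra)))
    })
    sites <- data.frame(
      chrom = rep(chroms, lengths(pos_l)),
      pos = unlist(pos_l),
      stringsAsFactors = FALSE
    )
    ns <- nrow(sites)
    site_gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))

    # baseline: heavily methylated genome
    lev <- matrix(rbeta(ns, 8, 2), ns, 3, dimnames = list(NULL, stage_levels()))

    # hypomethylated cores: CGIs and TSS-proximal windows, level tied to the
    # owning gene's expression-coupled core mean
    if (nrow(genes) > 0 || nrow(cgis) > 0) {
      mu_map <- setNames(truth$gene_params$core_mu, truth$gene_params$gene_id)
      reg <- rbind(
        if (nrow(genes) > 0) data.frame(
          chrom = genes$chrom, start = pmax(1L, genes$tss - CORE_HALF),
          end = genes$tss + CORE_HALF, mu = unname(mu_map[genes$gene_id]),
          stringsAsFactors = FALSE
        ),
        if (nrow(cgis) > 0) data.frame(
          chrom = cgis$chrom, start = cgis$start, end = cgis$end,
          mu = ifelse(is.na(cgis$gene_id), 0.05, unname(mu_map[cgis$gene_id])),
          stringsAsFactors = FALSE
        )
      )
      reg_gr <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
      ov <- GenomicRanges::findOverlaps(site_gr, reg_gr, select = "first")
      hit <- !is.na(ov)
      mu <- reg$mu[ov[hit]]
      lev[hit, ] <- rbeta(sum(hit), mu * CORE_BETA_K, (1 - mu) * CORE_BETA_K)
    }

    # planted DM-DEG promoters: per-stage targets with a shared per-site offset
    if (nrow(truth$planted_dmdegs) > 0) {
      gd <- merge(truth$planted_dmdegs, genes, by = "gene_id")
      dm_gr <- GenomicRanges::GRanges(
        gd$chrom, IRanges::IRanges(pmax(1L, gd$tss - DMDEG_HALF), gd$tss + DMDEG_HALF)
      )
      ov <- GenomicRanges::findOverlaps(site_gr, dm_gr, select = "first")
      hit <- which(!is.na(ov))
      if (length(hit)) {
        gi <- ov[hit]
        jit <- rnorm(length(hit), 0, 0.03)
        for (s in stage_levels()) {
          lev[hit, s] <- pmin(pmax(gd[[paste0("meth_", s)]][gi] + jit, 0.01), 0.99)
        }
      }
    }

    # planted DMRs: per-site baseline drawn so the full shift fits in [0,1]
    if (nrow(truth$planted_dmrs) > 0) {
      for (i in seq_len(nrow(truth$planted_dmrs))) {
        d <- truth$planted_dmrs[i, ]
        hit <- which(sites$chrom == d$chrom & sites$pos >= d$start & sites$pos <= d$end)
        if (!length(hit)) next
        # baseline chosen so that baseline + effect stays inside [0.02, 0.98]
        hi <- max(0.98 - config$dmr_effect, 0.021)
        lo <- max(0.02, min(0.15, hi - 0.01))
        base <- runif(length(hit), lo, max(min(0.45, hi), lo + 0.001))
        if (d$direction == "hypo") base <- 1 - base
        lev[hit, ] <- dmr_stage_levels(base, config$dmr_effect, d$direction, d$contrast)
      }
    }

    strand <- sample(c("+", "-"), ns, replace = TRUE)

    # non-CpG records at positions distinct from the CpG sites
    n_extra <- round(config$frac_non_cpg / (1 - config$frac_non_cpg) * ns)
    extra <- NULL
    if (n_extra > 0) {
      ch <- sample(chroms, n_extra, replace = TRUE)
      ep <- as.integer(floor(runif(n_extra, 1, config$chrom_length)))
      keep <- !duplicated(paste(ch, ep))
      ch <- ch[keep]; ep <- ep[keep]
      extra <- data.frame(
        chrom = ch, pos = ep,
        strand = sample(c("+", "-"), length(ep), replace = TRUE),
        context = sample(c("CHG", "CHH"), length(ep), replace = TRUE, prob = c(0.4, 0.6)),
        level = rbeta(length(ep), 1, 50),
        stringsAsFactors = FALSE
      )
    }

    design <- config$design
    out <- vector("list", nrow(design))
    names(out) <- design$sample
    for (j in seq_len(nrow(design))) {
      st <- design$stage[j]
      cov <- rpois(ns, config$mean_coverage)
      C <- rbinom(ns, cov, lev[, st])
      tab <- data.frame(
        chrom = sites$chrom, pos = sites$pos, strand = strand,
        count_methylated = C, count_unmethylated = cov - C,
        context = "CpG", stringsAsFactors = FALSE
      )
      if (!is.null(extra)) {
        ecov <- rpois(nrow(extra), config$mean_coverage)
        eC <- rbinom(nrow(extra), ecov, extra$level)
        tab <- rbind(tab, data.frame(
          chrom = extra$chrom, pos = extra$pos, strand = extra$strand,
          count_methylated = eC, count_unmethylated = ecov - eC,
          context = extra$context, stringsAsFactors = FALSE
        ))
      }
      tab <- tab[order_sites(tab$chrom, tab$pos), , drop = FALSE]
      rownames(tab) <- NULL
      out[[j]] <- tab
    }
    attr(out, "sites") <- sites
    attr(out, "true_levels") <- lev
    out
  })
}

#' Simulate the RNA-seq count matrix
#'
#' Negative-binomial counts around per-stage gene means: baseline means from
#' the ground truth multiplied by the planted DEG / DM-DEG stage
#' multipliers; in the zero-dispersion limit the counts are Poisson.
#'
#' @inheritParams simulate_methylome
#' @return list with `counts` (genes x samples integer matrix),
#'   `gene_lengths` (named vector, bp), and `design`.
#' @export
simulate_expression <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  genes <- annotation$genes
  with_seed(config$seed + 4L, {
    design <- config$design
    n <- nrow(genes)
    mult <- matrix(1, n, 3, dimnames = list(genes$gene_id, stage_levels()))
    if (nrow(truth$planted_dmdegs) > 0) {
      i <- match(truth$planted_dmdegs$gene_id, genes$gene_id)
      for (s in stage_levels()) mult[i, s] <- truth$planted_dmdegs[[paste0("expr_mult_", s)]]
    }
    extra <- truth$planted_degs[!truth$planted_degs$gene_id %in% truth$planted_dmdegs$gene_id, ]
    if (nrow(extra) > 0) {
      i <- match(extra$gene_id, genes$gene_id)
      mult[cbind(i, match(extra$peak_stage, stage_levels()))] <- 2^config$dmdeg_lfc
    }
    counts <- matrix(0L, n, nrow(design), dimnames = list(genes$gene_id, design$sample))
    size <- if (config$dispersion_expression > 0) 1 / config$dispersion_expression else Inf
    for (j in seq_len(nrow(design))) {
      mu <- truth$gene_params$base_mean * mult[, design$stage[j]]
      counts[, j] <- if (is.finite(size)) rnbinom(n, mu = mu, size = size) else rpois(n, mu)
    }
    list(
      counts = counts,
      gene_lengths = setNames(genes$length, genes$gene_id),
      design = design
    )
  })
}

#' Run all generators and return the full synthetic dataset
#'
#' @param config a [sim_config()].
#' @return list with `config`, `annotation`, `truth`, `methylomes` (per-sample
#'   cytosine reports), and `expression` (counts, gene lengths, design).
#' @export
simulate_dataset <- function(config = sim_config()) {
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(annotation, config)
  methylomes <- simulate_methylome(annotation, truth, config)
  expression <- simulate_expression(annotation, truth, config)
  list(
    config = config, annotation = annotation, truth = truth,
    methylomes = methylomes, expression = expression
  )
}
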