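#' Tile a genome into fixed-width windows
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param window tile width in bp.
#' @param step distance between tile starts; `step > window` leaves gaps
#'   (flagged with a message), `step < window` makes overlapping tiles.
#' @return data frame chrom, start, end (1-based inclusive); the last
#'   partial tile of each chromosome is kept.
#' @export
tile_genome <- function(chrom_sizes, window = 1000, step = window) {
  stopifnot(window >= 1, step >= 1)
  if (step > window) message("step > window: tiling leaves uncovered gaps")
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    starts <- seq.int(1L, L, by = step)
    data.frame(
      chrom = ch, start = starts, end = pmin(starts + window - 1L, L),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# Two-sided conditional exact test on a 2x2 table of pooled
# methylated/unmethylated counts, vectorized over tables. For each table the
# p-value sums the hypergeometric probabilities of all outcomes no more
# likely than the observed one (the same two-sided rule as fisher.test).
cond_exact_p <- function(m1, u1, m2, u2) {
  n <- length(m1)
  stopifnot(length(u1) == n, length(m2) == n, length(u2) == n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    k <- m1[i] + u1[i]        # group-A total
    K <- m1[i] + m2[i]        # methylated total
    N <- k + m2[i] + u2[i]
    if (N == 0 || K == 0 || K == N || k == 0 || k == N) {
      p[i] <- 1
      next
    }
    lo <- max(0L, k - (N - K))
    hi <- min(k, K)
    d <- dhyper(lo:hi, K, N - K, k)
    p[i] <- min(1, sum(d[d <= d[m1[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

#' Test one genome tile for differential methylation
#'
#' Counts are pooled over sites and replicates within each group; the
#' methylation difference is the difference of pooled proportions (B minus
#' A) and the p-value comes from a two-sided conditional exact test of the
#' 2x2 methylated/unmethylated by group table.
#'
#' @param a_meth,a_unmeth pooled methylated/unmethylated read counts in
#'   group A.
#' @param b_meth,b_unmeth pooled counts in group B.
#' @return list with `meth_diff` and `p_value`.
#' @export
test_tile <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  stopifnot(a_meth >= 0, a_unmeth >= 0, b_meth >= 0, b_unmeth >= 0)
  pa <- if (a_meth + a_unmeth > 0) a_meth / (a_meth + a_unmeth) else NA_real_
  pb <- if (b_meth + b_unmeth > 0) b_meth / (b_meth + b_unmeth) else NA_real_
  list(
    meth_diff = pb - pa,
    p_value = cond_exact_p(a_meth, a_unmeth, b_meth, b_unmeth)
  )
}

#' Call differentially methylated regions between two stages
#'
#' The genome is tiled; per tile, read counts are pooled within each stage
#' group over sites and replicates and tested with the conditional exact
#' test. Benjamini-Hochberg correction is applied across all tested tiles;
#' tiles passing both the methylation-difference and q-value cutoffs are
#' kept, and adjacent significant tiles with the same direction are merged
#' into one record (whose summary statistics are recomputed over the merged
#' span).
#'
#' @param mm a `meth_matrix`.
#' @param contrast character vector `c(A, B)`; direction is B relative to A
#'   (hyper = higher in B).
#' @param chrom_sizes named vector; defaults to the last covered site per
#'   chromosome.
#' @param window tile width (bp).
#' @param diff_cutoff minimum |methylation difference|.
#' @param q_cutoff maximum BH-adjusted p.
#' @param min_cpg minimum number of CpG sites covered in at least one sample
#'   of each group for a tile to be tested.
#' @return data frame of DMR records (chrom, start, end, n_cpg,
#'   mean_level_A, mean_level_B, meth_diff, p_value, q_value, direction)
#'   with attributes `n_tested` (tiles tested) and `n_skipped`.
#' @export
call_dmrs <- function(mm, contrast, chrom_sizes = NULL, window = 1000,
                      diff_cutoff = 0.25, q_cutoff = 0.05, min_cpg = 3) {
  stopifnot(length(contrast) == 2)
  design <- mm$design
  if (!all(contrast %in% design$stage)) {
    stop("unknown stage in contrast: ", paste(setdiff(contrast, design$stage), collapse = ", "))
  }
  sa <- design$sample[design$stage == contrast[1]]
  sb <- design$sample[design$stage == contrast[2]]
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(mm$sites$pos, mm$sites$chrom, max)
    chrom_sizes <- setNames(as.vector(chrom_sizes), names(chrom_sizes))
  }
  tiles <- tile_genome(chrom_sizes, window = window, step = window)

  C <- mm$level * mm$coverage # methylated read counts
  U <- mm$coverage - C

  tile_gr <- GenomicRanges::GRanges(tiles$chrom, IRanges::IRanges(tiles$start, tiles$end))
  site_gr <- GenomicRanges::GRanges(mm$sites$chrom, IRanges::IRanges(mm$sites$pos, mm$sites$pos))
  ov <- GenomicRanges::findOverlaps(site_gr, tile_gr)
  si <- queryHits(ov)
  ti <- subjectHits(ov)

  cov_a <- rowSums(!is.na(mm$level[, sa, drop = FALSE])) > 0
  cov_b <- rowSums(!is.na(mm$level[, sb, drop = FALSE])) > 0
  ok_site <- cov_a & cov_b

  n_ok <- tabulate(ti[ok_site[si]], nbins = nrow(tiles))
  testable <- n_ok >= min_cpg

  # pooled counts per tile (rounded to whole reads)
  agg <- function(M, samp) {
    v <- rowSums(M[, samp, drop = FALSE], na.rm = TRUE)
    out <- numeric(nrow(tiles))
    s <- rowsum(v[si], ti)
    out[as.integer(rownames(s))] <- s[, 1]
    round(out)
  }
  ma <- agg(C, sa); ua <- agg(U, sa)
  mb <- agg(C, sb); ub <- agg(U, sb)

  idx <- which(testable)
  n_skipped <- sum(!testable & tabulate(ti, nbins = nrow(tiles)) > 0)
  if (!length(idx)) {
    res <- empty_dmr_frame()
    attr(res, "n_tested") <- 0L
    attr(res, "n_skipped") <- n_skipped
    return(res)
  }
  p <- cond_exact_p(ma[idx], ua[idx], mb[idx], ub[idx])
  q <- p.adjust(p, method = "BH")
  la <- ma[idx] / pmax(ma[idx] + ua[idx], 1)
  lb <- mb[idx] / pmax(mb[idx] + ub[idx], 1)
  diff <- lb - la
  sig <- q <= q_cutoff & abs(diff) >= diff_cutoff & (ma + ua)[idx] > 0 & (mb + ub)[idx] > 0
  hit <- data.frame(
    tile = idx, chrom = tiles$chrom[idx], start = tiles$start[idx],
    end = tiles$end[idx], n_cpg = n_ok[idx],
    ma = ma[idx], ua = ua[idx], mb = mb[idx], ub = ub[idx],
    p_value = p, q_value = q, diff = diff, stringsAsFactors = FALSE
  )[sig, , drop = FALSE]

  if (!nrow(hit)) {
    res <- empty_dmr_frame()
    attr(res, "n_tested") <- length(idx)
    attr(res, "n_skipped") <- n_skipped
    return(res)
  }
  hit <- hit[order_sites(hit$chrom, hit$start), , drop = FALSE]
  dir <- ifelse(hit$diff > 0, "hyper", "hypo")
  new_run <- c(TRUE, !(
    hit$chrom[-1] == hit$chrom[-nrow(hit)] &
      hit$start[-1] == hit$end[-nrow(hit)] + 1L &
      dir[-1] == dir[-nrow(hit)]
  ))
  run <- cumsum(new_run)
  merged <- lapply(split(seq_len(nrow(hit)), run), function(ii) {
    h <- hit[ii, , drop = FALSE]
    MA <- sum(h$ma); UA <- sum(h$ua); MB <- sum(h$mb); UB <- sum(h$ub)
    la <- MA / (MA + UA); lb <- MB / (MB + UB)
    data.frame(
      chrom = h$chrom[1], start = min(h$start), end = max(h$end),
      n_cpg = sum(h$n_cpg), mean_level_A = la, mean_level_B = lb,
      meth_diff = lb - la, p_value = min(h$p_value), q_value = min(h$q_value),
      direction = if (lb - la > 0) "hyper" else "hypo",
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  attr(res, "n_tested") <- length(idx)
  attr(res, "n_skipped") <- n_skipped
  res
}

empty_dmr_frame <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    n_cpg = integer(), mean_level_A = numeric(), mean_level_B = numeric(),
    meth_diff = numeric(), p_value = numeric(), q_value = numeric(),
    direction = character(), stringsAsFactors = FALSE
  )
}

#' Genomic distribution of DMRs
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param index a [build_feature_index()] result.
#' @return list with `feature_fraction` (named vector summing to 1) and
#'   `per_chromosome` (named counts summing to the number of DMRs); both
#'   empty for an empty DMR set.
#' @export
dmr_feature_distribution <- function(dmrs, index) {
  if (nrow(dmrs) == 0) {
    return(list(feature_fraction = numeric(), per_chromosome = integer()))
  }
  ann <- annotate_region(dmrs[, c("chrom", "start", "end")], index)
  tab <- table(ann$feature)
  list(
    feature_fraction = setNames(as.vector(tab) / nrow(dmrs), names(tab)),
    per_chromosome = setNames(
      as.vector(table(dmrs$chrom)), names(table(dmrs$chrom))
    )
  )
}
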