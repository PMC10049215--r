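#' Read a Bismark-style cytosine report
#'
#' Parses a TSV (optionally gzipped) with columns chrom, pos (1-based),
#' strand, count_methylated, count_unmethylated, context. Rows are validated;
#' malformed rows raise an error naming the offending line.
#'
#' @param path path to the report; `.gz` files are read transparently.
#' @return data frame with the six typed columns.
#' @export
read_cytosine_report <- function(path) {
  raw <- tryCatch(
    read.table(path,
      sep = "\t", header = FALSE, colClasses = "character",
      quote = "", comment.char = "", blank.lines.skip = FALSE
    ),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    }
  )
  if (is.null(raw) || nrow(raw) == 0) {
    warning("empty cytosine report: ", path)
    return(data.frame(
      chrom = character(), pos = integer(), strand = character(),
      count_methylated = integer(), count_unmethylated = integer(),
      context = character(), stringsAsFactors = FALSE
    ))
  }
  if (ncol(raw) < 6) {
    stop("cytosine report must have >= 6 columns; found ", ncol(raw), " in ", path)
  }
  raw <- raw[, 1:6]
  names(raw) <- c(
    "chrom", "pos", "strand", "count_methylated", "count_unmethylated", "context"
  )
  pos <- suppressWarnings(as.integer(raw$pos))
  cm <- suppressWarnings(as.integer(raw$count_methylated))
  cu <- suppressWarnings(as.integer(raw$count_unmethylated))
  bad <- which(
    is.na(pos) | pos < 1 |
      is.na(cm) | cm < 0 | is.na(cu) | cu < 0 |
      !raw$strand %in% c("+", "-") |
      !raw$context %in% c("CpG", "CHG", "CHH")
  )
  if (length(bad)) {
    stop(sprintf(
      "malformed cytosine report row(s) at line(s) %s of %s",
      paste(head(bad, 5), collapse = ", "), path
    ))
  }
  data.frame(
    chrom = raw$chrom, pos = pos, strand = raw$strand,
    count_methylated = cm, count_unmethylated = cu, context = raw$context,
    stringsAsFactors = FALSE
  )
}

#' Context composition of methylated cytosines
#'
#' Fraction of methylated cytosine sites per sequence context
#' (CpG/CHG/CHH). A site is counted as methylated when it carries at least
#' `min_meth_reads` methylated reads after coverage filtering.
#'
#' @param table cytosine-report data frame.
#' @param min_coverage minimum read coverage for a site to be considered.
#' @param min_meth_reads methylated-read threshold defining a methylated
#'   cytosine (default 1).
#' @return named numeric vector of fractions over CpG, CHG, CHH (sums to 1).
#' @export
context_composition <- function(table, min_coverage = 5, min_meth_reads = 1) {
  if (nrow(table) == 0) stop("context_composition: empty table")
  cov <- table$count_methylated + table$count_unmethylated
  keep <- cov >= min_coverage & table$count_methylated >= min_meth_reads
  if (!any(keep)) stop("context_composition: no methylated cytosines found")
  ctx <- factor(table$context[keep], levels = c("CpG", "CHG", "CHH"))
  tab <- table(ctx)
  setNames(as.vector(tab) / sum(tab), names(tab))
}

#' Compute CpG methylation levels for one sample
#'
#' The level of each CpG is the number of methylated reads C divided by the
#' total reads C + T at the site; sites with coverage below `min_coverage`
#' (default 5 reads) are dropped. Non-CpG context rows are excluded.
#'
#' @param table cytosine-report data frame.
#' @param min_coverage minimum coverage; must be >= 1.
#' @param merge_strands if TRUE, counts of the two strands of a symmetric
#'   CpG dinucleotide (positions p on + and p+1 on -) are summed before
#'   filtering; by default the two strand sites are kept separate.
#' @return data frame (chrom, pos, level, coverage) sorted by (chrom, pos).
#' @export
compute_levels <- function(table, min_coverage = 5, merge_strands = FALSE) {
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  t <- table[table$context == "CpG", , drop = FALSE]
  if (merge_strands && nrow(t) > 0) {
    key_pos <- ifelse(t$strand == "-", t$pos - 1L, t$pos)
    agg <- rowsum(
      cbind(t$count_methylated, t$count_unmethylated),
      group = paste(t$chrom, key_pos)
    )
    key <- strsplit(rownames(agg), " ", fixed = TRUE)
    t <- data.frame(
      chrom = vapply(key, `[`, "", 1L),
      pos = as.integer(vapply(key, `[`, "", 2L)),
      count_methylated = agg[, 1], count_unmethylated = agg[, 2],
      stringsAsFactors = FALSE
    )
  }
  cov <- t$count_methylated + t$count_unmethylated
  keep <- cov >= min_coverage
  out <- data.frame(
    chrom = t$chrom[keep], pos = t$pos[keep],
    level = t$count_methylated[keep] / cov[keep],
    coverage = cov[keep], stringsAsFactors = FALSE
  )
  out <- out[order_sites(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge single-sample level tables into a methylation matrix
#'
#' Outer join on (chrom, pos): a site appears if defined in any sample;
#' missing entries stay NA. Output row order is sorted by (chrom, pos) and is
#' invariant to the input sample order.
#'
#' @param samples named list of [compute_levels()] outputs; names must match
#'   `design$sample`.
#' @param design data frame with columns sample, stage, replicate.
#' @return object of class `meth_matrix`: list with `sites` (chrom, pos),
#'   `level` and `coverage` (site x sample matrices), and `design`.
#' @export
merge_samples <- function(samples, design) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list")
  }
  if (anyDuplicated(names(samples))) stop("duplicate sample names")
  if (!setequal(names(samples), design$sample)) {
    stop("sample names must match design$sample")
  }
  samples <- samples[design$sample]
  site_key <- function(chrom, pos) sprintf("%s %d", chrom, as.integer(pos))
  for (nm in names(samples)) {
    if (anyDuplicated(site_key(samples[[nm]]$chrom, samples[[nm]]$pos))) {
      stop("duplicate site within sample ", nm)
    }
  }
  all_key <- unique(unlist(lapply(samples, function(s) site_key(s$chrom, s$pos))))
  sp <- strsplit(all_key, " ", fixed = TRUE)
  sites <- data.frame(
    chrom = vapply(sp, `[`, "", 1L),
    pos = as.integer(vapply(sp, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  o <- order_sites(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  key <- site_key(sites$chrom, sites$pos)
  n <- nrow(sites)
  level <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, names(samples)))
  coverage <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, names(samples)))
  for (nm in names(samples)) {
    s <- samples[[nm]]
    i <- match(site_key(s$chrom, s$pos), key)
    level[i, nm] <- s$level
    coverage[i, nm] <- s$coverage
  }
  structure(
    list(sites = sites, level = level, coverage = coverage, design = design),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(
    "meth_matrix: %d sites x %d samples (%.1f%% defined)\n",
    nrow(x$sites), ncol(x$level), 100 * mean(!is.na(x$level))
  ))
  invisible(x)
}

#' Per-sample methylation level histogram
#'
#' Counts of defined levels in `n_bins` equal-width bins partitioning
#' \[0, 1\] (default 20 bins of 5%); a level of exactly 1 falls in the last
#' bin.
#'
#' @param mm a `meth_matrix`.
#' @param n_bins number of bins (>= 2).
#' @return matrix `n_bins` x samples; each column sums to the number of
#'   defined levels of that sample.
#' @export
level_histogram <- function(mm, n_bins = 20) {
  stopifnot(n_bins >= 2)
  apply(mm$level, 2, function(v) {
    v <- v[!is.na(v)]
    tabulate(pmin(floor(v * n_bins), n_bins - 1L) + 1L, n_bins)
  })
}

#' Classify sites into low / medium / high methylation
#'
#' Low: level <= 25%; medium: 25% < level < 75%; high: level >= 75%.
#'
#' @param mm a `meth_matrix`.
#' @return 3 x samples matrix of fractions (columns sum to 1).
#' @export
classify_sites <- function(mm) {
  out <- apply(mm$level, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(low = NA_real_, medium = NA_real_, high = NA_real_))
    c(
      low = mean(v <= 0.25),
      medium = mean(v > 0.25 & v < 0.75),
      high = mean(v >= 0.75)
    )
  })
  rownames(out) <- c("low", "medium", "high")
  out
}

#' Pairwise Pearson correlation between samples
#'
#' Each pair is correlated over the sites defined in both samples; pairs with
#' fewer than two common sites (or zero variance) yield NA with a warning.
#'
#' @param mm a `meth_matrix`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_sample_correlation <- function(mm) {
  k <- ncol(mm$level)
  if (k < 2) stop("need >= 2 samples")
  out <- diag(1, k)
  dimnames(out) <- list(colnames(mm$level), colnames(mm$level))
  flagged <- FALSE
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(mm$level[, i]) & !is.na(mm$level[, j])
      if (sum(ok) < 2) {
        out[i, j] <- out[j, i] <- NA_real_
        flagged <- TRUE
      } else {
        r <- suppressWarnings(cor(mm$level[ok, i], mm$level[ok, j]))
        out[i, j] <- out[j, i] <- r
        if (is.na(r)) flagged <- TRUE
      }
    }
  }
  if (flagged) warning("some sample pairs had <2 common sites or zero variance")
  out
}

#' PCA of samples on complete-case methylation levels
#'
#' Sites with any missing sample value are excluded; samples are projected
#' onto principal components of the centered level matrix.
#'
#' @param mm a `meth_matrix`.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained_variance`
#'   (per component), `total_variance`, and `n_sites` used.
#' @export
methylation_pca <- function(mm, n_components = 2) {
  if (ncol(mm$level) < 2) stop("need >= 2 samples")
  ok <- complete.cases(mm$level)
  X <- t(mm$level[ok, , drop = FALSE])
  if (sum(ok) < n_components) {
    stop(sprintf(
      "only %d complete-case sites for %d components", sum(ok), n_components
    ))
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  list(
    scores = p$x[, seq_len(k), drop = FALSE],
    explained_variance = p$sdev[seq_len(k)]^2,
    total_variance = sum(p$sdev^2),
    n_sites = sum(ok)
  )
}
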