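# Feature precedence used to resolve a single primary label per position.
FEATURE_PRECEDENCE <- c(
  "cgi", "cgi_shore", "cgi_shelf", "promoter", "utr5", "utr3",
  "exon", "intron", "gene_body", "distal_intergenic"
)

#' Build a genomic feature index
#'
#' Derives labeled interval sets from gene models and CpG islands:
#' CGI shores are the 2 kb flanks of each island, shelves the next 2 kb
#' beyond the shores; promoters span TSS - `promoter_up` to
#' TSS + `promoter_down` in transcription direction; UTRs, exons and introns
#' come from the simple gene models when present; anything not covered by a
#' gene-linked or CGI-linked feature is distal intergenic. All coordinates
#' are 1-based inclusive.
#'
#' @param genes gene data frame (as from [simulate_annotation()]); must have
#'   gene_id, chrom, strand, start, end, tss; optional utr5_len, utr3_len,
#'   intron_start, intron_end.
#' @param cgis data frame chrom, start, end.
#' @param promoter_up,promoter_down bp upstream/downstream of the TSS
#'   (transcription direction) covered by the promoter.
#' @return object of class `feature_index`: feature GRanges in precedence
#'   order, per-gene promoter ranges, the gene table, and known chromosomes.
#' @export
build_feature_index <- function(genes, cgis, promoter_up = 3000, promoter_down = 3000) {
  gr <- function(chrom, start, end) {
    keep <- !is.na(start) & !is.na(end) & end >= start
    GenomicRanges::GRanges(chrom[keep], IRanges::IRanges(pmax(1, start[keep]), end[keep]))
  }
  empty <- GenomicRanges::GRanges()
  feats <- list()

  cgi_gr <- if (nrow(cgis)) gr(cgis$chrom, cgis$start, cgis$end) else empty
  feats$cgi <- GenomicRanges::reduce(cgi_gr)
  if (length(cgi_gr)) {
    shore_raw <- c(
      GenomicRanges::flank(cgi_gr, 2000, start = TRUE),
      GenomicRanges::flank(cgi_gr, 2000, start = FALSE)
    )
    shore_raw <- GenomicRanges::trim(shore_raw)
    feats$cgi_shore <- GenomicRanges::setdiff(GenomicRanges::reduce(shore_raw), feats$cgi)
    shelf_raw <- GenomicRanges::trim(c(
      GenomicRanges::flank(cgi_gr, 4000, start = TRUE),
      GenomicRanges::flank(cgi_gr, 4000, start = FALSE)
    ))
    feats$cgi_shelf <- GenomicRanges::setdiff(
      GenomicRanges::reduce(shelf_raw),
      GenomicRanges::union(feats$cgi, feats$cgi_shore)
    )
  } else {
    feats$cgi_shore <- empty
    feats$cgi_shelf <- empty
  }

  if (nrow(genes)) {
    plus <- genes$strand == "+"
    pstart <- ifelse(plus, genes$tss - promoter_up, genes$tss - promoter_down)
    pend <- ifelse(plus, genes$tss + promoter_down, genes$tss + promoter_up)
    prom_by_gene <- gr(genes$chrom, pstart, pend)
    names(prom_by_gene) <- genes$gene_id
    feats$promoter <- GenomicRanges::reduce(prom_by_gene)

    if (!is.null(genes$utr5_len)) {
      u5s <- ifelse(plus, genes$start, genes$end - genes$utr5_len + 1L)
      u5e <- ifelse(plus, genes$start + genes$utr5_len - 1L, genes$end)
      u3s <- ifelse(plus, genes$end - genes$utr3_len + 1L, genes$start)
      u3e <- ifelse(plus, genes$end, genes$start + genes$utr3_len - 1L)
      feats$utr5 <- GenomicRanges::reduce(gr(genes$chrom, u5s, u5e))
      feats$utr3 <- GenomicRanges::reduce(gr(genes$chrom, u3s, u3e))
    } else {
      feats$utr5 <- empty
      feats$utr3 <- empty
    }
    body_gr <- gr(genes$chrom, genes$start, genes$end)
    if (!is.null(genes$intron_start)) {
      intron_gr <- gr(genes$chrom, genes$intron_start, genes$intron_end)
      feats$intron <- GenomicRanges::reduce(intron_gr)
      feats$exon <- GenomicRanges::setdiff(GenomicRanges::reduce(body_gr), feats$intron)
    } else {
      feats$intron <- empty
      feats$exon <- GenomicRanges::reduce(body_gr)
    }
    feats$gene_body <- GenomicRanges::reduce(body_gr)
  } else {
    prom_by_gene <- empty
    feats$promoter <- empty
    feats$utr5 <- empty
    feats$utr3 <- empty
    feats$exon <- empty
    feats$intron <- empty
    feats$gene_body <- empty
  }

  chroms <- unique(c(genes$chrom, cgis$chrom))
  structure(
    list(
      features = feats[setdiff(FEATURE_PRECEDENCE, "distal_intergenic")],
      promoters = prom_by_gene, genes = genes, chroms = chroms,
      promoter_up = promoter_up, promoter_down = promoter_down
    ),
    class = "feature_index"
  )
}

# primary label of arbitrary query ranges, by precedence
primary_label <- function(query, index) {
  lab <- rep(NA_character_, length(query))
  for (f in names(index$features)) {
    hit <- IRanges::overlapsAny(query, index$features[[f]])
    lab[is.na(lab) & hit] <- f
  }
  lab[is.na(lab)] <- "distal_intergenic"
  lab
}

#' Assign CpG sites to a primary genomic feature
#'
#' Each site gets exactly one label, resolved by the fixed precedence
#' CGI > shore > shelf > promoter > 5'UTR > 3'UTR > exon > intron >
#' gene body > distal intergenic. Sites on chromosomes unknown to the index
#' are returned as NA with a warning.
#'
#' @param mm a `meth_matrix` (or data frame with chrom, pos).
#' @param index a [build_feature_index()] result.
#' @return character vector of labels, one per site.
#' @export
assign_sites <- function(mm, index) {
  sites <- if (inherits(mm, "meth_matrix")) mm$sites else mm
  known <- sites$chrom %in% index$chroms
  lab <- rep(NA_character_, nrow(sites))
  if (any(!known)) {
    warning(sum(!known), " site(s) on chromosomes unknown to the index; excluded")
  }
  if (any(known)) {
    q <- GenomicRanges::GRanges(
      sites$chrom[known], IRanges::IRanges(sites$pos[known], sites$pos[known])
    )
    lab[known] <- primary_label(q, index)
  }
  lab
}

#' Mean methylation per feature and sample
#'
#' @param mm a `meth_matrix`.
#' @param labels per-site labels from [assign_sites()].
#' @return features x samples matrix of mean levels (NA where a feature has
#'   no defined level).
#' @export
feature_mean_levels <- function(mm, labels) {
  stopifnot(length(labels) == nrow(mm$sites))
  feats <- FEATURE_PRECEDENCE[FEATURE_PRECEDENCE %in% labels]
  out <- matrix(NA_real_, length(feats), ncol(mm$level),
    dimnames = list(feats, colnames(mm$level))
  )
  for (f in feats) {
    i <- which(labels == f)
    out[f, ] <- colMeans(mm$level[i, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Annotate regions with their primary feature and nearest gene
#'
#' Distance to the nearest TSS is signed in gene orientation: negative when
#' the region lies upstream of the TSS, zero when it contains the TSS. Ties
#' between equidistant TSSs are broken by gene id order.
#'
#' @param regions data frame chrom, start, end (1-based inclusive).
#' @param index a [build_feature_index()] result.
#' @return `regions` with added columns `feature`, `nearest_gene`,
#'   `dist_to_tss`.
#' @export
annotate_region <- function(regions, index) {
  genes <- index$genes
  if (nrow(regions) == 0) {
    regions$feature <- character()
    regions$nearest_gene <- character()
    regions$dist_to_tss <- numeric()
    return(regions)
  }
  q <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end)
  )
  regions$feature <- primary_label(q, index)
  regions$nearest_gene <- NA_character_
  regions$dist_to_tss <- NA_real_
  if (nrow(genes)) {
    # genes sorted by id so ties resolve deterministically
    genes <- genes[order(genes$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(regions))) {
      g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
      if (!nrow(g)) next
      d <- ifelse(
        g$tss >= regions$start[i] & g$tss <= regions$end[i], 0,
        ifelse(g$tss < regions$start[i], regions$start[i] - g$tss, regions$end[i] - g$tss)
      )
      # d > 0: region downstream of TSS in genomic coords; flip sign by strand
      signed <- ifelse(g$strand == "+", d, -d)
      j <- which.min(abs(d))
      regions$nearest_gene[i] <- g$gene_id[j]
      regions$dist_to_tss[i] <- signed[j]
    }
  }
  regions
}
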