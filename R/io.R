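#' Write a synthetic dataset to plain-text files
#'
#' Emits the standard exchange formats: one cytosine-report TSV per sample,
#' genes as BED6+ (name = gene id, thickStart/thickEnd unused), CpG islands
#' as BED3, the count matrix and design as TSV, and the ground truth as
#' JSON. BED output is 0-based half-open; all in-memory tables are 1-based
#' inclusive.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(dataset$methylomes)) {
    p <- file.path(dir, paste0(nm, ".cytosine_report.tsv"))
    write.table(dataset$methylomes[[nm]], p,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  g <- dataset$annotation$genes
  bed <- data.frame(
    chrom = g$chrom, start = g$start - 1L, end = g$end,
    name = g$gene_id, score = 0L, strand = g$strand
  )
  p <- file.path(dir, "genes.bed")
  write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- c(paths, p)
  ci <- dataset$annotation$cgis
  p <- file.path(dir, "cgis.bed")
  write.table(
    data.frame(ci$chrom, ci$start - 1L, ci$end), p,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  paths <- c(paths, p)
  p <- file.path(dir, "counts.tsv")
  cm <- data.frame(
    gene_id = rownames(dataset$expression$counts),
    length = dataset$expression$gene_lengths[rownames(dataset$expression$counts)],
    dataset$expression$counts, check.names = FALSE
  )
  write.table(cm, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "design.tsv")
  write.table(dataset$expression$design, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    lapply(unclass(dataset$truth), as.data.frame), p,
    dataframe = "columns", digits = NA, pretty = TRUE
  )
  paths <- c(paths, p)
  invisible(paths)
}

#' Export DMRs as BED6+
#'
#' name = direction, score = -10 log10(q) capped at 1000; positions
#' converted to 0-based half-open.
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(round(-10 * log10(pmax(dmrs$q_value, 1e-100))), 1000)
  bed <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
    name = dmrs$direction, score = score, strand = "."
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export per-sample methylation levels as bedGraph
#'
#' One file per sample: chrom, 0-based start, end, level.
#'
#' @param mm a `meth_matrix`.
#' @param dir output directory.
#' @export
write_bedgraph <- function(mm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in colnames(mm$level)) {
    ok <- !is.na(mm$level[, nm])
    p <- file.path(dir, paste0(nm, ".bedGraph"))
    write.table(
      data.frame(mm$sites$chrom[ok], mm$sites$pos[ok] - 1L,
        mm$sites$pos[ok], mm$level[ok, nm]),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a gene-count matrix with lengths
#'
#' Expects the layout written by [write_dataset()]: gene_id, length, then
#' one column per sample.
#'
#' @param path counts TSV.
#' @return list with `counts` and `gene_lengths`.
#' @export
read_counts <- function(path) {
  t <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  counts <- as.matrix(t[, -(1:2), drop = FALSE])
  rownames(counts) <- t$gene_id
  list(counts = counts, gene_lengths = setNames(t$length, t$gene_id))
}
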