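# On-disk formats: FASTA via Biostrings, BED6/bedGraph via rtracklayer
# (1-based in memory, 0-based half-open on disk), TSV via base utils.

#' Write a genome to FASTA
#' @param sequence genome string.
#' @param path output file.
#' @param name sequence name.
#' @export
write_genome_fasta <- function(sequence, path, name = "sim") {
  seqs <- Biostrings::DNAStringSet(stats::setNames(sequence, name))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read the first sequence of a FASTA file as a string
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path)[[1L]])
}

#' Write per-position counts as BED6 (count in the score field)
#' @param df data frame with columns `pos`, `strand` and `count` (tag files)
#'   or just `pos`, `strand` (read anchors; scores written as 1).
#' @param path output file.
#' @param chrom chromosome name.
#' @export
write_bed6 <- function(df, path, chrom = "sim") {
  score <- if ("count" %in% names(df)) df$count else rep(1L, nrow(df))
  strand <- if ("strand" %in% names(df)) df$strand else rep("+", nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = df$pos, width = 1L),
    strand = strand)
  gr$name <- rep(".", nrow(df))
  gr$score <- score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 file of per-position counts
#' @param path BED file written by [write_bed6()] (or compatible).
#' @return data frame with `pos` (1-based), `strand`, `count`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(pos = GenomicRanges::start(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             count = if (!is.null(gr$score)) as.numeric(gr$score) else 1,
             stringsAsFactors = FALSE)
}

#' Write a per-position track as bedGraph
#' @param track numeric vector over genome positions.
#' @param path output file.
#' @param chrom chromosome name.
#' @export
write_bedgraph <- function(track, path, chrom = "sim") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write/read a plain TSV table
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read aligned strain triples from TSV
#'
#' Four columns: focal-strain coordinate, focal base, sister base, outgroup
#' base — the columnar three-strain alignment consumed by the ancestral
#' inference.
#' @param path TSV file.
#' @return data frame with columns `coord`, `focal`, `sister`, `outgroup`.
#' @export
read_alignment_triples <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character",
                                         "character"))
  names(df) <- c("coord", "focal", "sister", "outgroup")
  if (is.unsorted(df$coord, strictly = TRUE)) {
    stop("alignment coordinates must be strictly increasing")
  }
  df
}
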