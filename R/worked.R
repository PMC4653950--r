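# Small worked-arithmetic helpers for sequencing-library summaries.

#' Genome coverage of a single-end nucleosome library
#'
#' Coverage is the number of uniquely mapped reads multiplied by the
#' assumed mono-nucleosome fragment length and divided by the genome size:
#' each read stands for one protected fragment.
#'
#' @param uniquely_mapped_reads read count.
#' @param fragment_length assumed fragment length in bp (default 147).
#' @param genome_size genome size in bp.
#' @return fold coverage.
#' @export
genome_coverage <- function(uniquely_mapped_reads, fragment_length = 147,
                            genome_size) {
  uniquely_mapped_reads * fragment_length / genome_size
}

#' Unique-mapping ratio of a sequencing library
#'
#' @param uniquely_mapped_reads uniquely aligned read count.
#' @param total_reads collected read count.
#' @return percentage of reads aligned to unique positions.
#' @export
mapping_ratio <- function(uniquely_mapped_reads, total_reads) {
  100 * uniquely_mapped_reads / total_reads
}
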