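# Aligned-fragment input: SAM/BAM via Rsamtools, BED via rtracklayer.
#
# Fragments are plain data frames (chrom, start, end, strand,
# sample_id) with 0-based half-open coordinates, the carrier consumed
# by count_fragments().

#' Read aligned fragments from SAM/BAM or BED
#'
#' SAM/BAM records that are unmapped, secondary or supplementary are
#' skipped; 1-based POS is converted to 0-based start and the end is
#' start + aligned reference span (from the CIGAR). BED intervals pass
#' through unchanged (BED is already 0-based half-open).
#'
#' @param path path to a `.sam`, `.bam` or `.bed` file.
#' @param sample_id sample identifier attached to every fragment.
#' @param genome optional [genome_index()]; when given, fragments on
#'   chromosomes absent from it raise an error naming the record.
#' @param min_mapq minimum mapping quality for SAM/BAM records
#'   (default 0 = no filter; the aligner's defaults are trusted).
#' @return data.frame with columns chrom, start, end, strand,
#'   sample_id.
#' @export
read_alignments <- function(path, sample_id, genome = NULL, min_mapq = 0) {
  if (!file.exists(path)) stop_medip("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  frags <- switch(
    ext,
    bed = read_fragments_bed(path, sample_id),
    sam = ,
    bam = read_fragments_bam(path, sample_id, is_sam = identical(ext, "sam"),
                             min_mapq = min_mapq),
    stop_medip("unknown alignment format '.", ext,
               "'; accepted formats: SAM, BAM, BED")
  )
  if (!is.null(genome)) {
    bad <- which(!(frags$chrom %in% genome$chrom_names))
    if (length(bad))
      stop_medip("fragment ", bad[1], " (", frags$chrom[bad[1]], ":",
                 frags$start[bad[1]], "-", frags$end[bad[1]],
                 ") references a chromosome absent from the genome")
  }
  frags
}

#' @noRd
read_fragments_bed <- function(path, sample_id) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "+"
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # GRanges is 1-based inclusive
    end = BiocGenerics::end(gr),
    strand = st,
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' @noRd
read_fragments_bam <- function(path, sample_id, is_sam, min_mapq = 0) {
  if (is_sam) {
    tmp <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = tmp, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("rname", "pos", "cigar", "strand", "mapq"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(rec$pos)
  if (min_mapq > 0) keep <- keep & !is.na(rec$mapq) & rec$mapq >= min_mapq
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  data.frame(
    chrom = as.character(rec$rname[keep]),
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + span,
    strand = as.character(rec$strand[keep]),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Write fragments as 6-column BED
#'
#' @param frags fragment data.frame as returned by [read_alignments()].
#' @param path output path.
#' @export
write_fragments_bed <- function(frags, path) {
  df <- data.frame(frags$chrom, frags$start, frags$end,
                   name = if (is.null(frags$sample_id)) "." else frags$sample_id,
                   score = 0L, strand = frags$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
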