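# Genome index: chromosome sizes plus CpG dinucleotide positions.
#
# CpG sites are scanned on the forward strand only: a CG dinucleotide is
# its own reverse complement, so counting one strand counts each
# methylatable site once. All coordinates are 0-based half-open
# internally.

#' Construct a genome index
#'
#' A `GenomeIndex` holds ordered chromosome names, chromosome lengths
#' (bp) and, per chromosome, the sorted 0-based positions of the C of
#' every CG dinucleotide on the forward strand.
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer vector of chromosome lengths in bp,
#'   parallel to `chrom_names`.
#' @param cpg_positions named list (one element per chromosome) of
#'   strictly increasing 0-based CpG positions.
#' @return An object of class `GenomeIndex`.
#' @export
genome_index <- function(chrom_names, chrom_lengths, cpg_positions) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names))
    stop_medip("duplicated chromosome names in genome index")
  if (length(chrom_lengths) != length(chrom_names))
    stop_medip("chrom_lengths must parallel chrom_names")
  chrom_lengths <- as.numeric(chrom_lengths)
  names(chrom_lengths) <- chrom_names
  if (is.null(names(cpg_positions))) names(cpg_positions) <- chrom_names
  cpg_positions <- lapply(cpg_positions, function(p) sort(as.numeric(p)))
  for (cn in chrom_names) {
    p <- cpg_positions[[cn]]
    if (is.null(p)) {
      cpg_positions[[cn]] <- numeric(0)
      next
    }
    if (length(p) && (anyDuplicated(p) || any(p < 0) ||
                      any(p >= chrom_lengths[[cn]] - 1)))
      stop_medip("invalid CpG positions on ", cn,
                 ": must be unique, >= 0 and < length - 1")
  }
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = chrom_lengths,
         cpg_positions = cpg_positions[chrom_names]),
    class = "GenomeIndex"
  )
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp,",
      format(sum(lengths(x$cpg_positions)), big.mark = ","), "CpG sites\n")
  invisible(x)
}

#' Read a genome FASTA and index its CpG sites
#'
#' Sequences are read with Biostrings (case is normalized to upper
#' case, so soft-masked references are handled); CpG positions are the
#' 0-based indices i with sequence[i..i+1] == "CG".
#'
#' @param path path to a FASTA file.
#' @return A [genome_index()] object.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_medip("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_medip("malformed FASTA '", path, "': ",
                                   conditionMessage(e))
  )
  if (length(seqs) == 0L)
    stop_medip("FASTA file '", path, "' contains no sequences")
  # header up to first whitespace is the chromosome name
  nms <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- nms
  hits <- Biostrings::vmatchPattern("CG", seqs)
  cpg <- lapply(Biostrings::startIndex(hits), function(s) {
    if (is.null(s)) numeric(0) else as.numeric(s) - 1
  })
  names(cpg) <- nms
  genome_index(nms, Biostrings::width(seqs), cpg)
}

#' Count CpG sites in genomic intervals
#'
#' Counts CpG positions p (position of the C) with start <= p < end.
#'
#' @param genome a [genome_index()].
#' @param chrom,start,end parallel vectors describing 0-based half-open
#'   intervals.
#' @return Integer vector of CpG counts.
#' @export
count_cpgs <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "GenomeIndex"))
  chrom <- as.character(chrom)
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop_medip("chrom, start, end must have equal length")
  out <- integer(n)
  for (cn in unique(chrom)) {
    if (!cn %in% genome$chrom_names)
      stop_medip("chromosome '", cn, "' not in genome index")
    idx <- which(chrom == cn)
    bad <- start[idx] < 0 | end[idx] > genome$chrom_lengths[[cn]] |
      start[idx] >= end[idx]
    if (any(bad))
      stop_medip("interval outside chromosome ", cn)
    p <- genome$cpg_positions[[cn]]
    # findInterval on sorted positions: count of p < bound
    out[idx] <- findInterval(end[idx] - 0.5, p) -
      findInterval(start[idx] - 0.5, p)
  }
  out
}
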