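# Gene annotation input (GFF3 or BED) and the sample sheet.

#' Read gene annotation from GFF3 or BED
#'
#' From GFF3 only records of type `gene` are loaded and their 1-based
#' inclusive coordinates converted to 0-based half-open; in BED every
#' record is taken as a gene (name column = gene id). Gene ids come
#' from the `ID` attribute (falling back to `gene_id` / `Name`).
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file.
#' @return data.frame with columns gene_id, gene_name, chrom, start,
#'   end, strand (0-based half-open).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_medip("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- if (is.null(gr$ID)) rep(NA_character_, length(gr))
           else as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$gene_id)) ids <- as.character(gr$gene_id)
    nms <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
    if (anyNA(ids)) {
      miss <- which(is.na(ids))[1]
      stop_medip("gene record ", miss, " in '", path,
                 "' lacks an ID attribute")
    }
    nms[is.na(nms)] <- ids[is.na(nms)]
    genes <- data.frame(
      gene_id = ids, gene_name = nms,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
    st <- as.character(BiocGenerics::strand(gr))
    st[st == "*"] <- "+"
    genes <- data.frame(
      gene_id = ids, gene_name = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = st,
      stringsAsFactors = FALSE)
  } else {
    stop_medip("unknown annotation format '.", ext,
               "'; accepted formats: GFF3, BED")
  }
  if (anyDuplicated(genes$gene_id))
    stop_medip("duplicated gene_id in annotation: ",
               genes$gene_id[anyDuplicated(genes$gene_id)])
  if (any(genes$start >= genes$end))
    stop_medip("annotation contains a gene with start >= end")
  rownames(genes) <- NULL
  genes
}

#' Read or write a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `group`
#' (case/control), `cohort` (e.g. mother, father, female_child,
#' male_child) and `path` (source alignment or count file; may be
#' empty for simulated data).
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "cohort")
  if (!all(need %in% names(ss)))
    stop_medip("sample sheet must have columns: ",
               paste(need, collapse = ", "))
  if (anyDuplicated(ss$sample_id))
    stop_medip("duplicated sample_id in sample sheet")
  if (!all(ss$group %in% c("case", "control")))
    stop_medip("sample sheet group must be 'case' or 'control'")
  if (is.null(ss$path)) ss$path <- NA_character_
  ss
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
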