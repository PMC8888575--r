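# Tabular outputs: DMR tables (TSV, 1-based inclusive coordinates for
# display, NCBI-style), DMR BED, and per-window BEDGraph tracks.
# Internal coordinates are 0-based half-open everywhere; conversion
# happens only at the file boundary, and write-then-read restores the
# internal values exactly.

# shortest decimal representation that parses back to the same double
#' @noRd
format_roundtrip <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

DMR_TABLE_COLS <- c("name", "chrom", "start", "stop", "n_windows",
                    "n_sig_windows", "min_p", "fdr_q",
                    "log2_fold_change", "cpg_count", "cpg_per_100bp",
                    "genes")

#' Write a DMR table as TSV
#'
#' One row per DMR with name, chromosome, start and stop nucleotide
#' (1-based inclusive in the file), total and significant window
#' counts, minimum window p-value, its BH FDR q, log2 fold change,
#' CpG count and density per 100 bp, and associated gene ids
#' (comma-separated). Numeric fields are printed with enough digits
#' to round-trip exactly through [read_dmr_table()].
#'
#' @param dmrs DMR data.frame from [call_dmrs()] (0-based half-open
#'   internally); may be empty.
#' @param path output TSV path.
#' @export
write_dmr_table <- function(dmrs, path) {
  df <- data.frame(
    name = as.character(dmrs$name),
    chrom = as.character(dmrs$chrom),
    start = dmrs$start + 1,      # 1-based inclusive for display
    stop = dmrs$end,
    n_windows = dmrs$n_windows,
    n_sig_windows = dmrs$n_sig_windows,
    min_p = format_roundtrip(dmrs$min_p),
    fdr_q = format_roundtrip(dmrs$fdr_q),
    log2_fold_change = format_roundtrip(dmrs$log2_fold_change),
    cpg_count = dmrs$cpg_count,
    cpg_per_100bp = format_roundtrip(dmrs$cpg_per_100bp),
    genes = if (is.null(dmrs$genes)) rep("", nrow(dmrs))
            else as.character(dmrs$genes),
    stringsAsFactors = FALSE)
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop_medip("cannot write '", path,
                                                 "': ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dmr_table
#' @return `read_dmr_table` returns the DMR data.frame with internal
#'   0-based half-open coordinates restored.
#' @export
read_dmr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(genes = "character"))
  if (!all(DMR_TABLE_COLS %in% names(df)))
    stop_medip("'", path, "' is not a DMR table (missing columns)")
  out <- data.frame(
    name = as.character(df$name), chrom = as.character(df$chrom),
    start = as.numeric(df$start - 1), end = as.numeric(df$stop),
    n_windows = as.integer(df$n_windows),
    n_sig_windows = as.integer(df$n_sig_windows),
    min_p = as.numeric(df$min_p), fdr_q = as.numeric(df$fdr_q),
    log2_fold_change = as.numeric(df$log2_fold_change),
    cpg_count = as.integer(df$cpg_count),
    cpg_per_100bp = as.numeric(df$cpg_per_100bp),
    genes = as.character(df$genes),
    stringsAsFactors = FALSE)
  out$genes[is.na(out$genes)] <- ""
  out
}

#' Write DMRs as a BED track
#'
#' @param dmrs DMR data.frame.
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  df <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$name,
                   score = pmin(1000, round(-10 * log10(dmrs$min_p))),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-window -log10(p) as BEDGraph
#'
#' For genome-browser inspection of the window test track.
#'
#' @param results window test results from [test_windows()].
#' @param path output path.
#' @export
write_pvalue_bedgraph <- function(results, path) {
  df <- data.frame(results$chrom, results$start, results$end,
                   round(-log10(results$p_value), 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write window test results as TSV
#'
#' @param results window test results from [test_windows()].
#' @param path output TSV path.
#' @export
write_test_results <- function(results, path) {
  df <- results
  for (col in c("p_value", "log2_fold_change", "fdr_q"))
    df[[col]] <- format_roundtrip(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_test_results
#' @export
read_test_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
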