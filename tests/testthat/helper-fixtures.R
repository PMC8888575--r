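# Programmatic fixtures: tiny FASTA/SAM/BED/GFF3 files and cheap
# in-memory objects built at test time.

write_fasta_fixture <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]])))
  writeLines(lines, path)
  path
}

# minimal single-chromosome SAM with given records
# records: data.frame(qname, flag, pos, mapq, cigar)
write_sam_fixture <- function(records, chrom = "c1", chrom_len = 10000,
                              path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  read_len <- function(cigar) {
    # bases consuming the query: M, I, S, =, X
    hits <- regmatches(cigar,
                       gregexpr("[0-9]+(?=[MIS=X])", cigar, perl = TRUE))[[1]]
    max(1, sum(as.numeric(hits)))
  }
  body <- vapply(seq_len(nrow(records)), function(i) {
    rl <- read_len(records$cigar[i])
    paste(records$qname[i], records$flag[i], chrom, records$pos[i],
          records$mapq[i], records$cigar[i], "*", 0, 0,
          strrep("A", rl), strrep("I", rl), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

write_bed_fixture <- function(df, path = tempfile(fileext = ".bed")) {
  if (is.null(df$name)) df$name <- "."
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "+"
  write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

write_gff_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# GenomeIndex without sequences: enough for tiling/simulation tests
toy_genome_index <- function(n_chroms = 1, len = 1e5, cpg = NULL) {
  nms <- paste0("chr", seq_len(n_chroms))
  if (is.null(cpg)) cpg <- lapply(nms, function(x) numeric(0))
  genome_index(nms, rep(len, n_chroms), cpg)
}

# window test results table from a vector of p-values on a 1-kb grid
make_results <- function(p, chrom = "chr1", w = 1000, lfc = NULL) {
  n <- length(p)
  if (is.null(lfc)) lfc <- rep(1, n)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * w,
             end = seq_len(n) * w, p_value = p,
             log2_fold_change = lfc, fdr_q = bh_fdr(p),
             stringsAsFactors = FALSE)
}

# small two-group NB dataset for stats tests
quick_dataset <- function(seed = 1, n_windows = 2000, n_case = 12,
                          n_control = 12, phi = 0.1, fold = 1,
                          n_planted = 0, baseline = 50,
                          spread = c(0.5, 2), width = 1) {
  genome <- toy_genome_index(1, n_windows * 1000)
  cfg <- simulation_config(
    seed = seed, n_chroms = 1, chrom_length = n_windows * 1000,
    n_case = n_case, n_control = n_control, baseline_mean = baseline,
    dispersion = phi, libsize_spread = spread, n_planted = n_planted,
    planted_fold_change = fold,
    planted_width_windows = width)
  simulate_dataset(cfg, genome)
}
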