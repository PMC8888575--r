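# Gene association within a distance cutoff, exact and extended
# cross-cohort DMR overlap, and chromosomal clustering. Interval
# algebra goes through GenomicRanges; distances are edge-to-edge on a
# strand-agnostic coordinate line, 0 for intersecting intervals.

#' @noRd
.as_granges <- function(df, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(df$chrom)
  GenomicRanges::GRanges(
    factor(df$chrom, levels = seqlevels),
    IRanges::IRanges(start = df$start + 1, end = df$end))  # to 1-based
}

# shared seqlevels for cross-set interval operations (avoids spurious
# Seqinfo merge warnings when chromosome sets differ)
#' @noRd
.shared_levels <- function(...) {
  unique(unlist(lapply(list(...), function(d) unique(d$chrom))))
}

#' Associate genes with DMRs
#'
#' A gene is associated when the minimum genomic gap between the DMR
#' and gene intervals is at most `max_distance` (default 10 kb,
#' covering proximal and distal promoters as well as the gene body;
#' 0 for overlapping intervals). Qualifying gene ids are listed
#' sorted by distance then id, comma-separated, in the `genes`
#' column.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param genes gene data.frame from [read_annotation()].
#' @param max_distance association cutoff in bp (default 10000).
#' @return `dmrs` with the `genes` column filled.
#' @export
associate_genes <- function(dmrs, genes, max_distance = 10000) {
  if (max_distance < 0) stop_medip("max_distance must be >= 0")
  if (!nrow(dmrs)) return(dmrs)
  dmrs$genes <- ""
  if (!nrow(genes)) return(dmrs)
  lv <- .shared_levels(dmrs, genes)
  gr_d <- .as_granges(dmrs, lv)
  gr_g <- .as_granges(genes, lv)
  # max_distance 0 means pure intersection: book-ended intervals
  # (gap 0 but no shared base) only qualify at a positive cutoff
  hits <- GenomicRanges::findOverlaps(
    gr_d, gr_g, maxgap = if (max_distance == 0) -1L else max_distance)
  if (!length(hits)) return(dmrs)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(gr_d[qh], gr_g[sh])
  for (i in unique(qh)) {
    sel <- qh == i
    ids <- genes$gene_id[sh[sel]]
    ord <- order(d[sel], ids)
    dmrs$genes[i] <- paste(ids[ord], collapse = ",")
  }
  dmrs
}

#' Exact DMR overlap between two cohorts
#'
#' A DMR of cohort A is shared when it genomically intersects (>= 1
#' bp, half-open semantics: book-ended intervals do not intersect)
#' any DMR of cohort B. `n_shared` counts A-side DMRs and
#' `percent_of_a` normalizes by A's DMR count, matching the row-wise
#' percent convention of cross-group overlap tables.
#'
#' @param dmrs_a,dmrs_b DMR data.frames.
#' @param label_a,label_b cohort labels for the report.
#' @return list of class `OverlapReport`: `report` (one-row
#'   data.frame: cohort_a, cohort_b, mode, n_a, n_b, n_shared,
#'   percent_of_a) and `shared_pairs` (indices of intersecting
#'   pairs).
#' @export
overlap_exact <- function(dmrs_a, dmrs_b, label_a = "A", label_b = "B") {
  if (nrow(dmrs_a) && nrow(dmrs_b)) {
    lv <- .shared_levels(dmrs_a, dmrs_b)
    hits <- GenomicRanges::findOverlaps(.as_granges(dmrs_a, lv),
                                        .as_granges(dmrs_b, lv))
    shared <- unique(S4Vectors::queryHits(hits))
    pairs <- data.frame(idx_a = S4Vectors::queryHits(hits),
                        idx_b = S4Vectors::subjectHits(hits))
  } else {
    shared <- integer(0)
    pairs <- data.frame(idx_a = integer(0), idx_b = integer(0))
  }
  structure(
    list(report = data.frame(
           cohort_a = label_a, cohort_b = label_b, mode = "exact",
           n_a = nrow(dmrs_a), n_b = nrow(dmrs_b),
           n_shared = length(shared),
           percent_of_a = if (nrow(dmrs_a)) 100 * length(shared) / nrow(dmrs_a)
                          else NA_real_,
           stringsAsFactors = FALSE),
         shared_pairs = pairs),
    class = "OverlapReport")
}

#' Extended DMR overlap against relaxed windows of another cohort
#'
#' A DMR of cohort A (called at the strict seed threshold) counts as
#' overlapping when it intersects any window of cohort B with
#' p below `relaxed_p` (default 0.05) — the extended overlap that
#' asks whether the other cohort shows sub-threshold signal at the
#' same loci.
#'
#' @param dmrs_a DMR data.frame of cohort A.
#' @param window_results_b [test_windows()] results of cohort B, on
#'   the same window grid.
#' @param relaxed_p relaxed threshold (must exceed the seed
#'   threshold used for A).
#' @param label_a,label_b cohort labels.
#' @param p_sig seed threshold A was called at (for validation).
#' @return An `OverlapReport` (mode "extended").
#' @export
overlap_extended <- function(dmrs_a, window_results_b,
                             relaxed_p = 0.05,
                             label_a = "A", label_b = "B",
                             p_sig = 1e-4) {
  if (relaxed_p <= p_sig)
    stop_medip("relaxed_p must exceed the seed threshold")
  wsize <- window_results_b$end - window_results_b$start
  if (nrow(dmrs_a)) {
    w <- max(wsize)
    if (any(dmrs_a$start %% w != 0 & dmrs_a$start != 0) &&
        all(window_results_b$start %% w == 0))
      stop_medip("DMRs and windows come from mismatched grids")
  }
  hot <- window_results_b[window_results_b$p_value < relaxed_p, ,
                          drop = FALSE]
  if (nrow(dmrs_a) && nrow(hot)) {
    lv <- .shared_levels(dmrs_a, hot)
    hits <- GenomicRanges::findOverlaps(.as_granges(dmrs_a, lv),
                                        .as_granges(hot, lv))
    shared <- unique(S4Vectors::queryHits(hits))
  } else shared <- integer(0)
  structure(
    list(report = data.frame(
           cohort_a = label_a, cohort_b = label_b, mode = "extended",
           n_a = nrow(dmrs_a), n_b = NA_integer_,
           n_shared = length(shared),
           percent_of_a = if (nrow(dmrs_a)) 100 * length(shared) / nrow(dmrs_a)
                          else NA_real_,
           stringsAsFactors = FALSE),
         shared_pairs = NULL),
    class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Venn-style partition of several DMR sets
#'
#' All DMR intervals across the sets are merged into connected
#' components (genomic intersection as the link); each component is
#' classified by which cohorts contribute to it and counts are
#' reported per membership combination.
#'
#' @param dmr_sets named list of DMR data.frames.
#' @return data.frame: combination (e.g. "mother+father"),
#'   n_components.
#' @export
venn_partition <- function(dmr_sets) {
  stopifnot(is.list(dmr_sets), !is.null(names(dmr_sets)))
  all_df <- do.call(rbind, lapply(names(dmr_sets), function(nm) {
    d <- dmr_sets[[nm]]
    if (!nrow(d)) return(NULL)
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               set = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(all_df))
    return(data.frame(combination = character(0),
                      n_components = integer(0)))
  gr <- .as_granges(all_df)
  comp <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(comp, gr)
  member <- tapply(all_df$set[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits),
                   function(s) paste(sort(unique(s)), collapse = "+"))
  tab <- table(unlist(member))
  data.frame(combination = names(tab),
             n_components = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Chromosomal DMR clusters
#'
#' Single-linkage grouping of DMRs along each chromosome with
#' inter-DMR gap at most `cluster_gap` (default 2 Mb, a descriptive
#' choice for ideogram-style location figures); clusters of size >= 2
#' are reported with their spans.
#'
#' @param dmrs DMR data.frame.
#' @param cluster_gap linkage gap in bp.
#' @return data.frame: chrom, start, end, n_dmrs, dmr_names.
#' @export
cluster_summary <- function(dmrs, cluster_gap = 2e6) {
  if (cluster_gap <= 0) stop_medip("cluster_gap must be positive")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_dmrs = integer(0),
                      dmr_names = character(0), stringsAsFactors = FALSE)
  if (!nrow(dmrs)) return(empty)
  out <- list()
  for (cn in unique(dmrs$chrom)) {
    d <- dmrs[dmrs$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    gap_prev <- c(Inf, d$start[-1] - d$end[-nrow(d)])
    cl <- cumsum(gap_prev > cluster_gap)
    for (g in unique(cl)) {
      sel <- cl == g
      if (sum(sel) < 2) next
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, start = min(d$start[sel]), end = max(d$end[sel]),
        n_dmrs = sum(sel),
        dmr_names = paste(d$name[sel], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Write overlap reports as TSV
#'
#' @param reports list of `OverlapReport` objects.
#' @param path output TSV path.
#' @export
write_overlap_table <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) r$report))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
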