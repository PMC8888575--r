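# DMR calling: windows with p below the seed threshold (1e-4) start a
# DMR; edges are then extended until no window with p below the edge
# threshold (0.1) remains within the reach (1000 bp) of the DMR span.
# "Within 1000 bp" is read strictly: a window qualifies when at least
# one of its bases lies among the `edge_reach` bases flanking the
# current span, i.e. its edge-to-edge gap is < edge_reach. Absorption
# iterates to a fixed point; seeds whose grown spans meet merge into
# one DMR.
#
# Because the span only ever grows by absorbing qualifying windows,
# the fixed point equals single-linkage chaining of the qualifying
# (p < p_edge) windows with inter-window gap < edge_reach, keeping
# chains that contain at least one seed; the implementation uses that
# closed form, and the test suite checks it against a literal
# iterated-absorption reference.

#' DMR calling parameters
#'
#' @param p_sig seed significance threshold (default 1e-4; strict
#'   inequality p < p_sig).
#' @param p_edge extension threshold (default 0.1).
#' @param edge_reach reach of the extension rule in bp (default 1000).
#' @param contiguous_only when TRUE, extension only absorbs windows
#'   whose gap to the span is 0 (no bridging over absent windows).
#' @return list of class `DmrCallParams`.
#' @export
dmr_call_params <- function(p_sig = 1e-4, p_edge = 0.1,
                            edge_reach = 1000,
                            contiguous_only = FALSE) {
  if (!(p_sig < p_edge && p_edge <= 1))
    stop_medip("need p_sig < p_edge <= 1")
  if (edge_reach <= 0) stop_medip("edge_reach must be positive")
  structure(list(p_sig = p_sig, p_edge = p_edge,
                 edge_reach = edge_reach,
                 contiguous_only = contiguous_only),
            class = "DmrCallParams")
}

#' Call DMRs from window test results
#'
#' @param results a [test_windows()] data.frame (chrom, start, end,
#'   p_value, log2_fold_change, fdr_q), windows sorted and
#'   non-overlapping within each chromosome.
#' @param params a [dmr_call_params()].
#' @param cohort cohort label used in DMR names
#'   (`cohort:chrom:ordinal`).
#' @param genome optional [genome_index()]; when given, CpG count,
#'   density and desert flag are filled in.
#' @param logfc_from "min_p" (default: fold change of the minimum-p
#'   window) or "mean_sig" (mean over significant windows).
#' @return DMR data.frame (possibly 0 rows): name, chrom, start, end
#'   (0-based half-open), n_windows, n_sig_windows, min_p, fdr_q,
#'   log2_fold_change, cpg_count, cpg_per_100bp, cpg_desert, genes.
#' @export
call_dmrs <- function(results, params = dmr_call_params(),
                      cohort = "dmr", genome = NULL,
                      logfc_from = c("min_p", "mean_sig")) {
  logfc_from <- match.arg(logfc_from)
  stopifnot(inherits(params, "DmrCallParams"))
  need <- c("chrom", "start", "end", "p_value", "log2_fold_change")
  if (!all(need %in% names(results)))
    stop_medip("results must have columns: ", paste(need, collapse = ", "))
  if (is.null(results$fdr_q)) results$fdr_q <- bh_fdr(results$p_value)
  out <- list()
  for (cn in unique(results$chrom)) {
    r <- results[results$chrom == cn, , drop = FALSE]
    if (is.unsorted(r$start, strictly = TRUE))
      stop_medip("windows on ", cn, " are not sorted")
    if (any(r$start[-1] < r$end[-nrow(r)]))
      stop_medip("windows on ", cn, " overlap")
    spans <- .chain_windows(r, params)
    if (!nrow(spans)) next
    dmr <- lapply(seq_len(nrow(spans)), function(i) {
      inside <- r$start < spans$end[i] & r$end > spans$start[i]
      sig <- inside & r$p_value < params$p_sig
      imin <- which(inside)[which.min(r$p_value[inside])]
      lfc <- if (logfc_from == "min_p") r$log2_fold_change[imin]
        else mean(r$log2_fold_change[sig])
      data.frame(chrom = cn, start = spans$start[i], end = spans$end[i],
                 n_windows = sum(inside), n_sig_windows = sum(sig),
                 min_p = r$p_value[imin], fdr_q = r$fdr_q[imin],
                 log2_fold_change = lfc, stringsAsFactors = FALSE)
    })
    out[[cn]] <- do.call(rbind, dmr)
  }
  if (!length(out)) {
    dmrs <- data.frame(name = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       n_windows = integer(0), n_sig_windows = integer(0),
                       min_p = numeric(0), fdr_q = numeric(0),
                       log2_fold_change = numeric(0),
                       cpg_count = integer(0), cpg_per_100bp = numeric(0),
                       cpg_desert = logical(0), genes = character(0),
                       stringsAsFactors = FALSE)
    return(dmrs)
  }
  dmrs <- do.call(rbind, out)
  dmrs <- dmrs[order(match(dmrs$chrom, unique(results$chrom)),
                     dmrs$start), ]
  ord <- stats::ave(seq_len(nrow(dmrs)), dmrs$chrom,
                    FUN = seq_along)
  dmrs <- data.frame(name = paste(cohort, dmrs$chrom, ord, sep = ":"),
                     dmrs, stringsAsFactors = FALSE)
  dmrs$cpg_count <- NA_integer_
  dmrs$cpg_per_100bp <- NA_real_
  dmrs$cpg_desert <- NA
  dmrs$genes <- ""
  rownames(dmrs) <- NULL
  if (!is.null(genome)) dmrs <- dmr_cpg_density(dmrs, genome)
  dmrs
}

# single-linkage chains of qualifying windows; returns spans of
# chains containing >= 1 seed
#' @noRd
.chain_windows <- function(r, params) {
  qual <- which(r$p_value < params$p_edge)
  seed <- r$p_value < params$p_sig
  if (!any(seed)) return(data.frame(start = numeric(0), end = numeric(0)))
  qs <- r$start[qual]
  qe <- r$end[qual]
  gap_prev <- c(Inf, qs[-1] - qe[-length(qual)])
  linked <- if (params$contiguous_only) gap_prev <= 0
    else gap_prev < params$edge_reach
  chain <- cumsum(!linked)
  keep <- tapply(seed[qual], chain, any)
  spans <- data.frame(
    start = tapply(qs, chain, min)[keep],
    end = tapply(qe, chain, max)[keep])
  rownames(spans) <- NULL
  spans
}

#' CpG density of DMRs
#'
#' Counts CG dinucleotides (position of the C) inside each DMR
#' interval, computes the density per 100 bp, and flags CpG deserts
#' (density below 3 CpG/100 bp; islands run around 8-10).
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param genome a [genome_index()].
#' @return `dmrs` with cpg_count, cpg_per_100bp and cpg_desert filled.
#' @export
dmr_cpg_density <- function(dmrs, genome) {
  if (!nrow(dmrs)) return(dmrs)
  dmrs$cpg_count <- count_cpgs(genome, dmrs$chrom, dmrs$start, dmrs$end)
  dmrs$cpg_per_100bp <- 100 * dmrs$cpg_count / (dmrs$end - dmrs$start)
  dmrs$cpg_desert <- dmrs$cpg_per_100bp < 3
  dmrs
}

#' DMR counts across significance thresholds
#'
#' Re-calls DMRs at each seed threshold (edge parameters unchanged)
#' and tabulates the total ("all-window") and multiple-significant-
#' window counts, plus the increase/decrease split of DMR fold
#' changes at the default threshold.
#'
#' @param results a [test_windows()] data.frame.
#' @param thresholds p-value cutoffs to tabulate.
#' @param params baseline [dmr_call_params()]; `params$p_sig` is the
#'   threshold at which the fold-change split is reported.
#' @return list of class `dmr_summary`: `by_threshold` (data.frame
#'   threshold, n_all, n_multiple), `n_increase`, `n_decrease`,
#'   `increase_fraction`.
#' @export
summarize_dmrs <- function(results,
                           thresholds = c(1e-2, 1e-3, 1e-4, 1e-5,
                                          1e-6, 1e-7),
                           params = dmr_call_params()) {
  rows <- lapply(thresholds, function(th) {
    p <- params
    p$p_sig <- th
    p$p_edge <- max(p$p_edge, th * 1.0000001)  # keep p_sig < p_edge valid
    d <- call_dmrs(results, p)
    data.frame(threshold = th, n_all = nrow(d),
               n_multiple = sum(d$n_sig_windows >= 2))
  })
  d0 <- call_dmrs(results, params)
  n_inc <- sum(d0$log2_fold_change > 0)
  n_dec <- sum(d0$log2_fold_change < 0)
  structure(list(by_threshold = do.call(rbind, rows),
                 n_increase = n_inc, n_decrease = n_dec,
                 increase_fraction = if (nrow(d0)) n_inc / nrow(d0)
                                     else NA_real_),
            class = "dmr_summary")
}

#' @export
print.dmr_summary <- function(x, ...) {
  cat("DMR counts by seed p-value threshold:\n")
  print(x$by_threshold, row.names = FALSE)
  cat(sprintf("Fold-change split at default threshold: %d increase / %d decrease (%.0f%% increase)\n",
              x$n_increase, x$n_decrease, 100 * x$increase_fraction))
  invisible(x)
}
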