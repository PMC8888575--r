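# Fixed-window tiling of the genome and the window x sample count
# matrix. Windows are consecutive half-open intervals [k*w, (k+1)*w)
# clipped to the chromosome end; each fragment is assigned to exactly
# one window (the one containing its midpoint), so counting conserves
# fragment totals and windows stay statistically independent under the
# NB model. An MEDIPS-style "overlap" mode (a fragment increments every
# window it overlaps) is available but off by default.

#' Tile a genome into fixed windows
#'
#' @param genome a [genome_index()].
#' @param window_size window width in bp (default 1000, minimum 100).
#' @return A `WindowGrid`: window size, per-chromosome window counts
#'   and coordinate lookup.
#' @export
tile_genome <- function(genome, window_size = 1000) {
  stopifnot(inherits(genome, "GenomeIndex"))
  if (!is_count(window_size) || window_size <= 0)
    stop_medip("window_size must be a positive integer")
  if (window_size < 100)
    stop_medip("window_size below 100 bp is not supported")
  n_win <- ceiling(genome$chrom_lengths / window_size)
  structure(
    list(window_size = window_size,
         chrom_names = genome$chrom_names,
         chrom_lengths = genome$chrom_lengths,
         n_windows = n_win,
         offsets = stats::setNames(cumsum(c(0, n_win[-length(n_win)])),
                                   genome$chrom_names)),
    class = "WindowGrid")
}

#' Window coordinates of a grid
#'
#' @param grid a [tile_genome()] grid.
#' @return data.frame(chrom, start, end), 0-based half-open, in grid
#'   order.
#' @export
window_coords <- function(grid) {
  stopifnot(inherits(grid, "WindowGrid"))
  w <- grid$window_size
  chrom <- rep(grid$chrom_names, grid$n_windows)
  k <- unlist(lapply(grid$n_windows, function(n) seq_len(n) - 1),
              use.names = FALSE)
  start <- k * w
  end <- pmin(start + w, rep(grid$chrom_lengths, grid$n_windows))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Construct a window-count container
#'
#' @param windows data.frame(chrom, start, end) of retained windows.
#' @param counts integer matrix, windows x samples.
#' @param samples ordered sample ids (column names).
#' @param library_sizes total counted fragments per sample (defaults
#'   to the column sums; preserved unchanged by [filter_windows()]).
#' @param window_size bp width of the tiling the windows came from.
#' @return A `WindowCounts` object.
#' @export
window_counts <- function(windows, counts, samples,
                          library_sizes = NULL, window_size = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(windows))
    stop_medip("counts rows must match windows")
  if (ncol(counts) != length(samples))
    stop_medip("counts columns must match samples")
  if (any(counts < 0)) stop_medip("negative counts")
  colnames(counts) <- samples
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  names(library_sizes) <- samples
  if (is.null(window_size))
    window_size <- max(windows$end - windows$start, 1)
  structure(
    list(windows = windows, counts = counts, samples = samples,
         library_sizes = library_sizes, window_size = window_size),
    class = "WindowCounts")
}

#' @export
print.WindowCounts <- function(x, ...) {
  cat("WindowCounts:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples;", x$window_size, "bp windows\n")
  invisible(x)
}

#' Count fragments into windows
#'
#' Each fragment is first extended from its 5' end in the strand
#' direction to length `extend_to` (the MeDIP immunoprecipitated
#' fragment length; 0 disables), clipped to the chromosome, then
#' assigned to the single window containing its midpoint (a midpoint
#' exactly on a boundary belongs to the right window, by the half-open
#' convention). `mode = "overlap"` instead increments every window the
#' extended fragment overlaps.
#'
#' @param fragments data.frame from [read_alignments()] (or pooled
#'   over samples); must carry a `sample_id` column.
#' @param grid a [tile_genome()] grid.
#' @param extend_to target fragment length in bp (default 300).
#' @param samples optional explicit sample ordering; defaults to
#'   sorted unique sample ids.
#' @param mode "midpoint" (default) or "overlap".
#' @return A [window_counts()] object covering the full grid.
#' @export
count_fragments <- function(fragments, grid, extend_to = 300,
                            samples = NULL,
                            mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "WindowGrid"))
  bad <- which(!(fragments$chrom %in% grid$chrom_names))
  if (length(bad))
    stop_medip("fragment ", bad[1], " (", fragments$chrom[bad[1]], ":",
               fragments$start[bad[1]], "-", fragments$end[bad[1]],
               ") on a chromosome absent from the window grid")
  if (is.null(samples)) samples <- sort(unique(fragments$sample_id))
  w <- grid$window_size
  n_total <- sum(grid$n_windows)
  clen <- grid$chrom_lengths[fragments$chrom]
  start <- fragments$start
  end <- fragments$end
  if (extend_to > 0) {
    plus <- fragments$strand != "-"
    end[plus] <- pmin(start[plus] + extend_to, clen[plus])
    start[!plus] <- pmax(end[!plus] - extend_to, 0)
  }
  off <- grid$offsets[fragments$chrom]
  nw <- grid$n_windows[fragments$chrom]
  samp <- match(fragments$sample_id, samples)
  counts <- matrix(0L, nrow = n_total, ncol = length(samples))
  if (mode == "midpoint") {
    mid <- (start + end) %/% 2
    win <- pmin(mid %/% w, nw - 1)  # clip: extension may pass chrom end
    idx <- off + win + 1
    tab <- table(factor(idx, levels = seq_len(n_total)),
                 factor(samp, levels = seq_along(samples)))
    counts <- matrix(as.integer(tab), nrow = n_total)
  } else {
    first <- start %/% w
    last <- pmin((end - 1) %/% w, nw - 1)
    reps <- last - first + 1
    idx <- off[rep(seq_along(first), reps)] +
      unlist(lapply(seq_along(first),
                    function(i) first[i]:last[i]), use.names = FALSE) + 1
    samp_rep <- samp[rep(seq_along(first), reps)]
    tab <- table(factor(idx, levels = seq_len(n_total)),
                 factor(samp_rep, levels = seq_along(samples)))
    counts <- matrix(as.integer(tab), nrow = n_total)
  }
  window_counts(window_coords(grid), counts, samples,
                window_size = w)
}

#' Drop windows with too few total counts
#'
#' Windows whose summed count across all samples falls below
#' `min_total` carry no testable signal but inflate the FDR
#' denominator and destabilize dispersion estimation; they are
#' removed before testing. Retained windows keep their genomic
#' coordinates; per-sample library sizes are left unchanged.
#'
#' @param counts a [window_counts()] object.
#' @param min_total minimum summed count (default 10).
#' @return A `WindowCounts` subset.
#' @export
filter_windows <- function(counts, min_total = 10) {
  stopifnot(inherits(counts, "WindowCounts"))
  if (!is_count(min_total)) stop_medip("min_total must be a count >= 0")
  keep <- rowSums(counts$counts) >= min_total
  out <- counts
  out$windows <- counts$windows[keep, , drop = FALSE]
  rownames(out$windows) <- NULL
  out$counts <- counts$counts[keep, , drop = FALSE]
  out
}

#' Read/write a window-count matrix as TSV
#'
#' First three columns are the window coordinates (chrom, start, end;
#' 0-based half-open, matching the internal convention for count
#' matrices); remaining columns are per-sample counts.
#'
#' @param counts a [window_counts()] object.
#' @param path TSV path.
#' @export
write_window_counts <- function(counts, path) {
  df <- cbind(counts$windows,
              as.data.frame(counts$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_counts
#' @export
read_window_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 4)
    stop_medip("count table needs chrom, start, end plus >=1 sample")
  windows <- df[, 1:3]
  names(windows) <- c("chrom", "start", "end")
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(m) <- "integer"
  window_counts(windows, m, colnames(m))
}
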