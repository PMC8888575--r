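# Independent reference implementations used only to check the
# package's optimized code paths. Deliberately naive: direct
# probability products, literal iterated absorption, regex scans.

# Two-sided conditional exact test by direct enumeration: joint
# probabilities of every split s + t = A + B, summed over outcomes no
# more likely than the observed one. Shares the 1e-10 relative tie
# tolerance (the convention for comparing mathematically equal
# probabilities in floating point).
oracle_exact_p <- function(A, B, nA, nB, phi) {
  N <- A + B
  mu <- N / (nA + nB)
  pr <- numeric(N + 1)
  for (s in 0:N) {
    pr[s + 1] <- if (phi > 0) {
      dnbinom(s, size = nA / phi, mu = nA * mu) *
        dnbinom(N - s, size = nB / phi, mu = nB * mu)
    } else {
      dpois(s, nA * mu) * dpois(N - s, nB * mu)
    }
  }
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[A + 1] * (1 + 1e-10)]))
}

# Literal iterated-absorption DMR caller: every seed window starts
# its own region; regions repeatedly absorb any window with
# p < p_edge whose edge-to-edge gap to the region is < edge_reach
# (<= 0 in contiguous mode); overlapping or touching regions merge;
# loop until nothing changes. Returns sorted spans.
oracle_dmr_spans <- function(windows, params) {
  spans <- list()
  for (cn in unique(windows$chrom)) {
    w <- windows[windows$chrom == cn, , drop = FALSE]
    regions <- lapply(which(w$p_value < params$p_sig),
                      function(i) c(w$start[i], w$end[i]))
    if (!length(regions)) next
    qual <- which(w$p_value < params$p_edge)
    repeat {
      changed <- FALSE
      for (ri in seq_along(regions)) {
        r <- regions[[ri]]
        for (j in qual) {
          gap <- max(0, w$start[j] - r[2], r[1] - w$end[j])
          ok <- if (isTRUE(params$contiguous_only)) gap <= 0
            else gap < params$edge_reach
          if (ok && (w$start[j] < r[1] || w$end[j] > r[2])) {
            r <- c(min(r[1], w$start[j]), max(r[2], w$end[j]))
            changed <- TRUE
          }
        }
        regions[[ri]] <- r
      }
      # merge overlapping or touching regions
      m <- do.call(rbind, regions)
      m <- m[order(m[, 1]), , drop = FALSE]
      merged <- list(m[1, ])
      if (nrow(m) > 1) for (i in 2:nrow(m)) {
        last <- merged[[length(merged)]]
        if (m[i, 1] <= last[2]) {
          merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
        } else merged[[length(merged) + 1]] <- m[i, ]
      }
      if (length(merged) < length(regions)) changed <- TRUE
      if (!changed) break
      regions <- merged
    }
    spans[[cn]] <- data.frame(
      chrom = cn,
      start = vapply(regions, `[`, numeric(1), 1),
      end = vapply(regions, `[`, numeric(1), 2))
  }
  if (!length(spans))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  out <- do.call(rbind, spans)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# CpG positions of a sequence by regex scan (0-based)
oracle_cpg_positions <- function(seq) {
  m <- gregexpr("CG", toupper(seq), fixed = TRUE)[[1]]
  if (m[1] == -1) numeric(0) else as.numeric(m) - 1
}
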