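# Synthetic genomes, annotations and MeDIP-style case/control count
# data with planted DMRs. The generator is count-level: the NB
# window-count matrix is the statistical object the differential test
# consumes, so counts are drawn directly as NB(mu, phi) with variance
# mu + phi*mu^2 (edgeR convention). An optional read-level emitter
# places fragments inside windows to exercise the counting module.

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: two-group
#' buccal MeDIP cohorts of 19 preterm cases vs 21 term controls,
#' 1-kb windows, overdispersed counts (phi = 0.1), per-sample library
#' sizes spread over [0.5, 2] of the reference depth, and 20 planted
#' DMRs of 1-3 windows at fold change 3 whose direction alternates so
#' roughly half increase and half decrease methylation.
#'
#' @param seed integer RNG seed; every draw derives from it.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp; must be a multiple of
#'   `window_size` (and of the 100-bp CpG tiling).
#' @param window_size window width in bp.
#' @param n_case,n_control samples per group.
#' @param baseline_mean expected count per window at reference library
#'   size.
#' @param dispersion NB dispersion phi >= 0 (0 = Poisson).
#' @param libsize_spread length-2 multiplicative range of per-sample
#'   library-size factors.
#' @param n_planted number of true DMRs to plant.
#' @param planted_fold_change multiplicative methylation effect (> 0).
#' @param planted_width_windows integer vector of allowed DMR widths
#'   in windows (1-3).
#' @param cpg_island_fraction fraction of the genome with elevated
#'   (island-like) CpG density.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1,
                              n_chroms = 2,
                              chrom_length = 2.5e6,
                              window_size = 1000,
                              n_case = 19,
                              n_control = 21,
                              baseline_mean = 50,
                              dispersion = 0.1,
                              libsize_spread = c(0.5, 2.0),
                              n_planted = 20,
                              planted_fold_change = 3,
                              planted_width_windows = 1:3,
                              cpg_island_fraction = 0.02) {
  if (planted_fold_change <= 0) stop_medip("fold change must be > 0")
  if (dispersion < 0) stop_medip("dispersion must be >= 0")
  if (length(libsize_spread) != 2 || any(libsize_spread <= 0) ||
      libsize_spread[1] > libsize_spread[2])
    stop_medip("libsize_spread must be an increasing positive pair")
  if (!all(planted_width_windows %in% 1:3))
    stop_medip("planted widths must be 1-3 windows")
  structure(as.list(environment()), class = "SimulationConfig")
}

# CpG tiling resolution (bp) used by the sequence generator
.CPG_TILE <- 100L

#' Generate a synthetic genome with controlled CpG density
#'
#' Sequences are built in 100-bp tiles: background tiles carry 1-3
#' CpGs per 100 bp (the CpG-desert regime covering most of a
#' mammalian genome), island tiles carry 8-10 per 100 bp. Island
#' blocks of 1 kb cover `cpg_island_fraction` of each chromosome.
#' Accidental CG dinucleotides are removed before placement, so the
#' planted positions are exactly the genome's CpG sites.
#'
#' @param config a [simulation_config()].
#' @param fasta optional path; when given the genome FASTA is written
#'   there.
#' @return list with `genome` (a [genome_index()]), `sequences`
#'   (DNAStringSet) and `islands` (data.frame of island blocks).
#' @export
generate_genome <- function(config, fasta = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  len <- config$chrom_length
  if (len %% config$window_size != 0)
    stop_medip("chrom_length must be a multiple of window_size")
  if (len %% .CPG_TILE != 0 || config$window_size %% .CPG_TILE != 0)
    stop_medip("lengths must be multiples of the 100-bp CpG tiling")
  with_seed(config$seed, {
    nms <- paste0("chr", seq_len(config$n_chroms))
    seqs <- character(config$n_chroms)
    cpg <- vector("list", config$n_chroms)
    islands <- list()
    n_tiles <- len %/% .CPG_TILE
    tiles_per_block <- 1000L %/% .CPG_TILE
    n_blocks_total <- n_tiles %/% tiles_per_block
    n_island_blocks <- round(config$cpg_island_fraction * n_blocks_total)
    for (ci in seq_len(config$n_chroms)) {
      island_blocks <- if (n_island_blocks > 0)
        sort(sample(n_blocks_total, n_island_blocks)) else integer(0)
      island_tile <- rep(FALSE, n_tiles)
      for (b in island_blocks)
        island_tile[((b - 1) * tiles_per_block + 1):(b * tiles_per_block)] <- TRUE
      k <- ifelse(island_tile,
                  sample(8:10, n_tiles, replace = TRUE),
                  sample(1:3, n_tiles, replace = TRUE))
      # background with every accidental CG destroyed
      base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      base <- gsub("CG", "CA", base, fixed = TRUE)
      raw <- charToRaw(base)
      # place k[t] CGs per tile at even offsets (never overlapping)
      offs <- lapply(seq_len(n_tiles),
                     function(t) sample(seq(0L, 98L, 2L), k[t]))
      pos <- unlist(offs, use.names = FALSE) +
        rep((seq_len(n_tiles) - 1L) * .CPG_TILE, k)
      pos <- sort(pos)
      raw[pos + 1L] <- charToRaw("C")
      raw[pos + 2L] <- charToRaw("G")
      seqs[ci] <- rawToChar(raw)
      cpg[[ci]] <- pos
      if (length(island_blocks))
        islands[[ci]] <- data.frame(
          chrom = nms[ci],
          start = (island_blocks - 1) * 1000,
          end = island_blocks * 1000)
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- nms
    if (!is.null(fasta)) Biostrings::writeXStringSet(dss, fasta)
    list(genome = genome_index(nms, rep(len, config$n_chroms), cpg),
         sequences = dss,
         islands = if (length(islands)) do.call(rbind, islands)
                   else data.frame(chrom = character(0),
                                   start = numeric(0), end = numeric(0)))
  })
}

#' Generate a synthetic gene annotation
#'
#' Genes are placed uniformly and non-overlapping with lengths of
#' 2-20 kb, enough structure to exercise the 10-kb gene-association
#' rule.
#'
#' @param genome a [genome_index()].
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @return gene data.frame as from [read_annotation()].
#' @export
generate_annotation <- function(genome, n_genes, seed = 1) {
  stopifnot(inherits(genome, "GenomeIndex"))
  if (!is_count(n_genes)) stop_medip("n_genes must be a count >= 0")
  if (n_genes == 0)
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    placed <- vector("list", n_genes)
    occupied <- lapply(genome$chrom_names, function(x) NULL)
    names(occupied) <- genome$chrom_names
    tries <- 0
    i <- 1
    while (i <= n_genes) {
      tries <- tries + 1
      if (tries > 200 * n_genes)
        stop_medip("genome too small to place ", n_genes,
                   " non-overlapping genes")
      cn <- sample(genome$chrom_names, 1,
                   prob = genome$chrom_lengths / sum(genome$chrom_lengths))
      glen <- round(stats::runif(1, 2000, 20000))
      if (glen >= genome$chrom_lengths[[cn]]) next
      s <- floor(stats::runif(1, 0, genome$chrom_lengths[[cn]] - glen))
      occ <- occupied[[cn]]
      if (!is.null(occ) &&
          any(pmax(occ[, 1], s) < pmin(occ[, 2], s + glen))) next
      occupied[[cn]] <- rbind(occ, c(s, s + glen))
      placed[[i]] <- data.frame(chrom = cn, start = s, end = s + glen,
                                strand = sample(c("+", "-"), 1),
                                stringsAsFactors = FALSE)
      i <- i + 1
    }
    genes <- do.call(rbind, placed)
    genes <- genes[order(genes$chrom, genes$start), ]
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      gene_name = sprintf("gene%04d", seq_len(n_genes)),
      genes, stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    genes
  })
}

#' Choose window-aligned regions to plant DMRs in
#'
#' Regions are non-overlapping and separated by at least two windows
#' so called DMRs cannot bridge distinct truths; effect direction
#' alternates (odd regions increase, even decrease) giving an about
#' 50/50 split of methylation gains and losses.
#'
#' @param genome a [genome_index()].
#' @param config a [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return `DmrTruthSet` data.frame: chrom, start, end, width_windows,
#'   direction (+1/-1), fold_change (effect actually applied to case
#'   means: `planted_fold_change` or its reciprocal).
#' @export
plant_dmr_regions <- function(genome, config, seed = config$seed) {
  w <- config$window_size
  n <- config$n_planted
  if (n == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), width_windows = integer(0),
                      direction = integer(0), fold_change = numeric(0),
                      stringsAsFactors = FALSE))
  n_win <- floor(genome$chrom_lengths / w)
  if (n * (max(config$planted_width_windows) + 2) > sum(n_win))
    stop_medip("genome too small for ", n, " planted DMRs")
  with_seed(seed, {
    regions <- vector("list", n)
    taken <- lapply(genome$chrom_names, function(x) NULL)
    names(taken) <- genome$chrom_names
    tries <- 0
    i <- 1
    while (i <= n) {
      tries <- tries + 1
      if (tries > 500 * n)
        stop_medip("could not place ", n, " separated DMRs")
      cn <- sample(genome$chrom_names, 1, prob = n_win / sum(n_win))
      width <- if (length(config$planted_width_windows) == 1)
        config$planted_width_windows else
        sample(config$planted_width_windows, 1)
      if (n_win[[cn]] < width) next
      k <- sample.int(n_win[[cn]] - width + 1, 1) - 1  # start window
      occ <- taken[[cn]]
      # enforce >= 2 empty windows between planted regions
      if (!is.null(occ) &&
          any(pmax(occ[, 1] - 2, k) <= pmin(occ[, 2] + 2, k + width - 1)))
        next
      taken[[cn]] <- rbind(occ, c(k, k + width - 1))
      regions[[i]] <- data.frame(chrom = cn, start = k * w,
                                 end = (k + width) * w,
                                 width_windows = width,
                                 stringsAsFactors = FALSE)
      i <- i + 1
    }
    truth <- do.call(rbind, regions)
    truth$direction <- rep_len(c(1L, -1L), n)
    truth$fold_change <- ifelse(truth$direction > 0,
                                config$planted_fold_change,
                                1 / config$planted_fold_change)
    truth <- truth[order(truth$chrom, truth$start), ]
    rownames(truth) <- NULL
    truth
  })
}

#' Simulate a case/control MeDIP window-count dataset
#'
#' Counts for window w and sample s are drawn NB with mean
#' `baseline_mean * libfactor_s * effect(w, s)` and dispersion phi,
#' where the effect is the planted fold change inside planted DMRs
#' for case samples and 1 elsewhere. With phi = 0 the draw is
#' Poisson. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param genome a [genome_index()] tiled at the same window size.
#' @param planted optional truth table (as from [plant_dmr_regions()])
#'   to use instead of random placement, e.g. to share planted DMRs
#'   between cohorts.
#' @param cohort cohort label written into the sample sheet and
#'   sample ids.
#' @return list of class `SimulatedDataset`: `counts` (a
#'   [window_counts()]), `truth` (`DmrTruthSet`), `samples` (sample
#'   sheet data.frame), `lib_factors`.
#' @export
simulate_dataset <- function(config, genome, planted = NULL,
                             cohort = "cohort") {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(genome, "GenomeIndex"))
  grid <- tile_genome(genome, config$window_size)
  wins <- window_coords(grid)
  truth <- if (is.null(planted))
    plant_dmr_regions(genome, config) else planted
  n_case <- config$n_case
  n_control <- config$n_control
  if (n_case < 2 || n_control < 2)
    stop_medip("need >= 2 samples per group")
  ids <- c(sprintf("%s_case_%02d", cohort, seq_len(n_case)),
           sprintf("%s_control_%02d", cohort, seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  with_seed(config$seed + 1L, {
    libf <- stats::runif(n_case + n_control,
                         config$libsize_spread[1], config$libsize_spread[2])
    mu <- outer(rep(config$baseline_mean, nrow(wins)), libf)
    if (nrow(truth)) {
      for (r in seq_len(nrow(truth))) {
        in_dmr <- wins$chrom == truth$chrom[r] &
          wins$start >= truth$start[r] & wins$end <= truth$end[r]
        mu[in_dmr, group == "case"] <-
          mu[in_dmr, group == "case"] * truth$fold_change[r]
      }
    }
    n <- length(mu)
    counts <- if (config$dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    else stats::rpois(n, mu)
    counts <- matrix(as.integer(counts), nrow = nrow(wins))
    wc <- window_counts(wins, counts, ids,
                        window_size = config$window_size)
    sheet <- data.frame(sample_id = ids, group = group, cohort = cohort,
                        path = NA_character_, stringsAsFactors = FALSE)
    structure(list(counts = wc, truth = truth, samples = sheet,
                   lib_factors = stats::setNames(libf, ids)),
              class = "SimulatedDataset")
  })
}

#' Emit read-level fragments matching a count matrix
#'
#' For each window and sample, places exactly that many fragments
#' uniformly inside the window (fragments never straddle a window
#' boundary), so counting with `extend_to = 0` reproduces the matrix
#' exactly. Exercises the counting module and the BED path.
#'
#' @param counts a [window_counts()] object.
#' @param seed RNG seed.
#' @param read_length fragment length in bp (< window size).
#' @return fragment data.frame (chrom, start, end, strand, sample_id).
#' @export
simulate_reads <- function(counts, seed = 1, read_length = 50) {
  stopifnot(inherits(counts, "WindowCounts"))
  if (read_length >= counts$window_size)
    stop_medip("read_length must be below the window size")
  with_seed(seed, {
    per_sample <- lapply(seq_along(counts$samples), function(s) {
      k <- counts$counts[, s]
      tot <- sum(k)
      if (tot == 0) return(NULL)
      wi <- rep(seq_along(k), k)
      lo <- counts$windows$start[wi]
      hi <- counts$windows$end[wi] - read_length
      st <- floor(stats::runif(tot, lo, pmax(lo + 1, hi)))
      data.frame(chrom = counts$windows$chrom[wi],
                 start = st, end = st + read_length,
                 strand = sample(c("+", "-"), tot, replace = TRUE),
                 sample_id = counts$samples[s],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_sample)
    rownames(out) <- NULL
    out
  })
}
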