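small_cfg <- function(...) {
  simulation_config(seed = 5, n_chroms = 2, chrom_length = 1e5,
                    n_case = 4, n_control = 4, n_planted = 4,
                    planted_width_windows = 1, ...)
}

test_that("genome generation is deterministic and shaped correctly", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_equal(length(g1$sequences), 2)
  expect_equal(unname(Biostrings::width(g1$sequences)), rep(1e5, 2))
  expect_error(generate_genome(simulation_config(chrom_length = 1234)),
               "multiple")
})

test_that("generated CpG index matches the written FASTA", {
  cfg <- small_cfg()
  fa <- tempfile(fileext = ".fa")
  g <- generate_genome(cfg, fasta = fa)
  reread <- read_genome_fasta(fa)
  expect_equal(reread$cpg_positions, g$genome$cpg_positions)
  expect_equal(reread$chrom_lengths, g$genome$chrom_lengths)
})

test_that("island fraction 0 gives only desert-density tiles", {
  g <- generate_genome(small_cfg(cpg_island_fraction = 0))
  s <- as.character(g$sequences[[1]])
  pos <- oracle_cpg_positions(s)
  per_tile <- table(pos %/% 100)
  expect_lte(max(per_tile), 3)
})

test_that("island tiles reach island-range density", {
  g <- generate_genome(small_cfg(cpg_island_fraction = 0.2))
  isl <- g$islands[g$islands$chrom == "chr1", ]
  expect_gt(nrow(isl), 0)
  d <- 100 * count_cpgs(g$genome, isl$chrom, isl$start, isl$end) /
    (isl$end - isl$start)
  expect_true(all(d >= 8 & d <= 10))
})

test_that("annotation generation places disjoint genes deterministically", {
  g <- toy_genome_index(1, 1e6)
  expect_equal(nrow(generate_annotation(g, 0)), 0)
  a1 <- generate_annotation(g, 50, seed = 7)
  a2 <- generate_annotation(g, 50, seed = 7)
  expect_identical(a1, a2)
  expect_true(all(a1$end - a1$start >= 2000 & a1$end - a1$start <= 20000))
  # pairwise disjoint on the single chromosome
  o <- order(a1$start)
  expect_true(all(a1$start[o][-1] >= a1$end[o][-50]))
  expect_error(generate_annotation(toy_genome_index(1, 3e4), 50),
               "too small")
})

test_that("planted regions are window-aligned, separated and sign-balanced", {
  g <- toy_genome_index(2, 2e5)
  cfg <- simulation_config(seed = 3, n_chroms = 2, chrom_length = 2e5,
                           n_planted = 12)
  tr <- plant_dmr_regions(g, cfg)
  expect_equal(nrow(tr), 12)
  expect_true(all(tr$start %% 1000 == 0 & tr$end %% 1000 == 0))
  expect_equal(sum(tr$direction > 0), 6)  # even n -> exact 50/50
  for (cn in unique(tr$chrom)) {
    d <- tr[tr$chrom == cn, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1)
      expect_true(all(d$start[-1] - d$end[-nrow(d)] >= 2000))
  }
})

test_that("simulation is deterministic with the expected shape", {
  ds1 <- quick_dataset(seed = 9, n_windows = 100, n_case = 12,
                       n_control = 12)
  ds2 <- quick_dataset(seed = 9, n_windows = 100, n_case = 12,
                       n_control = 12)
  expect_identical(ds1$counts$counts, ds2$counts$counts)
  expect_equal(dim(ds1$counts$counts), c(100, 24))
  expect_equal(nrow(quick_dataset(n_planted = 0)$truth), 0)
})

test_that("Poisson limit columns have the configured means", {
  ds <- quick_dataset(seed = 2, n_windows = 5000, n_case = 3,
                      n_control = 3, phi = 0, baseline = 50)
  mu <- 50 * ds$lib_factors
  z <- abs(colMeans(ds$counts$counts) - mu) / sqrt(mu / 5000)
  # 6 simultaneous checks: Bonferroni-widened normal bound
  expect_lt(max(z), qnorm(1 - 0.005 / 6))
})

test_that("count variance is consistent with mu + phi*mu^2", {
  ds <- quick_dataset(seed = 4, n_windows = 4000, n_case = 6,
                      n_control = 6, phi = 0.2, spread = c(1, 1))
  y <- ds$counts$counts
  phi_emp <- (apply(y, 2, var) - colMeans(y)) / colMeans(y)^2
  expect_true(all(abs(phi_emp - 0.2) < 0.05))
})

test_that("null groups are exchangeable in mean coverage", {
  ds <- quick_dataset(seed = 6, n_windows = 3000, phi = 0.1,
                      spread = c(1, 1))
  grp <- ds$samples$group
  m_case <- mean(ds$counts$counts[, grp == "case"])
  m_ctrl <- mean(ds$counts$counts[, grp == "control"])
  expect_lt(abs(m_case / m_ctrl - 1), 0.01)
})

test_that("read-level emission reproduces the count matrix exactly", {
  ds <- quick_dataset(seed = 8, n_windows = 40, n_case = 2,
                      n_control = 2, baseline = 10)
  frags <- simulate_reads(ds$counts, seed = 1)
  grid <- tile_genome(toy_genome_index(1, 40 * 1000), 1000)
  wc <- count_fragments(frags, grid, extend_to = 0,
                        samples = ds$counts$samples)
  expect_equal(wc$counts, ds$counts$counts, ignore_attr = TRUE)
})
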