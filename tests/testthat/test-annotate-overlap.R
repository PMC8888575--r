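dmr_df <- function(chrom, start, end, name = NULL) {
  n <- length(start)
  data.frame(name = if (is.null(name)) paste0("d", seq_len(n)) else name,
             chrom = chrom, start = start, end = end,
             n_windows = 1L, n_sig_windows = 1L, min_p = 1e-6,
             fdr_q = 1e-4, log2_fold_change = 1, cpg_count = 0L,
             cpg_per_100bp = 0, cpg_desert = TRUE, genes = "",
             stringsAsFactors = FALSE)
}

gene_df <- function(chrom, start, end, id) {
  data.frame(gene_id = id, gene_name = id, chrom = chrom,
             start = start, end = end, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("gene association applies the 10-kb distance rule", {
  d <- dmr_df("c1", 5000, 6000)
  expect_equal(associate_genes(d, gene_df("c1", 15000, 20000, "gA"))$genes,
               "gA")                               # gap 9000
  expect_equal(associate_genes(d, gene_df("c1", 17000, 20000, "gB"))$genes,
               "")                                 # gap 11000
  expect_equal(associate_genes(d, gene_df("c1", 5500, 7000, "gC"))$genes,
               "gC")                               # overlapping, gap 0
  genes <- gene_df("c1", c(5500, 15000, 9000), c(7000, 20000, 9500),
                   c("far", "farther", "near"))
  # sorted by distance then id: overlap(0) < 2000 < 9000
  expect_equal(associate_genes(d, genes)$genes, "far,near,farther")
})

test_that("gene association at distance 0 is pure intersection", {
  d <- dmr_df("c1", c(0, 5000), c(1000, 6000))
  genes <- gene_df("c1", c(999, 1000), c(2000, 2001), c("gA", "gB"))
  out <- associate_genes(d, genes, max_distance = 0)
  expect_equal(out$genes, c("gA", ""))  # book-ended gB does not touch
})

test_that("exact overlap uses half-open intersection semantics", {
  a <- dmr_df("c1", 0, 2000)
  b <- dmr_df("c1", 1500, 2500)
  expect_equal(overlap_exact(a, b)$report$n_shared, 1)
  b2 <- dmr_df("c1", 2000, 3000)  # book-ended
  expect_equal(overlap_exact(a, b2)$report$n_shared, 0)
  b3 <- dmr_df("c2", 0, 2000)     # different chromosome
  expect_equal(overlap_exact(a, b3)$report$n_shared, 0)
})

test_that("intersecting pairs are symmetric between argument orders", {
  set.seed(71)
  a <- dmr_df("c1", sort(sample(seq(0, 5e4, 1000), 10)) , numeric(10))
  a$end <- a$start + 1000
  b <- dmr_df("c1", sort(sample(seq(0, 5e4, 500), 15)), numeric(15))
  b$end <- b$start + 2000
  ab <- overlap_exact(a, b)$shared_pairs
  ba <- overlap_exact(b, a)$shared_pairs
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$idx_a, ab$idx_b),
                  paste(ba$idx_b, ba$idx_a))
})

test_that("extended overlap counts DMRs touching relaxed windows", {
  a <- dmr_df("chr1", 0, 2000)
  wins <- make_results(c(0.5, 0.01, 0.9))
  r <- overlap_extended(a, wins, relaxed_p = 0.05)
  expect_equal(r$report$n_shared, 1)
  wins$p_value <- c(0.5, 0.9, 0.9)
  expect_equal(overlap_extended(a, wins)$report$percent_of_a, 0)
  expect_error(overlap_extended(a, wins, relaxed_p = 1e-5), "exceed")
})

test_that("extended overlap contains the exact overlap on shared signal", {
  g <- toy_genome_index(1, 1.5e6)
  cfg <- simulation_config(seed = 72, n_chroms = 1, chrom_length = 1.5e6,
                           n_case = 10, n_control = 10, n_planted = 8,
                           planted_fold_change = 3)
  shared <- plant_dmr_regions(g, cfg)
  dsA <- simulate_dataset(cfg, g, planted = shared, cohort = "A")
  cfgB <- cfg; cfgB$seed <- 73
  dsB <- simulate_dataset(cfgB, g, planted = shared, cohort = "B")
  resA <- test_windows(filter_windows(dsA$counts, 10), dsA$samples$group)
  resB <- test_windows(filter_windows(dsB$counts, 10), dsB$samples$group)
  dmrsA <- call_dmrs(resA, cohort = "A")
  dmrsB <- call_dmrs(resB, cohort = "B")
  n_exact <- overlap_exact(dmrsA, dmrsB)$report$n_shared
  n_ext <- overlap_extended(dmrsA, resB)$report$n_shared
  expect_gte(n_ext, n_exact)
  expect_gt(n_ext, 0)
})

test_that("venn partition classifies merged components by membership", {
  sets <- list(
    m = dmr_df("c1", c(0, 10000), c(2000, 11000)),
    f = dmr_df("c1", c(1000, 50000), c(3000, 51000)))
  v <- venn_partition(sets)
  expect_equal(v$n_components[v$combination == "f+m"], 1)
  expect_equal(v$n_components[v$combination == "m"], 1)
  expect_equal(v$n_components[v$combination == "f"], 1)
})

test_that("chromosomal clustering groups DMRs by single linkage", {
  d <- dmr_df("c1", c(1.0e6, 1.5e6, 9.0e6), c(1.01e6, 1.51e6, 9.01e6))
  cl <- cluster_summary(d, cluster_gap = 2e6)
  expect_equal(nrow(cl), 1)           # singleton at 9 Mb not reported
  expect_equal(cl$n_dmrs, 2)
  expect_equal(cl$start, 1.0e6)
  expect_equal(nrow(cluster_summary(d[1, ], 2e6)), 0)
  all_in <- cluster_summary(d, cluster_gap = 1e7)
  expect_equal(all_in$n_dmrs, 3)
})
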