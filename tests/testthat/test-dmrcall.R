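test_that("edge extension absorbs a qualifying neighbor window", {
  res <- make_results(c(5e-6, 0.05, 0.5))
  d <- call_dmrs(res)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(0, 2000))
  expect_equal(d$n_windows, 2)
  expect_equal(d$n_sig_windows, 1)
})

test_that("a non-qualifying window blocks bridging between seeds", {
  res <- make_results(c(1e-5, 0.5, 1e-5))
  d <- call_dmrs(res)
  expect_equal(nrow(d), 2)
  expect_equal(d$start, c(0, 2000))
  expect_equal(d$end, c(1000, 3000))
})

test_that("adjacent seeds merge into one multiple-window DMR", {
  res <- make_results(c(1e-5, 1e-6, 0.9), lfc = c(1.1, 1.4, 0))
  d <- call_dmrs(res)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(0, 2000))
  expect_equal(d$n_sig_windows, 2)
  expect_equal(d$min_p, 1e-6)
  expect_equal(d$log2_fold_change, 1.4)  # from the min-p window
})

test_that("extension can bridge a missing window when reach allows", {
  # window [1000,2000) was filtered out; gap to [2000,3000) is 1000
  res <- make_results(c(1e-5, 0.05))
  res$start <- c(0, 2000); res$end <- c(1000, 3000)
  d1 <- call_dmrs(res)  # reach 1000: gap 1000 not < 1000 -> blocked
  expect_equal(c(d1$start, d1$end), c(0, 1000))
  d2 <- call_dmrs(res, dmr_call_params(edge_reach = 1001))
  expect_equal(c(d2$start, d2$end), c(0, 3000))
  expect_equal(d2$n_windows, 2)
  d3 <- call_dmrs(res, dmr_call_params(edge_reach = 1001,
                                       contiguous_only = TRUE))
  expect_equal(c(d3$start, d3$end), c(0, 1000))
})

test_that("threshold is strict: p exactly at p_sig does not seed", {
  res <- make_results(c(1e-4, 0.5))
  expect_equal(nrow(call_dmrs(res)), 0)
})

test_that("caller agrees with the iterated-absorption reference", {
  set.seed(61)
  params_pool <- list(dmr_call_params(),
                      dmr_call_params(edge_reach = 2500),
                      dmr_call_params(p_sig = 1e-3, p_edge = 0.2),
                      dmr_call_params(contiguous_only = TRUE))
  for (i in 1:300) {
    n <- sample(3:50, 1)
    p <- 10^runif(n, -8, 0)
    res <- make_results(p)
    # random gaps: drop some windows to emulate filtering
    keep <- runif(n) > 0.2
    keep[1] <- TRUE
    res <- res[keep, ]
    params <- params_pool[[sample(4, 1)]]
    got <- call_dmrs(res, params)
    want <- oracle_dmr_spans(res, params)
    expect_equal(got[, c("chrom", "start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("DMRs are disjoint and contain every significant window once", {
  set.seed(62)
  for (i in 1:20) {
    p <- 10^runif(60, -8, 0)
    res <- make_results(p)
    d <- call_dmrs(res)
    if (nrow(d) > 1)
      expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    sig <- res[res$p_value < 1e-4, ]
    if (nrow(sig)) {
      hits <- vapply(seq_len(nrow(sig)), function(j)
        sum(sig$start[j] < d$end & sig$end[j] > d$start), integer(1))
      expect_true(all(hits == 1))
    }
    expect_true(all(d$n_sig_windows >= 1))
    expect_true(all(d$min_p < 1e-4))
  }
})

test_that("relaxing the seed threshold only grows the DMR set", {
  set.seed(63)
  p <- 10^runif(80, -7, 0)
  res <- make_results(p)
  d_strict <- call_dmrs(res, dmr_call_params(p_sig = 1e-5))
  d_loose <- call_dmrs(res, dmr_call_params(p_sig = 1e-3))
  expect_gte(nrow(d_loose), nrow(d_strict))
  for (i in seq_len(nrow(d_strict))) {
    inside <- any(d_loose$start <= d_strict$start[i] &
                    d_loose$end >= d_strict$end[i])
    expect_true(inside)
  }
})

test_that("unsorted or overlapping windows are rejected", {
  res <- make_results(c(1e-5, 0.5))
  expect_error(call_dmrs(res[c(2, 1), ]), "sorted")
  res2 <- res
  res2$start <- c(0, 500)  # overlaps window 1
  expect_error(call_dmrs(res2), "overlap")
})

test_that("CpG density and desert classification follow the definitions", {
  # 1000-bp DMR with 20 CpGs -> 2.0/100bp desert; 2000-bp with 180 -> 9.0
  cpg <- c(seq(0, 950, 50),                    # 20 in [0,1000)
           seq(2000, 3990, length.out = 180))  # 180 in [2000,4000)
  g <- genome_index("chr1", 10000, list(chr1 = cpg))
  dmrs <- data.frame(chrom = "chr1", start = c(0, 2000, 5000),
                     end = c(1000, 4000, 6000))
  d <- dmr_cpg_density(dmrs, g)
  expect_equal(d$cpg_count, c(20, 180, 0))
  expect_equal(d$cpg_per_100bp, c(2, 9, 0))
  expect_equal(d$cpg_desert, c(TRUE, FALSE, TRUE))
})

test_that("threshold summary is monotone and reports the sign split", {
  set.seed(64)
  ds <- quick_dataset(seed = 64, n_windows = 1500, n_case = 8,
                      n_control = 8, phi = 0.1, fold = 3,
                      n_planted = 8)
  fl <- filter_windows(ds$counts, 10)
  res <- test_windows(fl, ds$samples$group)
  s <- summarize_dmrs(res, thresholds = c(1e-2, 1e-3, 1e-4, 1e-5))
  tab <- s$by_threshold
  expect_true(all(diff(tab$n_all[order(tab$threshold)]) >= 0))
  expect_true(all(tab$n_multiple <= tab$n_all))
  expect_equal(s$n_increase + s$n_decrease,
               tab$n_all[tab$threshold == 1e-4])
  expect_gt(s$increase_fraction, 0.2)
  expect_lt(s$increase_fraction, 0.8)
})
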