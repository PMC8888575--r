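# strongly separated two-group dataset with DMR-restricted features
strong_features <- function(seed = 81, fold = 4, n_per_group = 10) {
  ds <- quick_dataset(seed = seed, n_windows = 800,
                      n_case = n_per_group, n_control = n_per_group,
                      phi = 0.1, fold = fold, n_planted = 6,
                      width = 1:2)
  fl <- filter_windows(ds$counts, 10)
  norm <- tmm_factors(fl)
  res <- test_windows(fl, ds$samples$group, norm = norm)
  dmrs <- call_dmrs(res)
  list(features = dmr_feature_matrix(fl, norm, dmrs),
       groups = ds$samples$group, dmrs = dmrs, counts = fl,
       norm = norm)
}

test_that("feature matrix covers exactly the DMR windows as log2 CPM", {
  s <- strong_features()
  n_dmr_windows <- sum(vapply(seq_len(nrow(s$dmrs)), function(i)
    sum(s$counts$windows$chrom == s$dmrs$chrom[i] &
          s$counts$windows$start < s$dmrs$end[i] &
          s$counts$windows$end > s$dmrs$start[i]), integer(1)))
  expect_equal(ncol(s$features$x), n_dmr_windows)
  expect_equal(nrow(s$features$x), 20)
  expect_error(dmr_feature_matrix(s$counts, s$norm, s$dmrs[0, ]),
               "empty DMR")
})

test_that("features are invariant to doubling counts and library size", {
  ds <- quick_dataset(seed = 82, n_windows = 100, n_case = 3,
                      n_control = 3, baseline = 30)
  wc <- ds$counts
  wc2 <- wc
  wc2$counts[, 1] <- wc$counts[, 1] * 2L
  wc2$library_sizes[1] <- wc$library_sizes[1] * 2
  dmrs <- data.frame(chrom = "chr1", start = 0, end = 5000)
  norm1 <- list(effective_lib_sizes = wc$library_sizes)
  norm2 <- list(effective_lib_sizes = wc2$library_sizes)
  f1 <- dmr_feature_matrix(wc, norm1, dmrs)
  f2 <- dmr_feature_matrix(wc2, norm2, dmrs)
  expect_equal(f1$x[1, ], f2$x[1, ])
  expect_equal(ncol(f1$x), 5)
  # zero count -> log2(0 + 1) = 0
  wc$counts[2, 1] <- 0L
  f0 <- dmr_feature_matrix(wc, norm1, dmrs)
  expect_equal(unname(f0$x[1, 2]), 0)
})

test_that("PCA satisfies its invariants and separates planted groups", {
  s <- strong_features()
  pca <- feature_pca(s$features)
  expect_lte(sum(pca$explained), 1 + 1e-9)
  # PC1 separates case from control with no range overlap
  pc1 <- pca$scores[, 1]
  grp <- s$groups
  expect_true(max(range(pc1[grp == "case"])) < min(pc1[grp == "control"]) ||
                max(pc1[grp == "control"]) < min(pc1[grp == "case"]))
  # duplicated sample rows get identical scores
  x2 <- rbind(s$features$x, s$features$x[1, , drop = FALSE])
  p2 <- feature_pca(x2, 3)
  expect_equal(unname(p2$scores[21, ]), unname(p2$scores[1, ]))
  expect_error(feature_pca(s$features$x, 50), "exceeds")
})

test_that("PCA scores are invariant to sample order up to the sign fix", {
  s <- strong_features()
  perm <- sample(nrow(s$features$x))
  p1 <- feature_pca(s$features$x, 3)
  p2 <- feature_pca(s$features$x[perm, ], 3)
  expect_equal(p2$scores, p1$scores[perm, ], tolerance = 1e-8)
})

test_that("dendrogram merges identical samples first and keeps all leaves", {
  x <- matrix(c(0, 0, 0, 0, 5, 5), byrow = TRUE, ncol = 2,
              dimnames = list(c("a", "b", "c"), NULL))
  tree <- feature_dendrogram(x)
  expect_equal(sort(tree$labels), c("a", "b", "c"))
  expect_equal(tree$height[1], 0)  # identical pair merges at height 0
  x2 <- matrix(c(0, 0, 3, 4), byrow = TRUE, ncol = 2,
               dimnames = list(c("a", "b"), NULL))
  t2 <- feature_dendrogram(x2)
  expect_equal(t2$height, 5)       # single merge at their distance
  nwk <- dendrogram_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
})

test_that("LDA separates a strong planted signal and validates input", {
  s <- strong_features()
  r <- lda_train_predict(s$features, s$groups)
  expect_gte(r$loo_accuracy, 0.9)
  # a test sample identical to a training case sample is called case
  i_case <- which(s$groups == "case")[1]
  pred <- lda_train_predict(s$features, s$groups,
                            test = s$features$x[i_case, , drop = FALSE],
                            loo = FALSE)$predictions
  expect_equal(unname(pred), "case")
  expect_error(lda_train_predict(s$features, rep("case", 20)),
               "two classes")
  expect_error(
    lda_train_predict(s$features, s$groups,
                      test = s$features$x[, 1:3, drop = FALSE]),
    "columns")
})

test_that("LDA predictions are invariant to a global affine feature map", {
  s <- strong_features()
  x <- s$features$x
  xt <- x[1:4, , drop = FALSE]
  p1 <- lda_train_predict(x, s$groups, test = xt, loo = FALSE)$predictions
  p2 <- lda_train_predict(3.7 * x + 11, s$groups, test = 3.7 * xt + 11,
                          loo = FALSE)$predictions
  expect_equal(p1, p2)
})
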