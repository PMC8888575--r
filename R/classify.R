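# Biomarker evaluation on DMR-restricted features: log-CPM feature
# matrix over DMR windows, PCA, average-linkage dendrogram, and a
# PCA-reduced shrinkage LDA with leave-one-out accuracy. With tens of
# samples and up to hundreds of windows (n << p), LDA needs both the
# PCA reduction (rank k = min(n - 2, 10)) and diagonal shrinkage of
# the pooled covariance to stay well-posed.

#' DMR-restricted feature matrix
#'
#' Rows are samples, columns the windows intersecting any DMR;
#' values are log2(CPM + 1) computed with TMM effective library
#' sizes, so a sample whose counts and library size double is
#' unchanged.
#'
#' @param counts a [window_counts()] object.
#' @param norm a [tmm_factors()] result for the same samples.
#' @param dmrs DMR data.frame (must be nonempty).
#' @return list of class `FeatureMatrix`: `x` (samples x windows),
#'   `windows` (column metadata), `samples`.
#' @export
dmr_feature_matrix <- function(counts, norm, dmrs) {
  stopifnot(inherits(counts, "WindowCounts"))
  if (!nrow(dmrs)) stop_medip("empty DMR set: no features to build")
  lv <- .shared_levels(counts$windows, dmrs)
  gr_w <- .as_granges(counts$windows, lv)
  gr_d <- .as_granges(dmrs, lv)
  keep <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gr_w, gr_d)))
  keep <- sort(keep)
  if (!length(keep)) stop_medip("no windows intersect the DMR set")
  eff <- norm$effective_lib_sizes[counts$samples]
  cpm <- sweep(counts$counts[keep, , drop = FALSE], 2, 1e6 / eff, "*")
  x <- t(log2(cpm + 1))
  colnames(x) <- paste0(counts$windows$chrom[keep], ":",
                        counts$windows$start[keep])
  structure(list(x = x, windows = counts$windows[keep, , drop = FALSE],
                 samples = counts$samples),
            class = "FeatureMatrix")
}

#' @noRd
.feature_x <- function(features) {
  if (inherits(features, "FeatureMatrix")) features$x
  else as.matrix(features)
}

#' PCA of a feature matrix
#'
#' Columns are centered, scores come from the singular value
#' decomposition, and each component's sign is fixed so its
#' largest-magnitude loading is positive (determinism under sample
#' reordering).
#'
#' @param features a [dmr_feature_matrix()] or plain matrix
#'   (samples x features).
#' @param n_components number of components (default
#'   `min(n - 1, p)`).
#' @return list of class `FeaturePca`: `scores` (n x k), `loadings`
#'   (p x k), `explained` (variance fractions of the k components),
#'   `center`.
#' @export
feature_pca <- function(features, n_components = NULL) {
  x <- .feature_x(features)
  n <- nrow(x)
  if (n < 2) stop_medip("PCA needs >= 2 samples")
  kmax <- min(n - 1, ncol(x))
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax)
    stop_medip("n_components exceeds min(samples - 1, features) = ", kmax)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, loadings = loadings,
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
                 center = ctr),
            class = "FeaturePca")
}

#' Average-linkage dendrogram of samples
#'
#' Euclidean distances on column-centered features, average-linkage
#' agglomeration (hclust), deterministic.
#'
#' @param features a [dmr_feature_matrix()] or matrix.
#' @return An [stats::hclust] tree over the samples.
#' @export
feature_dendrogram <- function(features) {
  x <- .feature_x(features)
  if (nrow(x) < 2) stop_medip("dendrogram needs >= 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  stats::hclust(stats::dist(xc), method = "average")
}

#' Export a dendrogram as Newick text
#'
#' @param tree an [stats::hclust] tree.
#' @param path optional output path; when NULL the Newick string is
#'   returned.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' @noRd
.lda_fit <- function(x, labels, n_components, shrinkage) {
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop_medip("LDA training needs exactly two classes, got ",
               length(classes))
  n <- nrow(x)
  k <- if (is.null(n_components)) max(1, min(n - 2, 10)) else n_components
  pca <- feature_pca(x, min(k, n - 1, ncol(x)))
  z <- pca$scores
  mu <- rbind(colMeans(z[labels == classes[1], , drop = FALSE]),
              colMeans(z[labels == classes[2], , drop = FALSE]))
  rownames(mu) <- classes
  centered <- z - mu[match(labels, classes), , drop = FALSE]
  s <- crossprod(centered) / max(1, n - 2)
  s_shrunk <- (1 - shrinkage) * s +
    shrinkage * mean(diag(s)) * diag(ncol(z))
  list(pca = pca, classes = classes, means = mu,
       cov_inv = solve(s_shrunk), shrinkage = shrinkage)
}

#' @noRd
.lda_predict <- function(model, x) {
  z <- sweep(x, 2, model$pca$center) %*% model$pca$loadings
  # linear discriminant score per class (equal priors)
  sc <- vapply(1:2, function(g) {
    m <- model$means[g, ]
    drop(z %*% model$cov_inv %*% m) - 0.5 * drop(m %*% model$cov_inv %*% m)
  }, numeric(nrow(z)))
  sc <- matrix(sc, ncol = 2)
  model$classes[max.col(sc, ties.method = "first")]
}

#' Train a shrinkage LDA on DMR features and classify test samples
#'
#' The model reduces features to the top principal components
#' (k = min(n - 2, 10) by default), fits class means and a pooled
#' within-class covariance with diagonal shrinkage
#' `(1 - lambda) * S + lambda * mean(diag(S)) * I`, and assigns the
#' class with the larger linear discriminant score (equal priors).
#' Leave-one-out training accuracy refits the whole model (PCA
#' included) with each training sample held out.
#'
#' @param train a [dmr_feature_matrix()] or matrix of training
#'   samples.
#' @param labels class labels (two classes, both present).
#' @param test optional matrix/FeatureMatrix of samples to classify;
#'   columns must match the training columns.
#' @param n_components PCA rank (default min(n - 2, 10)).
#' @param shrinkage shrinkage intensity lambda in [0, 1] (default
#'   0.1).
#' @param loo compute leave-one-out accuracy (default TRUE).
#' @return list of class `LdaResult`: `predictions` (for `test`),
#'   `loo_accuracy`, `loo_predictions`, `model`.
#' @export
lda_train_predict <- function(train, labels, test = NULL,
                              n_components = NULL, shrinkage = 0.1,
                              loo = TRUE) {
  x <- .feature_x(train)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop_medip("labels must parallel training samples")
  if (shrinkage < 0 || shrinkage > 1)
    stop_medip("shrinkage must be in [0, 1]")
  model <- .lda_fit(x, labels, n_components, shrinkage)
  predictions <- NULL
  if (!is.null(test)) {
    xt <- .feature_x(test)
    if (ncol(xt) != ncol(x))
      stop_medip("test feature columns do not match training columns")
    predictions <- stats::setNames(.lda_predict(model, xt),
                                   rownames(xt))
  }
  loo_accuracy <- NA_real_
  loo_pred <- NULL
  if (loo) {
    loo_pred <- character(nrow(x))
    for (i in seq_len(nrow(x))) {
      if (length(unique(labels[-i])) < 2) {
        loo_pred[i] <- NA_character_
        next
      }
      m <- .lda_fit(x[-i, , drop = FALSE], labels[-i],
                    n_components, shrinkage)
      loo_pred[i] <- .lda_predict(m, x[i, , drop = FALSE])
    }
    loo_accuracy <- mean(loo_pred == labels, na.rm = TRUE)
  }
  structure(list(predictions = predictions,
                 loo_accuracy = loo_accuracy,
                 loo_predictions = loo_pred,
                 model = model),
            class = "LdaResult")
}
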