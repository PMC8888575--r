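# Per-window differential-coverage statistics.
#
# The two-group comparison follows the classic count-based recipe:
# TMM effective library sizes, counts rescaled to a common library
# size, a common NB dispersion estimated by conditional maximum
# likelihood, and a two-sided conditional exact test per window.
# Under the null the group totals A (nA samples) and B (nB samples)
# are NB with means nA*mu and nB*mu and dispersions phi/nA, phi/nB;
# conditioning on N = A + B, the two-sided p-value sums the
# probabilities of all splits no more likely than the observed one
# (minimum-likelihood convention, so a perfectly balanced split gives
# p = 1). phi = 0 is handled as the Poisson limit, where the
# conditional law is Binomial(N, nA/(nA+nB)).

#' TMM normalization factors
#'
#' Trimmed mean of M-values between each sample and a reference
#' sample (the one whose 75th-percentile count fraction is closest to
#' the mean of those fractions). M-values are trimmed 30% from each
#' tail and A-values 5%, the surviving M-values are combined with
#' inverse-asymptotic-variance weights, and the factors are rescaled
#' to geometric mean 1.
#'
#' @param counts a [window_counts()] object.
#' @return list of class `NormalizationFactors`: `factors` (named,
#'   geometric mean 1), `effective_lib_sizes` (raw library size x
#'   factor), `ref_sample`.
#' @export
tmm_factors <- function(counts) {
  stopifnot(inherits(counts, "WindowCounts"))
  y <- counts$counts
  lib <- counts$library_sizes
  if (ncol(y) < 2) stop_medip("TMM needs >= 2 samples")
  zero <- which(colSums(y) == 0)
  if (length(zero))
    stop_medip("sample '", counts$samples[zero[1]],
               "' has all-zero counts")
  if (any(lib <= 0)) stop_medip("library sizes must be positive")
  p75 <- apply(y, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(p75 - mean(p75)))
  f <- vapply(seq_len(ncol(y)), function(s) {
    .tmm_pair(y[, s], y[, ref], lib[s], lib[ref])
  }, numeric(1))
  f <- f / geometric_mean(f)
  structure(
    list(factors = stats::setNames(f, counts$samples),
         effective_lib_sizes = stats::setNames(lib * f, counts$samples),
         ref_sample = counts$samples[ref]),
    class = "NormalizationFactors")
}

# one sample vs reference; returns 2^(weighted trimmed mean of M)
#' @noRd
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      trim_m = 0.3, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  po <- obs / lib_obs
  pr <- ref / lib_ref
  m <- log2(po / pr)
  a <- 0.5 * log2(po * pr)
  if (max(abs(m)) < 1e-6) return(1)  # identical proportions
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m, ties.method = "first") >= lo_m &
    rank(m, ties.method = "first") <= hi_m &
    rank(a, ties.method = "first") >= lo_a &
    rank(a, ties.method = "first") <= hi_a
  if (!any(keep2)) return(1)
  # asymptotic variance of M (delta method, binomial sampling)
  w <- 1 / ((lib_obs - obs) / (lib_obs * obs) +
              (lib_ref - ref) / (lib_ref * ref))[keep2]
  2^(sum(w * m[keep2]) / sum(w))
}

#' Rescale counts to a common effective library size
#'
#' Counts are scaled to the geometric mean of the effective library
#' sizes and rounded half-to-even, after which all samples are
#' directly comparable and the conditional exact test applies.
#'
#' @param counts a [window_counts()] object.
#' @param norm a [tmm_factors()] result (defaults to computing it).
#' @return list: `counts` (integer matrix), `common_lib_size`.
#' @export
equalize_lib_sizes <- function(counts, norm = tmm_factors(counts)) {
  eff <- norm$effective_lib_sizes[counts$samples]
  common <- geometric_mean(eff)
  y <- sweep(counts$counts, 2, common / eff, "*")
  y <- matrix(as.integer(round(y)), nrow = nrow(y),
              dimnames = dimnames(counts$counts))
  list(counts = y, common_lib_size = common)
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' On counts equalized to a common library size, the conditional
#' log-likelihood of phi given each group's total is summed over
#' windows and both groups and maximized by bounded one-dimensional
#' search over phi in [1e-6, 10]. Deterministic.
#'
#' @param counts a [window_counts()] object (typically filtered).
#' @param groups character vector ("case"/"control" or any two
#'   labels) parallel to the samples.
#' @param norm a [tmm_factors()] result.
#' @return list of class `DispersionEstimate`: `phi`,
#'   `n_windows_used`.
#' @export
estimate_dispersion <- function(counts, groups,
                                norm = tmm_factors(counts)) {
  stopifnot(inherits(counts, "WindowCounts"))
  groups <- as.character(groups)
  if (length(groups) != length(counts$samples))
    stop_medip("groups must parallel samples")
  tab <- table(groups)
  if (length(tab) != 2 || any(tab < 2))
    stop_medip("need exactly two groups with >= 2 samples each ",
               "(conditional likelihood undefined otherwise)")
  y <- equalize_lib_sizes(counts, norm)$counts
  glab <- names(tab)
  y1 <- y[, groups == glab[1], drop = FALSE]
  y2 <- y[, groups == glab[2], drop = FALSE]
  nll <- function(phi) {
    -(.cond_loglik_group(y1, phi) + .cond_loglik_group(y2, phi))
  }
  opt <- stats::optimize(nll, interval = c(1e-6, 10), tol = 1e-6)
  structure(list(phi = opt$minimum, n_windows_used = nrow(y)),
            class = "DispersionEstimate")
}

# conditional (on the row total) NB log-likelihood for one group,
# summed over windows; r = 1/phi per sample
#' @noRd
.cond_loglik_group <- function(y, phi) {
  n <- ncol(y)
  r <- 1 / phi
  z <- rowSums(y)
  sum(lgamma(y + r)) + nrow(y) * lgamma(n * r) -
    sum(lgamma(z + n * r)) - nrow(y) * n * lgamma(r)
}

# conditional pmf (log) of split s (case total) given N = A+B
#' @noRd
.cond_logpmf <- function(s, N, nA, nB, phi) {
  mu <- N / (nA + nB)  # per-sample mean under the null
  if (phi > 0) {
    stats::dnbinom(s, size = nA / phi, mu = nA * mu, log = TRUE) +
      stats::dnbinom(N - s, size = nB / phi, mu = nB * mu, log = TRUE)
  } else {
    stats::dpois(s, nA * mu, log = TRUE) +
      stats::dpois(N - s, nB * mu, log = TRUE)
  }
}

# relative tie tolerance when comparing outcome probabilities:
# mathematically equal probabilities (e.g. symmetric splits) must not
# be separated by floating-point noise
.TIE_EPS <- 1e-10

#' Two-sided conditional NB exact test for one window
#'
#' Counts must already be equalized to a common library size (see
#' [equalize_lib_sizes()]). The log2 fold change is
#' log2((mean case + c) / (mean control + c)) with prior count
#' c = `prior_count`, positive for increased methylation in cases.
#'
#' @param counts_case,counts_control integer count vectors for one
#'   window.
#' @param phi common NB dispersion (>= 0; 0 = Poisson limit).
#' @param prior_count prior added to each group mean for the fold
#'   change (default 0.5).
#' @return list: `p_value`, `log2_fold_change`.
#' @export
exact_test <- function(counts_case, counts_control, phi,
                       prior_count = 0.5) {
  if (any(counts_case < 0) || any(counts_control < 0))
    stop_medip("negative counts")
  if (phi < 0) stop_medip("phi must be >= 0")
  A <- sum(counts_case)
  B <- sum(counts_control)
  lfc <- log2((mean(counts_case) + prior_count) /
                (mean(counts_control) + prior_count))
  if (A + B == 0) return(list(p_value = 1, log2_fold_change = 0))
  p <- .exact_test_p(A, B, length(counts_case), length(counts_control),
                     phi)
  list(p_value = p, log2_fold_change = lfc)
}

#' @noRd
.exact_test_p <- function(A, B, nA, nB, phi) {
  N <- A + B
  lp <- .cond_logpmf(0:N, N, nA, nB, phi)
  lse <- logsumexp(lp)
  pr <- exp(lp - lse)
  obs <- pr[A + 1]
  min(1, sum(pr[pr <= obs * (1 + .TIE_EPS)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Validates that all p-values lie in (0, 1] and applies the BH
#' step-up procedure (via [stats::p.adjust()]); input order is
#' preserved.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop_medip("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-window differential methylation test
#'
#' Runs the full per-window stage: TMM normalization, library-size
#' equalization, common-dispersion estimation (unless `phi` is
#' given), the conditional exact test per window, and BH FDR.
#'
#' @param counts a [window_counts()] object (typically filtered with
#'   [filter_windows()]).
#' @param groups "case"/"control" labels parallel to samples.
#' @param norm optional [tmm_factors()] result.
#' @param phi optional dispersion override; default estimates it.
#' @param prior_count prior count for fold changes.
#' @return data.frame of class `window_test`: chrom, start, end,
#'   p_value, log2_fold_change, fdr_q, plus attributes `phi` and
#'   `norm`.
#' @export
test_windows <- function(counts, groups, norm = NULL, phi = NULL,
                         prior_count = 0.5) {
  stopifnot(inherits(counts, "WindowCounts"))
  groups <- as.character(groups)
  if (!all(groups %in% c("case", "control")))
    stop_medip("groups must be 'case' or 'control'")
  if (is.null(norm)) norm <- tmm_factors(counts)
  if (is.null(phi))
    phi <- estimate_dispersion(counts, groups, norm)$phi
  y <- equalize_lib_sizes(counts, norm)$counts
  case <- groups == "case"
  nA <- sum(case)
  nB <- sum(!case)
  A <- rowSums(y[, case, drop = FALSE])
  B <- rowSums(y[, !case, drop = FALSE])
  pv <- numeric(nrow(y))
  for (i in seq_len(nrow(y))) {
    pv[i] <- if (A[i] + B[i] == 0) 1 else
      .exact_test_p(A[i], B[i], nA, nB, phi)
  }
  lfc <- log2((A / nA + prior_count) / (B / nB + prior_count))
  lfc[A + B == 0] <- 0
  res <- data.frame(counts$windows,
                    p_value = pv,
                    log2_fold_change = lfc,
                    fdr_q = bh_fdr(pv),
                    stringsAsFactors = FALSE)
  attr(res, "phi") <- phi
  attr(res, "norm") <- norm
  class(res) <- c("window_test", "data.frame")
  res
}
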