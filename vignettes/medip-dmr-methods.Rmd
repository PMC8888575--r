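---
title: "Windowed differential methylation analysis with medipdmr: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed differential methylation analysis with medipdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

# The analysis problem

MeDIP-Seq enriches methylated DNA fragments by immunoprecipitation
and sequences them, so local read density proxies methylation level
across >90% of the genome — including the low-CpG-density regions
("CpG deserts", here < 3 CpG/100 bp) that array platforms barely
cover. Given two groups of samples (cases and controls, e.g. preterm
versus term birth within a cohort of mothers, fathers, or children),
the pipeline asks where coverage differs systematically, merges the
evidence into differential methylation regions (DMRs), characterizes
and compares them across cohorts, and evaluates the DMR set as a
classification biomarker.

This vignette documents the statistical model, every tunable
parameter with its default and rationale, the synthetic-data
generator used for validation, numerical choices, and known
limitations.

# Counting model

The genome is tiled into consecutive half-open windows of
`window_size` (default **1000 bp**); the last window of a chromosome
may be short. Each aligned fragment is extended from its 5' end in
the strand direction to `extend_to` (default **300 bp**, the
sonication fragment size that the 50-bp reads proxy) and assigned to
the single window containing its midpoint, with a boundary midpoint
belonging to the right window by the half-open convention. Midpoint
assignment conserves the fragment total exactly and keeps windows
statistically independent under the count model; an `overlap` mode
(each fragment increments every window it touches) is available for
compatibility with enrichment-style pipelines, but it double-counts
boundary-spanning fragments and is off by default.

Windows whose summed count across all samples is below `min_total`
(default **10**) are removed before testing: they cannot reach
significance but would destabilize dispersion estimation and inflate
the FDR denominator. Internally all coordinates are 0-based
half-open; written DMR tables use 1-based inclusive start/stop for
display, and write-then-read restores the internal values exactly.

Duplicate-read removal is not performed by default (a
`min_mapq` filter is available on SAM/BAM input but defaults to 0,
trusting the aligner); both choices are exposed rather than imposed
because the appropriate setting depends on library complexity.

# Per-window test

Counts are modeled as negative binomial with variance
$\mu + \phi\mu^2$. Three steps precede the test:

1. **TMM normalization** (`tmm_factors`). The reference sample is
   the one whose 75th-percentile count fraction is closest to the
   mean of those fractions. For each sample, M-values (log2 ratios
   of library-size-normalized counts against the reference) are
   trimmed 30% from each tail and A-values 5%, and the surviving
   M-values are averaged with inverse-asymptotic-variance weights;
   factors are rescaled to geometric mean 1. The unit tests
   cross-check the factors against edgeR's TMM on simulated data
   (agreement within 0.5%).
2. **Library-size equalization** (`equalize_lib_sizes`). Counts are
   scaled to the geometric mean of the effective library sizes and
   rounded half-to-even. This is a deliberate simplification of
   quantile-based adjustment: it preserves the conditional-test
   logic with far less machinery, and all validation here is via
   simulation properties rather than numerical equality with any
   specific external implementation.
3. **Common dispersion** (`estimate_dispersion`). $\phi$ maximizes
   the conditional (on each group's window total) NB log-likelihood
   summed over windows and both groups, by bounded one-dimensional
   search over $\phi \in [10^{-6}, 10]$ (`stats::optimize`,
   tolerance $10^{-6}$). A common dispersion is appropriate because
   the comparison is strictly two-group; tagwise or trended
   dispersion is out of scope.

The **conditional exact test** then evaluates each window: with case
total $A$ over $n_A$ samples and control total $B$ over $n_B$, under
the null $A \sim \mathrm{NB}(n_A\hat\mu, \phi/n_A)$ and
$B \sim \mathrm{NB}(n_B\hat\mu, \phi/n_B)$ with
$\hat\mu = (A+B)/(n_A+n_B)$. Conditioning on $N = A + B$, the
two-sided p-value is the total conditional probability of all splits
$s + t = N$ with $P(s,t) \le P(A,B)$ — the minimum-likelihood
convention, which avoids tail-doubling and makes a perfectly
balanced split give $p = 1$ exactly. $\phi = 0$ is handled as the
Poisson limit, where the conditional law is
$\mathrm{Binomial}(N, n_A/(n_A+n_B))$ and the test coincides with
the exact conditional binomial test. Probabilities are computed in
log space and outcomes within a relative $10^{-10}$ of the observed
probability are counted as ties, so mathematically equal symmetric
outcomes are never split by floating-point noise.

The per-DMR log2 fold change is
$\log_2\{(\bar y_{case} + c)/(\bar y_{ctrl} + c)\}$ on equalized
counts with prior count $c = 0.5$ (configurable), keeping fold
changes finite at zero counts. FDR control is Benjamini–Hochberg
(`bh_fdr`, a validated wrapper over `stats::p.adjust`).

# DMR calling

Windows with $p < 10^{-4}$ (strict inequality; `p_sig`) seed DMRs.
Edges extend until no window with $p < 0.1$ (`p_edge`) remains
within `edge_reach` = **1000 bp** of the DMR span. "Within 1000 bp"
is read strictly: a window qualifies when at least one of its bases
lies among the 1000 bp flanking the current span, i.e. its
edge-to-edge gap is **less than** the reach. Under this reading a
single non-qualifying 1000-bp window blocks extension past it at the
default reach — consistent with the behavior that two seeds
separated by one dead window form two DMRs — while a filtered-out
(missing) window can be bridged when the reach exceeds the gap. A
`contiguous_only` mode restricts absorption to gap-0 neighbors for
users who prefer never to bridge.

Because the span only grows by absorbing qualifying windows, the
iterated absorption has a closed form: single-linkage chains of
$p < p_\mathrm{edge}$ windows with consecutive gap below the reach,
keeping chains that contain a seed. The implementation uses the
closed form; the test suite verifies it against a literal
iterated-absorption reference on 1000 random window vectors, and
checks the monotonicity (relaxing `p_sig` never loses a DMR) and
partition (every significant window in exactly one DMR) properties.

Each DMR reports total and significant window counts, the minimum
window p-value and its BH q, a log2 fold change taken from the
minimum-p window (the mean over significant windows is available via
`logfc_from = "mean_sig"`; one number per DMR must be chosen and the
extreme window is the one that seeded the call), CpG count and
density per 100 bp from the reference sequence (desert flag below
3 CpG/100 bp), and genes within 10 kb (`max_distance`), covering
proximal and distal promoters. DMR names are
`cohort:chromosome:ordinal`. At `max_distance = 0` gene association
reduces to pure interval intersection; book-ended intervals share no
base and do not associate at that setting.

Cross-cohort comparison is by genomic intersection, not window
identity, since edge extension shifts boundaries between cohorts:
**exact** overlap intersects DMR sets; **extended** overlap
intersects one cohort's DMRs with the other cohort's $p < 0.05$
(`relaxed_p`) windows, asking whether sub-threshold signal exists at
the same loci. Percentages are normalized by the first (row) cohort,
which is why the two directions of a pair can differ. Chromosomal
clusters are single-linkage groups with inter-DMR gap at most
`cluster_gap` (default **2 Mb**) — a descriptive, plotting-oriented
summary with no inferential weight, hence the deliberately coarse
default.

# Classification

Features are $\log_2(\mathrm{CPM} + 1)$ values over the windows
intersecting the DMR set, using TMM effective library sizes. With
tens of samples and potentially more windows than samples, LDA is
regularized twice: features are reduced to the top
$k = \min(n - 2, 10)$ principal components, and the pooled
within-class covariance is shrunk as
$(1-\lambda)S + \lambda\,\overline{\mathrm{diag}(S)}\,I$ with
$\lambda = 0.1$ by default. Classification uses the larger linear
discriminant score with equal priors (deterministic under class
imbalance). Leave-one-out accuracy refits the entire model — PCA
included — for each held-out sample.

Feature selection is a leakage hazard: windows chosen on all samples
encode the held-out label. When the pipeline evaluates LOO accuracy
it uses DMRs called on the training cohort, and the null-data checks
in the test suite select features under a labelling independent of
the evaluated (shuffled) labels, so chance-level performance there
is leakage-free. PCA signs are fixed (largest-magnitude loading
positive) so scores are reproducible under sample reordering; the
dendrogram is average-linkage `hclust` on Euclidean distances of
centered features, exportable as Newick. Random-forest
classification is deliberately not implemented: it is an
off-the-shelf ensemble with no method content specific to this
pipeline, whereas PCA + shrinkage LDA is the deterministic,
fully specifiable core.

# The synthetic-data generator

`simulation_config()` defaults encode the emulated study design:
**19 cases vs 21 controls** per cohort, 1-kb windows, baseline mean
**50** counts per window, dispersion $\phi$ = **0.1**, per-sample
library-size factors uniform on **[0.5, 2]** (the real per-sample
depth range is known only as roughly 5–35 million reads, so this
spread is a stand-in for scale only), **20** planted DMRs of **1–3**
windows at fold change **3**, directions alternating so gains and
losses are balanced, and planted regions separated by at least two
windows so calls cannot bridge distinct truths. Genomes are built in
100-bp tiles carrying 1–3 CpGs (desert regime) or 8–10 CpGs in 1-kb
island blocks covering `cpg_island_fraction` (default 2%) of the
genome; accidental CG dinucleotides are removed before placement so
the planted positions are exactly the genome's CpG sites, a property
the tests verify by re-reading the written FASTA.

The generator is count-level by design — the NB matrix is the
statistical object the test consumes — with a read-level emitter
(`simulate_reads`) that places fragments inside windows to exercise
the counting and BED paths. It does **not** model fragment-length
distributions, GC or CpG-coupling bias, batch effects, or
paired-end structure; passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to those real-data artifacts. CpG-coupling normalization
is likewise out of scope: raw counts with TMM are tested, matching
the two-group design the pipeline targets.

Validation scale: the test suite runs at 5000 windows with 12 vs 12
samples for the type-I, dispersion-recovery, and planted-DMR
recovery checks, 1000 windows with 10 vs 10 at fold change 4 for the
classifier's strong-signal bracket, and 20 repetitions of 600-window
null datasets for its chance-level bracket — sizes at which
Monte-Carlo bands (three standard errors) are tight enough to be
meaningful while a full run of the suite stays interactive.

# Numerical and degenerate-input conventions

- A window with zero total count gives $p = 1$ and fold change 0.
- Exact-test ties use a relative $10^{-10}$ tolerance (shared by the
  enumeration reference in the tests).
- Library-size scaling rounds half-to-even; dispersion search is
  bounded in $[10^{-6}, 10]$, so a Poisson truth reports about
  $10^{-6}$ rather than exactly 0.
- p-values are validated to lie in $(0, 1]$ before FDR adjustment.
- `p_sig` must be strictly below `p_edge`; equal-p ties at the seed
  threshold are excluded (strict `<`).
- All simulators take one seed and restore the caller's RNG state;
  the pipeline derives every stage seed from the single run seed, so
  identical configurations produce byte-identical output tables.

# Known limitations

- Exact numerical equality with any particular release of external
  count-testing software is a non-goal; correctness is defined by
  the enumeration oracle and the simulation properties above.
- The common-dispersion model ignores window-specific dispersion;
  severely overdispersed outlier windows will look anti-conservative.
- Real cohort sizes of published MeDIP studies (hundreds of samples,
  3-Gb genomes) are far above the desk-scale synthetic defaults; the
  pipeline is O(windows × samples) and scales linearly, but the
  defaults here are chosen for validated, reproducible simulation
  rather than production throughput.
- Cross-cohort overlap percentages depend on the chosen denominator
  (row cohort); both directions are always reported.
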