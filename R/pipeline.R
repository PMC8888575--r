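# End-to-end orchestration: simulate -> (optional read counting) ->
# test -> call-dmrs -> annotate -> overlap -> classify, with a JSON
# manifest (parameter echo, stage outputs, checksums) so a run is
# reproducible and auditable. All randomness derives from the single
# config seed; re-running with the same config yields byte-identical
# tables.

#' Build a pipeline run configuration
#'
#' @param seed global RNG seed.
#' @param cohorts cohort labels to simulate and compare (>= 1; two or
#'   more enables the overlap stage).
#' @param shared_fraction fraction of planted DMR regions common to
#'   all cohorts (emulates cross-cohort sharing; default 0.5).
#' @param simulation a [simulation_config()] (its seed is derived
#'   from `seed` per cohort).
#' @param n_genes genes in the synthetic annotation.
#' @param min_total low-count window filter (see [filter_windows()]).
#' @param dmr a [dmr_call_params()].
#' @param max_gene_distance gene-association cutoff in bp.
#' @param relaxed_p extended-overlap threshold.
#' @param cluster_gap chromosomal cluster linkage gap in bp.
#' @param prior_count fold-change prior count.
#' @param shrinkage,n_components LDA settings.
#' @param genome_fasta optional existing genome FASTA (skips genome
#'   simulation).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(seed = 1,
                       cohorts = c("mother", "father"),
                       shared_fraction = 0.5,
                       simulation = simulation_config(),
                       n_genes = 60,
                       min_total = 10,
                       dmr = dmr_call_params(),
                       max_gene_distance = 10000,
                       relaxed_p = 0.05,
                       cluster_gap = 2e6,
                       prior_count = 0.5,
                       shrinkage = 0.1,
                       n_components = NULL,
                       genome_fasta = NULL) {
  if (!length(cohorts)) stop_medip("need at least one cohort")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop_medip("shared_fraction must be in [0, 1]")
  if (!is.null(genome_fasta) && !file.exists(genome_fasta))
    stop_medip("genome_fasta not found: ", genome_fasta)
  if (relaxed_p <= dmr$p_sig)
    stop_medip("relaxed_p must exceed the DMR seed threshold")
  structure(as.list(environment()), class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; the `simulation`
#' and `dmr` blocks mirror [simulation_config()] and
#' [dmr_call_params()].
#'
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$simulation))
    args$simulation <- do.call(simulation_config, y$simulation)
  if (!is.null(y$dmr)) args$dmr <- do.call(dmr_call_params, y$dmr)
  do.call(run_config, args)
}

#' Run the full DMR pipeline on synthetic data
#'
#' Executes simulation, counting-stage bookkeeping, per-window
#' testing, DMR calling with CpG characterization, gene association,
#' cross-cohort overlap, chromosomal clustering and LDA
#' classification, writing every table under `out_dir` and a
#' manifest JSON with md5 checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with per-cohort results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   cohorts = config$cohorts,
                   parameters = .echo_config(config),
                   stages = list(), files = list())
  t0 <- Sys.time()

  # --- stage 1: genome + annotation -------------------------------
  sim <- config$simulation
  if (is.null(config$genome_fasta)) {
    sim$seed <- config$seed
    fasta <- file.path(out_dir, "genome.fa")
    g <- generate_genome(sim, fasta = fasta)
    genome <- g$genome
  } else {
    fasta <- config$genome_fasta
    genome <- read_genome_fasta(fasta)
  }
  genes <- generate_annotation(genome, config$n_genes,
                               seed = config$seed + 101L)
  manifest$stages$simulate_genome <- list(
    fasta = basename(fasta), n_chroms = length(genome$chrom_names),
    n_genes = nrow(genes))

  # planted regions: a shared core plus cohort-private extras
  shared_cfg <- sim
  shared_cfg$n_planted <- round(config$shared_fraction * sim$n_planted)
  shared <- plant_dmr_regions(genome, shared_cfg,
                              seed = config$seed + 202L)

  cohort_res <- list()
  for (ci in seq_along(config$cohorts)) {
    co <- config$cohorts[ci]
    cfg <- sim
    cfg$seed <- config$seed + 1000L * ci
    # private regions drawn until separated from the shared core
    private_cfg <- cfg
    private_cfg$n_planted <- sim$n_planted - nrow(shared)
    truth <- shared
    if (private_cfg$n_planted > 0) {
      priv <- .plant_avoiding(genome, private_cfg, shared,
                              seed = cfg$seed + 7L)
      truth <- rbind(shared, priv)
    }
    truth <- truth[order(truth$chrom, truth$start), ]
    rownames(truth) <- NULL

    ds <- simulate_dataset(cfg, genome, planted = truth, cohort = co)
    filtered <- filter_windows(ds$counts, config$min_total)
    norm <- tmm_factors(filtered)
    res <- test_windows(filtered, ds$samples$group, norm = norm,
                        prior_count = config$prior_count)
    dmrs <- call_dmrs(res, config$dmr, cohort = co, genome = genome)
    dmrs <- associate_genes(dmrs, genes, config$max_gene_distance)
    summ <- summarize_dmrs(res, params = config$dmr)
    clusters <- cluster_summary(dmrs, config$cluster_gap)

    pfx <- file.path(out_dir, co)
    write_window_counts(ds$counts, paste0(pfx, "_counts.tsv"))
    write_sample_sheet(ds$samples, paste0(pfx, "_samples.tsv"))
    utils::write.table(truth, paste0(pfx, "_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_test_results(res, paste0(pfx, "_window_tests.tsv"))
    write_pvalue_bedgraph(res, paste0(pfx, "_pvalues.bedgraph"))
    write_dmr_table(dmrs, paste0(pfx, "_dmrs.tsv"))
    write_dmr_bed(dmrs, paste0(pfx, "_dmrs.bed"))
    utils::write.table(clusters, paste0(pfx, "_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    classify <- NULL
    if (nrow(dmrs)) {
      feat <- dmr_feature_matrix(filtered, norm, dmrs)
      pca <- feature_pca(feat, n_components = min(5, nrow(feat$x) - 1))
      lda <- lda_train_predict(feat, ds$samples$group,
                               n_components = config$n_components,
                               shrinkage = config$shrinkage)
      tree <- feature_dendrogram(feat)
      utils::write.table(
        data.frame(sample_id = rownames(pca$scores), pca$scores),
        paste0(pfx, "_pca_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      dendrogram_newick(tree, paste0(pfx, "_dendrogram.nwk"))
      utils::write.table(
        data.frame(sample_id = ds$samples$sample_id,
                   group = ds$samples$group,
                   loo_prediction = lda$loo_predictions),
        paste0(pfx, "_loo_predictions.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      classify <- list(pca = pca, lda = lda, tree = tree)
    }
    manifest$stages[[paste0("cohort_", co)]] <- list(
      n_windows_tested = nrow(res), phi = attr(res, "phi"),
      n_dmrs = nrow(dmrs),
      n_multi_window = sum(dmrs$n_sig_windows >= 2),
      loo_accuracy = if (!is.null(classify))
        classify$lda$loo_accuracy else NA)
    cohort_res[[co]] <- list(dataset = ds, results = res, dmrs = dmrs,
                             truth = truth, summary = summ,
                             clusters = clusters, classify = classify,
                             norm = norm)
  }

  # --- overlap stage ----------------------------------------------
  overlaps <- list()
  if (length(config$cohorts) >= 2) {
    pairs <- utils::combn(config$cohorts, 2, simplify = FALSE)
    for (pr in pairs) {
      a <- pr[1]; b <- pr[2]
      overlaps[[length(overlaps) + 1]] <-
        overlap_exact(cohort_res[[a]]$dmrs, cohort_res[[b]]$dmrs, a, b)
      overlaps[[length(overlaps) + 1]] <-
        overlap_exact(cohort_res[[b]]$dmrs, cohort_res[[a]]$dmrs, b, a)
      overlaps[[length(overlaps) + 1]] <-
        overlap_extended(cohort_res[[a]]$dmrs, cohort_res[[b]]$results,
                         config$relaxed_p, a, b,
                         p_sig = config$dmr$p_sig)
      overlaps[[length(overlaps) + 1]] <-
        overlap_extended(cohort_res[[b]]$dmrs, cohort_res[[a]]$results,
                         config$relaxed_p, b, a,
                         p_sig = config$dmr$p_sig)
    }
    write_overlap_table(overlaps, file.path(out_dir, "overlaps.tsv"))
    venn <- venn_partition(lapply(cohort_res, `[[`, "dmrs"))
    jsonlite::write_json(venn, file.path(out_dir, "venn.json"),
                         dataframe = "rows", auto_unbox = TRUE)
    manifest$stages$overlap <- list(n_pairs = length(pairs))
  }

  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest$files <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  manifest$elapsed_sec <- round(
    as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohorts = cohort_res, overlaps = overlaps,
                 manifest = manifest, genome = genome, genes = genes))
}

# plant regions rejecting anything within 2 windows of `avoid`
#' @noRd
.plant_avoiding <- function(genome, config, avoid, seed) {
  w <- config$window_size
  for (attempt in 1:50) {
    cand <- plant_dmr_regions(genome, config, seed = seed + attempt)
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      same <- avoid$chrom == cand$chrom[i]
      !any(same & avoid$start - 2 * w < cand$end[i] &
             avoid$end + 2 * w > cand$start[i])
    }, logical(1))
    if (all(ok)) {
      # re-alternate directions so the combined truth keeps ~50/50
      n0 <- nrow(avoid)
      cand$direction <- rep_len(c(1L, -1L), n0 + nrow(cand))[-seq_len(n0)]
      cand$fold_change <- ifelse(cand$direction > 0,
                                 config$planted_fold_change,
                                 1 / config$planted_fold_change)
      return(cand)
    }
  }
  stop_medip("could not place cohort-private DMRs away from shared ones")
}

#' @noRd
.echo_config <- function(config) {
  cfg <- unclass(config)
  cfg$simulation <- unclass(cfg$simulation)
  cfg$dmr <- unclass(cfg$dmr)
  cfg
}
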