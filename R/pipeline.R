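#' Run the full analysis pipeline end to end
#'
#' Simulates (or loads) a count data set and runs every analysis stage,
#' writing deterministic TSV outputs: counts, sample metadata, annotation
#' and truth; size factors and normalized expression; per-stage
#' background fits and detection calls; the receptor onset table,
#' per-sensillum summary and Notch tally at the focal stage;
#' transcription-factor stage-mean profiles, cluster assignments and the
#' dendrogram in Newick format; PCA scores, loadings and variance; and an
#' MA comparison for each consecutive stage pair. Identical `config` and
#' `seed` produce byte-identical output files.
#'
#' Detection calls for the onset reconstruction use Bonferroni-adjusted
#' p-values at family level `onset_alpha` across the receptor-by-stage
#' table: onset maps are sensitive to even one false early call, so
#' family-wise control is applied there, while the plain per-test rule at
#' `alpha` is used for the stage-wise detection table.
#'
#' @param config A [sim_config()]; its `rng_seed` is replaced by `seed`
#'   when one is given.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding `config$rng_seed`.
#' @param focal_stage Stage for the sensillum/Notch summaries (default
#'   the second-to-last stage).
#' @param alpha Per-test level for the detection table (default 0.05).
#' @param onset_alpha Family-wise level for the onset calls
#'   (default 0.01).
#' @param k Cluster count for the TF profiles.
#'
#' @return Invisibly, a named character vector of output file paths.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         focal_stage = NULL, alpha = 0.05,
                         onset_alpha = 0.01, k = config$n_cluster_archetypes) {
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  focal_stage <- focal_stage %||% stages[max(1L, length(stages) - 1L)]
  paths <- c()
  emit <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(x, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }

  sim <- simulate_counts(config)
  emit(sim$counts, "counts")
  emit(sim$samples, "samples")
  emit(sim$annotation, "annotation")
  emit(sim$truth, "truth")

  sf <- compute_size_factors(sim$counts)
  emit(sf, "size_factors")
  norm <- normalize_counts(sim$counts, sf)
  emit(tibble::as_tibble(norm), "normalized")

  bg <- fit_background(sim$counts, sim$samples, sim$annotation,
                       stages = stages)
  emit(tidy(bg), "background")
  calls <- call_expressed(sim$counts, sim$samples, sim$annotation, bg,
                          alpha = alpha)
  emit(calls, "detection_calls")

  onset_calls <- call_expressed(sim$counts, sim$samples, sim$annotation, bg,
                                alpha = onset_alpha, adjust = "bonferroni")
  onsets <- onset_table(onset_calls, stages)
  emit(onsets, "onsets")
  sens <- sensillum_report(onsets, sim$annotation, focal_stage)
  sens$typicality <- attr(sens, "typicality")
  emit(sens, "sensillum_summary")
  emit(notch_tally(onsets, sim$annotation, focal_stage), "notch_tally")

  tf_ids <- sim$annotation$gene_id[sim$annotation$gene_class == "TF"]
  profiles <- stage_means(norm, sim$samples, stages = stages)
  emit(profiles, "stage_means")
  tf_profiles <- profiles[profiles$gene_id %in% tf_ids, ]
  cl <- cluster_profiles(tf_profiles, k = k)
  emit(tidy(cl), "tf_clusters")
  dendro <- file.path(out_dir, "tf_dendrogram.nwk")
  write_dendrogram(cl, dendro)
  paths[["tf_dendrogram"]] <- dendro
  emit(classify_trend(tf_profiles), "tf_trends")

  pca <- run_pca(norm)
  emit(tidy(pca, "scores"), "pca_scores")
  emit(tidy(pca, "loadings"), "pca_loadings")
  emit(tidy(pca, "variance"), "pca_variance")

  for (i in seq_len(length(stages) - 1L)) {
    cmp <- pairwise_ma(sim$counts, sim$samples, stages[i], stages[i + 1L],
                       size_factors = sf)
    emit(tibble::as_tibble(cmp), paste0("ma_", stages[i], "_vs_", stages[i + 1L]))
  }

  invisible(unlist(paths))
}
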