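#' Simulate a developmental count data set
#'
#' Draws a gene-by-sample matrix of negative-binomial counts with the
#' statistical structure the downstream analyses assume: negative-control
#' genes and pre-onset receptors produce low background counts at every
#' stage; receptors at or after their planted onset produce counts around
#' the scheduled expressed mean, amplified by `adult_fold_increase` at the
#' adult stage; transcription factors are drawn around their planted
#' archetype profile plus a gene-level log2 offset; filler genes are
#' stage-constant. All means are multiplied by the sample's library size
#' factor before sampling, which keeps counts NB-distributed.
#'
#' Each gene draws from its own RNG stream derived from `rng_seed` and the
#' gene id, so the output is bit-reproducible and adding genes to a
#' configuration leaves the counts of existing genes unchanged.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{counts}{tibble, `gene_id` plus one integer column per sample}
#'     \item{samples}{tibble: `sample_id`, `stage`, `replicate`}
#'     \item{annotation}{tibble: `gene_id`, `gene_class`, `sensilla`,
#'       `notch_state`}
#'     \item{truth}{tibble of planted ground truth: `gene_id`,
#'       `gene_class`, `onset_stage` ("none" for non-receptors),
#'       `archetype` (NA for non-TFs), `expressed_mean`; the per-stage
#'       background parameters are attached as attribute `background`}
#'   }
#' @export
#'
#' @examples
#' sim <- simulate_counts(sim_config(n_tfs = 20, n_other_genes = 10))
#' dim(sim$counts)
simulate_counts <- function(config = sim_config()) {
  validate_sim_config(config)
  stages <- config$stages
  reps <- config$replicates_per_stage
  samples <- tidyr::expand_grid(stage = stages, replicate = seq_len(reps)) |>
    dplyr::mutate(sample_id = paste0(.data$stage, "_r", .data$replicate)) |>
    dplyr::select("sample_id", "stage", "replicate")
  n_samples <- nrow(samples)
  lsf <- config$library_size_factors %||% rep(1, n_samples)
  bm <- setNames(config$background_mean_per_stage, stages)
  stage_of_sample <- samples$stage

  gene_plan <- build_gene_plan(config)

  draw_gene <- function(row) {
    base <- switch(row$kind,
      control = unname(bm[stage_of_sample]),
      receptor = {
        on_idx <- match(row$onset_stage, stages)
        idx <- match(stage_of_sample, stages)
        mu <- unname(bm[stage_of_sample])
        on <- idx >= on_idx
        mu[on] <- row$expressed_mean
        adult <- idx == length(stages)
        mu[on & adult] <- row$expressed_mean * config$adult_fold_increase
        mu
      },
      tf = NA_real_, # filled inside the stream (needs the gene offset)
      other = NA_real_
    )
    with_seed(gene_seed(config$rng_seed, row$gene_id), {
      if (row$kind == "tf") {
        offset <- rnorm(1, 0, config$tf_gene_sd)
        prof <- unlist(config$archetype_profiles[row$archetype, stages])
        base <- 2^(unname(prof[stage_of_sample]) + offset)
      } else if (row$kind == "other") {
        lvl <- rnorm(1, config$other_mean_log2, config$other_sd)
        base <- rep(2^lvl, n_samples)
      }
      size <- switch(row$kind,
        control = config$background_dispersion,
        receptor = {
          on <- match(stage_of_sample, stages) >= match(row$onset_stage, stages)
          ifelse(on, config$receptor_dispersion, config$background_dispersion)
        },
        tf = config$tf_dispersion,
        other = config$other_dispersion
      )
      rnbinom(n_samples, mu = base * lsf, size = size)
    })
  }

  mat <- t(vapply(seq_len(nrow(gene_plan)),
                  function(i) draw_gene(gene_plan[i, ]),
                  numeric(n_samples)))
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = gene_plan$gene_id),
    tibble::as_tibble(matrix(as.integer(mat), nrow = nrow(mat),
                             dimnames = list(NULL, samples$sample_id)))
  )

  annotation <- tibble::tibble(
    gene_id = gene_plan$gene_id,
    gene_class = gene_plan$gene_class,
    sensilla = gene_plan$sensilla,
    notch_state = gene_plan$notch_state
  )

  truth <- tibble::tibble(
    gene_id = gene_plan$gene_id,
    gene_class = gene_plan$gene_class,
    onset_stage = ifelse(is.na(gene_plan$onset_stage), "none",
                         gene_plan$onset_stage),
    archetype = gene_plan$archetype,
    expressed_mean = gene_plan$expressed_mean
  )
  attr(truth, "background") <- tibble::tibble(
    stage = stages,
    mu = unname(bm),
    size = config$background_dispersion
  )

  out <- list(counts = counts, samples = samples,
              annotation = annotation, truth = truth)
  attr(out, "config") <- config
  class(out) <- "sim_dataset"
  out
}

# one row per simulated gene with everything draw_gene needs
build_gene_plan <- function(config) {
  sched <- config$onset_schedule
  controls <- tibble::tibble(
    gene_id = sprintf("nGR%02d", seq_len(config$n_control_genes)),
    gene_class = "GR_nonantennal", kind = "control",
    onset_stage = NA_character_, expressed_mean = NA_real_,
    sensilla = NA_character_, notch_state = "unknown",
    archetype = NA_integer_
  )
  receptors <- tibble::tibble(
    gene_id = sched$gene_id, gene_class = sched$gene_class, kind = "receptor",
    onset_stage = sched$onset_stage, expressed_mean = sched$expressed_mean,
    sensilla = sched$sensilla, notch_state = sched$notch_state,
    archetype = NA_integer_
  )
  tfs <- tibble::tibble(
    gene_id = sprintf("TF%03d", seq_len(config$n_tfs)),
    gene_class = "TF", kind = "tf",
    onset_stage = NA_character_, expressed_mean = NA_real_,
    sensilla = NA_character_, notch_state = "unknown",
    archetype = rep(seq_len(config$n_cluster_archetypes),
                    length.out = config$n_tfs)
  )
  others <- if (config$n_other_genes > 0) {
    tibble::tibble(
      gene_id = sprintf("gene%03d", seq_len(config$n_other_genes)),
      gene_class = "other", kind = "other",
      onset_stage = NA_character_, expressed_mean = NA_real_,
      sensilla = NA_character_, notch_state = "unknown",
      archetype = NA_integer_
    )
  } else {
    NULL
  }
  dplyr::bind_rows(controls, receptors, tfs, others)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d genes x %d samples (%s)\n",
    nrow(x$counts), nrow(x$samples),
    paste(unique(x$samples$stage), collapse = ", ")
  ))
  print(dplyr::count(x$annotation, .data$gene_class))
  invisible(x)
}
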