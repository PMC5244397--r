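#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_counts()]. The
#' defaults emulate the design of the antennal developmental time course
#' the package targets: four stages (third-instar larva, 8 h and 40 h
#' after puparium formation, adult) with two biological replicates each,
#' a family of 50 non-antennal gustatory receptors generating low
#' background counts, 62 antennal receptors with planted onset stages and
#' a ~100-fold expression increase between p40 and adult, and 400
#' transcription factors drawn from 11 planted temporal archetypes.
#'
#' @param stages Ordered character vector of stage labels.
#' @param replicates_per_stage Positive integer, replicates per stage.
#' @param n_control_genes Number of negative-control (non-antennal GR)
#'   genes generating pure background counts at every stage.
#' @param n_receptors Number of antennal receptor genes (OR + IR).
#' @param n_tfs Number of transcription-factor genes.
#' @param n_other_genes Number of unclassified filler genes.
#' @param background_mean_per_stage Expected background count per
#'   replicate at each stage, in stage order. Background counts for genes
#'   not expressed in the antenna are experimental noise of a few reads.
#' @param background_dispersion NB size parameter `k` of the background
#'   null (variance = mu + mu^2/k); small values give the heavy-tailed
#'   noise counts typical of unexpressed genes.
#' @param receptor_dispersion NB size for receptors at or after onset.
#'   Pooled-antennae bulk replicates are tightly reproducible, so
#'   expressed genes get a much larger size (smaller dispersion) than
#'   background noise.
#' @param tf_dispersion NB size for transcription-factor counts.
#' @param other_dispersion NB size for filler genes.
#' @param onset_schedule Data frame with one row per receptor: `gene_id`,
#'   `gene_class` ("OR" or "IR"), `onset_stage` (member of `stages`),
#'   `expressed_mean` (expected count per replicate at onset), `sensilla`
#'   (semicolon-separated sensillum labels) and `notch_state`
#'   ("On"/"Off"/"unknown"). Defaults to [default_onset_schedule()].
#' @param adult_fold_increase Multiplier applied to receptor expressed
#'   means at the adult stage (default 100, i.e. about two orders of
#'   magnitude above the pupal expression level).
#' @param n_cluster_archetypes Number of planted TF archetypes.
#' @param archetype_profiles Data frame of per-archetype log2 stage means
#'   as returned by [archetype_profiles_default()].
#' @param tf_gene_sd Standard deviation (log2 units) of the per-gene
#'   expression offset added to each TF's archetype profile.
#' @param other_mean_log2,other_sd Location and spread (log2 counts) of
#'   the filler-gene expression levels.
#' @param library_size_factors Optional per-sample multiplicative library
#'   size factors (length stages x replicates, in sample order); `NULL`
#'   means all 1.
#' @param rng_seed Integer root seed. Each gene derives its own stream
#'   from this root, so adding genes does not reshuffle existing counts.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(stages = default_stages(),
                       replicates_per_stage = 2L,
                       n_control_genes = 50L,
                       n_receptors = 62L,
                       n_tfs = 400L,
                       n_other_genes = 200L,
                       background_mean_per_stage = c(2, 3, 4, 6),
                       background_dispersion = 2,
                       receptor_dispersion = 20,
                       tf_dispersion = 50,
                       other_dispersion = 20,
                       onset_schedule = NULL,
                       adult_fold_increase = 100,
                       n_cluster_archetypes = 11L,
                       archetype_profiles = NULL,
                       tf_gene_sd = 1,
                       other_mean_log2 = 6,
                       other_sd = 2,
                       library_size_factors = NULL,
                       rng_seed = 1L) {
  if (is.null(onset_schedule)) {
    onset_schedule <- default_onset_schedule(
      n_receptors = n_receptors, stages = stages,
      background_mean_per_stage = background_mean_per_stage
    )
  }
  if (is.null(archetype_profiles)) {
    archetype_profiles <- archetype_profiles_default(n_cluster_archetypes, stages)
  }
  cfg <- list(
    stages = as.character(stages),
    replicates_per_stage = as.integer(replicates_per_stage),
    n_control_genes = as.integer(n_control_genes),
    n_receptors = as.integer(n_receptors),
    n_tfs = as.integer(n_tfs),
    n_other_genes = as.integer(n_other_genes),
    background_mean_per_stage = as.numeric(background_mean_per_stage),
    background_dispersion = as.numeric(background_dispersion),
    receptor_dispersion = as.numeric(receptor_dispersion),
    tf_dispersion = as.numeric(tf_dispersion),
    other_dispersion = as.numeric(other_dispersion),
    onset_schedule = tibble::as_tibble(onset_schedule),
    adult_fold_increase = as.numeric(adult_fold_increase),
    n_cluster_archetypes = as.integer(n_cluster_archetypes),
    archetype_profiles = tibble::as_tibble(archetype_profiles),
    tf_gene_sd = as.numeric(tf_gene_sd),
    other_mean_log2 = as.numeric(other_mean_log2),
    other_sd = as.numeric(other_sd),
    library_size_factors = if (is.null(library_size_factors)) NULL else as.numeric(library_size_factors),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every invariant the simulator relies on and raises a
#' configuration error naming the offending field.
#'
#' @param config A `sim_config` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  stages <- config$stages
  if (length(stages) < 2 || anyDuplicated(stages) > 0) {
    stop_config("stages", "must hold at least two distinct stage labels")
  }
  if (is.na(config$replicates_per_stage) || config$replicates_per_stage < 1) {
    stop_config("replicates_per_stage", "must be >= 1")
  }
  for (f in c("n_control_genes", "n_receptors", "n_tfs")) {
    if (is.na(config[[f]]) || config[[f]] < 1) stop_config(f, "must be a positive integer")
  }
  if (is.na(config$n_other_genes) || config$n_other_genes < 0) {
    stop_config("n_other_genes", "must be non-negative")
  }
  bm <- config$background_mean_per_stage
  if (length(bm) != length(stages) || any(!is.finite(bm)) || any(bm <= 0)) {
    stop_config("background_mean_per_stage",
                "must hold one strictly positive mean per stage")
  }
  for (f in c("background_dispersion", "receptor_dispersion", "tf_dispersion",
              "other_dispersion", "adult_fold_increase")) {
    if (!is.finite(config[[f]]) || config[[f]] <= 0) {
      stop_config(f, "must be strictly positive")
    }
  }
  sched <- config$onset_schedule
  req <- c("gene_id", "gene_class", "onset_stage", "expressed_mean",
           "sensilla", "notch_state")
  if (!all(req %in% names(sched))) {
    stop_config("onset_schedule",
                sprintf("must have columns %s", paste(req, collapse = ", ")))
  }
  if (nrow(sched) != config$n_receptors) {
    stop_config("onset_schedule", "must have one row per receptor")
  }
  if (anyDuplicated(sched$gene_id) > 0) {
    stop_config("onset_schedule", "has duplicated gene ids")
  }
  if (!all(sched$onset_stage %in% stages)) {
    stop_config("onset_schedule", "contains onset stages outside `stages`")
  }
  if (any(!is.finite(sched$expressed_mean)) || any(sched$expressed_mean <= 0)) {
    stop_config("onset_schedule", "expressed means must be strictly positive")
  }
  prof <- config$archetype_profiles
  if (nrow(prof) != config$n_cluster_archetypes) {
    stop_config("archetype_profiles",
                "row count must equal n_cluster_archetypes")
  }
  if (!all(stages %in% names(prof))) {
    stop_config("archetype_profiles", "must hold one column per stage")
  }
  if (!is.null(config$library_size_factors)) {
    n_samples <- length(stages) * config$replicates_per_stage
    lsf <- config$library_size_factors
    if (length(lsf) != n_samples || any(!is.finite(lsf)) || any(lsf <= 0)) {
      stop_config("library_size_factors",
                  sprintf("must hold %d strictly positive values", n_samples))
    }
  }
  if (is.na(config$rng_seed)) stop_config("rng_seed", "must be an integer")
  invisible(config)
}

#' Default receptor onset schedule
#'
#' Constructs the planted receptor design. For the default 62 receptors
#' over the default four stages it reproduces the structure reported for
#' the antennal time course: 21 receptors (17 ORs, 4 IRs) expressed by
#' p40 -- three ORs on from the larval stage, one IR on from p8, and 17
#' receptors with p40 onset -- housed in 21 sensilla of 1-4 receptors
#' each, with four sensilla carrying two early receptors and one IR shared
#' between two coeloconic sensilla; the 17 p40-expressed ORs split 9
#' Notch-On / 8 Notch-Off. The remaining 41 receptors have adult onset.
#' For other receptor counts a generic layout is built: sensilla of three
#' members, the first member of each with onset at the second-to-last
#' stage and the rest at the final stage.
#'
#' @param n_receptors Number of receptors.
#' @param stages Ordered stage labels.
#' @param background_mean_per_stage Background means, used to scale the
#'   expressed mean at onset.
#' @param expressed_fold Expressed mean at onset as a multiple of the
#'   onset stage's background mean (default 20).
#'
#' @return A tibble with columns `gene_id`, `gene_class`, `onset_stage`,
#'   `expressed_mean`, `sensilla`, `notch_state`.
#' @export
default_onset_schedule <- function(n_receptors = 62L,
                                   stages = default_stages(),
                                   background_mean_per_stage = c(2, 3, 4, 6),
                                   expressed_fold = 20) {
  bm <- setNames(background_mean_per_stage, stages)
  if (n_receptors == 62L && length(stages) == 4L) {
    sens <- c("ab1", paste0("ab", 2:10), paste0("at", 1:4), paste0("ac", 1:4),
              paste0("pb", 1:3))
    sizes <- setNames(c(4, rep(3, 9), rep(3, 4), rep(3, 4), 3, 3, 1), sens)
    # lay receptors into sensilla; ORs fill ab/at/pb, IRs fill ac
    rows <- list()
    or_i <- 0L; ir_i <- 0L
    next_or <- function() { or_i <<- or_i + 1L; sprintf("OR%02d", or_i) }
    next_ir <- function() { ir_i <<- ir_i + 1L; sprintf("IR%02d", ir_i) }
    # onset plan per sensillum: which member slots are early and at what stage
    early_plan <- list(
      ab1 = c(stages[1], stages[3]), ab5 = c(stages[3], stages[3]),
      ab8 = c(stages[1], stages[3]), at3 = stages[1],
      ab2 = stages[3], ab3 = stages[3], ab4 = stages[3], ab6 = stages[3],
      ab7 = stages[3], ab9 = stages[3], ab10 = stages[3],
      at1 = stages[3], at2 = stages[3], at4 = stages[3],
      ac1 = stages[2],                       # shared IR, on from p8
      ac3 = c(stages[3], stages[3]),         # two coeloconic IRs at p40
      ac4 = stages[3]
      # pb1..pb3: no early members
    )
    for (s in sens) {
      plan <- early_plan[[s]] %||% character(0)
      is_ir <- startsWith(s, "ac")
      for (m in seq_len(sizes[[s]])) {
        onset <- if (m <= length(plan)) plan[m] else stages[length(stages)]
        id <- if (is_ir) next_ir() else next_or()
        sensilla <- if (s == "ac1" && m == 1L) "ac1;ac2" else s
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = id,
          gene_class = if (is_ir) "IR" else "OR",
          onset_stage = onset,
          sensilla = sensilla
        )
      }
    }
    sched <- dplyr::bind_rows(rows)
    # Notch fates: among the 17 p40-expressed ORs, 9 On and 8 Off; later
    # ORs alternate; IR fates left unknown
    p40_or <- sched$gene_class == "OR" &
      sched$onset_stage %in% stages[seq_len(3)]
    notch <- rep("unknown", nrow(sched))
    notch[p40_or] <- rep(c("On", "Off"), length.out = sum(p40_or))
    late_or <- sched$gene_class == "OR" & !p40_or
    notch[late_or] <- rep(c("Off", "On"), length.out = sum(late_or))
    sched$notch_state <- notch
  } else {
    n_sens <- ceiling(n_receptors / 3)
    rows <- list()
    g <- 0L
    onset_mid <- stages[max(1L, length(stages) - 1L)]
    for (s in seq_len(n_sens)) {
      for (m in seq_len(min(3L, n_receptors - g))) {
        g <- g + 1L
        rows[[g]] <- tibble::tibble(
          gene_id = sprintf("OR%02d", g),
          gene_class = "OR",
          onset_stage = if (m == 1L) onset_mid else stages[length(stages)],
          sensilla = sprintf("s%02d", s)
        )
      }
    }
    sched <- dplyr::bind_rows(rows)
    sched$notch_state <- rep(c("On", "Off"), length.out = nrow(sched))
  }
  sched$expressed_mean <- expressed_fold * unname(bm[sched$onset_stage])
  sched[, c("gene_id", "gene_class", "onset_stage", "expressed_mean",
            "sensilla", "notch_state")]
}

#' Read or write a simulation configuration as YAML
#'
#' The configuration is stored as a flat YAML document; the onset schedule
#' and archetype profiles are stored column-wise.
#'
#' @param path File path.
#' @param config A `sim_config` object.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("onset_schedule", "archetype_profiles")) {
    if (!is.null(raw[[f]])) raw[[f]] <- tibble::as_tibble(raw[[f]])
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  out <- unclass(config)
  out$onset_schedule <- as.list(out$onset_schedule)
  out$archetype_profiles <- as.list(out$archetype_profiles)
  yaml::write_yaml(out, path)
  invisible(path)
}
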