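#' Default temporal cluster archetypes
#'
#' Returns `k` planted stage-mean profiles used by the count simulator to
#' generate clusterable transcription-factor expression. The library spans
#' the qualitative shapes seen in developmental time courses: early-high
#' profiles that decline after metamorphosis begins, late-rising profiles,
#' a constitutive ("expressed throughout") profile, and single-stage peaks.
#' Values are log2 expected counts per stage.
#'
#' The first two archetypes are an early-declining and a late-rising shape,
#' so `k = 2` yields the minimal early/late contrast. All pairwise Pearson
#' correlations between archetype shapes are below 0.95, which keeps the
#' planted partition identifiable under a correlation distance. The
#' constitutive archetype carries a mild alternating stage modulation
#' rather than a strictly constant profile: a constant vector has no
#' defined shape under a correlation metric, while real broadly-expressed
#' genes retain a characteristic low-amplitude stage pattern.
#'
#' @param k Number of archetypes, between 2 and 11.
#' @param stages Ordered character vector of stage labels (length 4).
#'
#' @return A tibble with columns `archetype` (integer id), `shape`
#'   (descriptive label) and one numeric column per stage holding the log2
#'   expected count.
#' @export
#'
#' @examples
#' archetype_profiles_default(2)
#' archetype_profiles_default(11)
archetype_profiles_default <- function(k, stages = default_stages()) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 2) {
    abort("`k` must be a single integer >= 2")
  }
  if (length(stages) != 4) {
    abort("the default archetype library is defined over 4 stages")
  }
  lib <- list(
    early_decline = c(12, 11.5, 5, 4),
    late_rise     = c(4, 5, 11, 12),
    constitutive  = c(10, 11.2, 10, 11.2),
    larval_peak   = c(12, 6, 5, 5),
    p8_peak       = c(5, 12, 6, 5),
    p40_peak      = c(5, 6, 12, 6),
    adult_peak    = c(5, 5, 6, 12),
    mid_dip       = c(11, 5, 5, 11),
    mid_peak      = c(5, 11, 11, 5),
    early_gradual = c(12, 9, 8, 4),
    late_gradual  = c(4, 9, 11, 11.5)
  )
  if (k > length(lib)) {
    abort(sprintf("the default archetype library holds %d shapes; `k` = %d requested",
                  length(lib), k))
  }
  lib <- lib[seq_len(k)]
  mat <- do.call(rbind, lib)
  colnames(mat) <- stages
  dplyr::bind_cols(
    tibble::tibble(archetype = seq_len(k), shape = names(lib)),
    tibble::as_tibble(mat)
  )
}
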