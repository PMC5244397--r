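#' Receptor onset table
#'
#' Reduces a detection-call table to one row per gene: the onset stage is
#' the earliest stage (in developmental order) at which the gene is
#' called expressed, or `"none"` if it never is. Genes with a missing
#' stage raise an error listing the offending gene/stage pairs; genes
#' flagged `missing` in the calls are carried through with onset
#' `"none"` and `missing = TRUE`.
#'
#' @param calls Detection-call tibble from [call_expressed()].
#' @param stage_order Ordered stage labels.
#'
#' @return A tibble: `gene_id`, `onset_stage`, `stages_expressed`
#'   (semicolon-joined, in stage order), `missing`.
#' @export
#'
#' @examples
#' calls <- tibble::tibble(
#'   gene_id = "OR01", stage = c("3L", "p8", "p40", "adult"),
#'   expressed = c(FALSE, FALSE, TRUE, TRUE), missing = FALSE
#' )
#' onset_table(calls, c("3L", "p8", "p40", "adult"))
onset_table <- function(calls, stage_order) {
  have <- dplyr::distinct(calls, .data$gene_id, .data$stage)
  need <- tidyr::expand_grid(gene_id = unique(calls$gene_id),
                             stage = stage_order)
  gap <- dplyr::anti_join(need, have, by = c("gene_id", "stage"))
  if (nrow(gap) > 0) {
    abort(sprintf(
      "calls missing for gene/stage pairs: %s",
      paste(utils::head(paste0(gap$gene_id, "@", gap$stage), 10), collapse = ", ")
    ))
  }
  calls |>
    dplyr::mutate(stage = factor(.data$stage, levels = stage_order)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$stage, .by_group = TRUE) |>
    dplyr::summarise(
      onset_stage = {
        on <- as.character(.data$stage[.data$expressed])
        if (length(on) == 0) "none" else on[1]
      },
      stages_expressed = paste(as.character(.data$stage[.data$expressed]),
                               collapse = ";"),
      missing = any(.data$missing),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene_id)
}

#' Per-sensillum expression summary at a focal stage
#'
#' Tallies, for every sensillum, how many of its member receptors are
#' expressed at the focal stage (a receptor is "expressed at" a stage if
#' that stage is in its expressed set), together with the Notch-fate
#' composition of the expressed members. A receptor mapped to several
#' sensilla contributes to each of them. The typicality statistic --
#' the fraction of sensilla with exactly one expressed member -- is
#' attached as attribute `typicality`; receptors with no sensillum
#' mapping are listed in attribute `unmapped`.
#'
#' @param onsets Onset table from [onset_table()].
#' @param annotation Gene annotation tibble with `sensilla` and
#'   `notch_state`.
#' @param focal_stage Stage label at which to summarise.
#'
#' @return A tibble, one row per sensillum: `sensillum`, `n_members`,
#'   `n_expressed`, `expressed_members` (semicolon-joined),
#'   `n_notch_on`, `n_notch_off`, `n_notch_unknown`, `typical`
#'   (exactly one expressed member), `multi` (more than one).
#' @export
sensillum_report <- function(onsets, annotation, focal_stage) {
  ann <- annotation[annotation$gene_id %in% onsets$gene_id, ]
  membership <- tibble::tibble(
    gene_id = ann$gene_id,
    notch_state = ann$notch_state,
    sensillum = split_sensilla(ann$sensilla)
  ) |>
    tidyr::unnest("sensillum")
  unmapped <- setdiff(onsets$gene_id, membership$gene_id)
  if (length(unmapped) > 0) {
    warn(sprintf("receptors without a sensillum mapping: %s",
                 paste(unmapped, collapse = ", ")))
  }
  expressed_at <- onsets$gene_id[
    purrr::map_lgl(strsplit(onsets$stages_expressed, ";"),
                   function(v) focal_stage %in% v)
  ]
  out <- membership |>
    dplyr::group_by(.data$sensillum) |>
    dplyr::summarise(
      n_members = dplyr::n_distinct(.data$gene_id),
      n_expressed = sum(.data$gene_id %in% expressed_at),
      expressed_members = paste(sort(.data$gene_id[.data$gene_id %in% expressed_at]),
                                collapse = ";"),
      n_notch_on = sum(.data$gene_id %in% expressed_at & .data$notch_state == "On"),
      n_notch_off = sum(.data$gene_id %in% expressed_at & .data$notch_state == "Off"),
      n_notch_unknown = sum(.data$gene_id %in% expressed_at &
                              !.data$notch_state %in% c("On", "Off")),
      .groups = "drop"
    ) |>
    dplyr::mutate(typical = .data$n_expressed == 1L,
                  multi = .data$n_expressed > 1L) |>
    dplyr::arrange(.data$sensillum)
  attr(out, "typicality") <- if (nrow(out) == 0) 0 else mean(out$typical)
  attr(out, "focal_stage") <- focal_stage
  attr(out, "unmapped") <- unmapped
  out
}

#' Notch-fate tally of receptors expressed at a focal stage
#'
#' Counts distinct receptor genes expressed at the focal stage,
#' partitioned by annotated Notch state. Unlike [sensillum_report()],
#' each gene counts once regardless of how many sensilla house it.
#'
#' @inheritParams sensillum_report
#' @return A one-row tibble: `focal_stage`, `n_expressed`, `n_notch_on`,
#'   `n_notch_off`, `n_unknown`.
#' @export
notch_tally <- function(onsets, annotation, focal_stage) {
  expressed_at <- onsets$gene_id[
    purrr::map_lgl(strsplit(onsets$stages_expressed, ";"),
                   function(v) focal_stage %in% v)
  ]
  st <- annotation$notch_state[match(expressed_at, annotation$gene_id)]
  st[is.na(st)] <- "unknown"
  tibble::tibble(
    focal_stage = focal_stage,
    n_expressed = length(expressed_at),
    n_notch_on = sum(st == "On"),
    n_notch_off = sum(st == "Off"),
    n_unknown = sum(!st %in% c("On", "Off"))
  )
}
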