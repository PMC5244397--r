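#' Packaged p40-expressed receptor table (synthetic stand-in)
#'
#' Loads the bundled table of the 21 receptors expressed above background
#' at 40 h after puparium formation, with sensillum housing and Notch
#' fate. The table is a synthetic stand-in for the study's supplementary
#' receptor tables, which are not redistributed: receptors named in the
#' main text are real, the remaining rows and the Notch-state
#' assignments are reconstructed to reproduce the reported totals (21
#' expressed receptors, 17 OR-group and 4 IR/coeloconic-group, the ORs
#' split 9 Notch-On / 8 Notch-Off). See the file header of
#' `inst/extdata/p40_receptors_synthetic.tsv` for details.
#'
#' @return A tibble: `gene_id`, `gene_class`, `receptor_group`,
#'   `sensilla`, `notch_state`, `expressed_p40`.
#' @export
#'
#' @examples
#' fx <- p40_receptor_fixture()
#' table(fx$receptor_group)
p40_receptor_fixture <- function() {
  path <- system.file("extdata", "p40_receptors_synthetic.tsv",
                      package = "antdev", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene_id = readr::col_character(),
    gene_class = readr::col_character(),
    receptor_group = readr::col_character(),
    sensilla = readr::col_character(),
    notch_state = readr::col_character(),
    expressed_p40 = readr::col_logical()
  ), progress = FALSE)
}

#' Onset-style table from the packaged p40 fixture
#'
#' Recasts the fixture into the shape [onset_table()] produces so it can
#' feed [sensillum_report()] and [notch_tally()] directly: every receptor
#' flagged `expressed_p40` is listed as expressed at `"p40"`.
#'
#' @return A tibble: `gene_id`, `onset_stage`, `stages_expressed`,
#'   `missing`.
#' @export
p40_fixture_onsets <- function() {
  fx <- p40_receptor_fixture()
  tibble::tibble(
    gene_id = fx$gene_id,
    onset_stage = ifelse(fx$expressed_p40, "p40", "none"),
    stages_expressed = ifelse(fx$expressed_p40, "p40", ""),
    missing = FALSE
  )
}
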