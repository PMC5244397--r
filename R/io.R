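#' Read and write count matrices with sample metadata
#'
#' Counts are stored as UTF-8 tab-delimited text: a header row of sample
#' ids, first column `gene_id`, integer counts. Sample metadata is a
#' companion TSV with columns `sample_id`, `stage`, `replicate`.
#' Malformed input is rejected with the offending row or column named.
#'
#' @param counts_path Path of the count matrix TSV.
#' @param samples_path Path of the sample metadata TSV.
#' @param stages Optional stage vocabulary; when given, stage labels
#'   outside it are a parse error.
#'
#' @return `read_counts()` returns a list with elements `counts` (tibble)
#'   and `samples` (tibble). `write_counts()` returns its paths invisibly.
#' @export
read_counts <- function(counts_path, samples_path, stages = NULL) {
  counts <- readr::read_tsv(counts_path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(counts)[1] != "gene_id") {
    stop_parse(sprintf("%s: first column must be `gene_id`", counts_path))
  }
  samples <- readr::read_tsv(samples_path, col_types = readr::cols(
    sample_id = readr::col_character(), stage = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  validate_counts(counts, samples, stages = stages)
  list(counts = counts, samples = samples)
}

#' @rdname read_counts
#' @param counts,samples Count matrix and sample metadata tibbles.
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  validate_counts(counts, samples)
  readr::write_tsv(counts, counts_path, progress = FALSE)
  readr::write_tsv(samples, samples_path, progress = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Validate a count matrix and its sample metadata
#'
#' Enforces the container invariants: unique gene and sample ids,
#' non-negative integer counts, every count column described by the
#' metadata, and (optionally) stage labels drawn from a known vocabulary.
#' Violations raise a parse error naming the offense and the row.
#'
#' @param counts Tibble: `gene_id` plus one numeric column per sample.
#' @param samples Tibble: `sample_id`, `stage`, `replicate`.
#' @param stages Optional stage vocabulary.
#' @return Invisibly `TRUE`.
#' @export
validate_counts <- function(counts, samples, stages = NULL) {
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup) > 0) {
    stop_parse(sprintf("duplicate gene ids: %s",
                       paste(unique(dup), collapse = ", ")))
  }
  sample_cols <- setdiff(names(counts), "gene_id")
  if (anyDuplicated(sample_cols) > 0) stop_parse("duplicate sample columns")
  if (anyDuplicated(samples$sample_id) > 0) {
    stop_parse("duplicate sample ids in metadata")
  }
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing) > 0) {
    stop_parse(sprintf("sample columns missing from metadata: %s",
                       paste(missing, collapse = ", ")))
  }
  for (col in sample_cols) {
    v <- counts[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop_parse(sprintf(
        "column `%s`: non-integer or negative count in row %d (gene %s)",
        col, bad[1], counts$gene_id[bad[1]]
      ))
    }
  }
  if (!is.null(stages)) {
    bad <- which(!samples$stage %in% stages)
    if (length(bad) > 0) {
      stop_parse(sprintf(
        "unknown stage label `%s` in metadata row %d",
        samples$stage[bad[1]], bad[1]
      ))
    }
  }
  invisible(TRUE)
}

#' Read and write gene annotation tables
#'
#' Tab-delimited with columns `gene_id`, `gene_class` (one of OR, IR,
#' GR_olfactory, GR_nonantennal, TF, other), `sensilla`
#' (semicolon-separated sensillum labels, empty when not applicable) and
#' `notch_state` (On, Off or unknown).
#'
#' @param path File path.
#' @param annotation Annotation tibble.
#' @return `read_annotation()` returns a tibble; `write_annotation()`
#'   returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("gene_id", "gene_class")
  if (!all(req %in% names(ann))) {
    stop_parse(sprintf("%s: annotation requires columns %s", path,
                       paste(req, collapse = ", ")))
  }
  classes <- c("OR", "IR", "GR_olfactory", "GR_nonantennal", "TF", "other")
  bad <- which(!ann$gene_class %in% classes)
  if (length(bad) > 0) {
    stop_parse(sprintf("unknown gene class `%s` in row %d",
                       ann$gene_class[bad[1]], bad[1]))
  }
  if (anyDuplicated(ann$gene_id) > 0) stop_parse("duplicate gene ids in annotation")
  if (!"sensilla" %in% names(ann)) ann$sensilla <- NA_character_
  if (!"notch_state" %in% names(ann)) ann$notch_state <- "unknown"
  ann$notch_state[is.na(ann$notch_state)] <- "unknown"
  ann
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

# split a semicolon-separated sensilla field into a character vector
split_sensilla <- function(x) {
  out <- stringr::str_split(dplyr::coalesce(x, ""), ";")
  purrr::map(out, function(v) v[nzchar(v)])
}
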