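#' Median-of-ratios size factors
#'
#' Computes per-sample library size factors by the median-of-ratios
#' construction: the reference for each gene is the geometric mean of its
#' counts across samples, taken over genes with all-positive counts, and
#' a sample's factor is the median over those genes of count / reference.
#' Factors of a matrix whose samples are identical are all 1, and
#' multiplying one sample's counts by c multiplies its factor by c.
#'
#' This is an explicit re-implementation of the standard median-of-ratios
#' normalization so the pipeline is self-contained and auditable; it is
#' not a bit-exact clone of any differential-expression package.
#'
#' @param counts Count matrix tibble (`gene_id` + one column per sample).
#'
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
#'
#' @examples
#' cm <- tibble::tibble(gene_id = c("a", "b"), s1 = c(2L, 8L), s2 = c(4L, 16L))
#' compute_size_factors(cm)
compute_size_factors <- function(counts) {
  mat <- count_matrix(counts)
  keep <- rowSums(mat > 0) == ncol(mat)
  if (!any(keep)) {
    abort(paste0(
      "no gene has positive counts in every sample; size factors cannot ",
      "be computed by median-of-ratios. Consider a pseudo-reference over ",
      "nonzero entries instead."
    ))
  }
  ref <- exp(rowMeans(log(mat[keep, , drop = FALSE])))
  sf <- apply(mat[keep, , drop = FALSE] / ref, 2, median)
  tibble::tibble(sample_id = colnames(mat), size_factor = unname(sf))
}

#' Normalize a count matrix
#'
#' Divides each sample's counts by its size factor. The returned tibble
#' carries the size factors and the pseudocount used for later log2
#' transforms as attributes.
#'
#' @param counts Count matrix tibble.
#' @param size_factors Tibble (`sample_id`, `size_factor`); computed by
#'   [compute_size_factors()] when `NULL`.
#' @param pseudocount Pseudocount used by downstream log2 transforms.
#'
#' @return A tibble of normalized expression with the same shape as
#'   `counts`, with attributes `size_factors` and `pseudocount`.
#' @export
normalize_counts <- function(counts, size_factors = NULL, pseudocount = 1) {
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  mat <- count_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(mat), size_factors$sample_id)]
  if (anyNA(sf)) abort("size factors missing for some samples")
  if (any(sf <= 0)) abort("size factors must be strictly positive")
  norm <- sweep(mat, 2, sf, "/")
  out <- dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id),
                          tibble::as_tibble(norm))
  attr(out, "size_factors") <- size_factors
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("norm_counts", class(out))
  out
}

#' Per-stage mean expression profiles
#'
#' Averages normalized expression over the replicates of each stage and,
#' by default, log2-transforms the stage means after averaging using the
#' pseudocount recorded on the normalized matrix.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param samples Sample metadata tibble (`sample_id`, `stage`).
#' @param log2 Apply `log2(mean + pseudocount)`? Default `TRUE`.
#' @param stages Ordered stage labels; defaults to order of appearance in
#'   `samples`.
#'
#' @return A tibble with `gene_id` and one numeric column per stage, in
#'   stage order; attribute `log2` records the transform.
#' @export
stage_means <- function(norm, samples, log2 = TRUE, stages = unique(samples$stage)) {
  mat <- count_matrix(norm)
  missing <- setdiff(stages, samples$stage)
  if (length(missing) > 0) {
    abort(sprintf("stages without samples: %s", paste(missing, collapse = ", ")))
  }
  pc <- attr(norm, "pseudocount") %||% 1
  means <- vapply(stages, function(s) {
    cols <- samples$sample_id[samples$stage == s]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  means <- matrix(means, nrow = nrow(mat), dimnames = list(NULL, stages))
  if (log2) means <- log2(means + pc)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = norm$gene_id),
                          tibble::as_tibble(means))
  attr(out, "log2") <- log2
  attr(out, "stages") <- stages
  out
}

# tibble (gene_id + sample columns) -> numeric matrix with gene rownames
count_matrix <- function(counts) {
  cols <- setdiff(names(counts), "gene_id")
  mat <- as.matrix(counts[, cols])
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  mat
}
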