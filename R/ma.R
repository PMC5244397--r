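#' Pairwise stage comparison (MA statistics)
#'
#' Computes, for every gene, the mean expression (A) and log2 fold change
#' (M) between two stages on size-factor-normalized counts, together with
#' a p-value from a deliberately simple two-group negative-binomial test:
#' a Wald statistic on the log mean ratio with a method-of-moments common
#' dispersion per gene and a normal approximation. This test is a
#' clearly-labeled stand-in for a full shrinkage-based differential
#' expression model; with two replicates per group it demonstrates the
#' pipeline rather than providing calibrated inference.
#'
#' `M` is antisymmetric under swapping the stage pair; `A` is invariant.
#'
#' @param counts Raw count matrix tibble.
#' @param samples Sample metadata tibble.
#' @param stage_a,stage_b The two stages to compare (distinct).
#' @param size_factors Optional size-factor tibble; computed from
#'   `counts` when `NULL`.
#' @param pseudocount Pseudocount for the log transforms (default 1).
#' @param p_threshold Significance threshold on the p-value
#'   (default `1e-6`).
#'
#' @return A tibble of class `ma_comparison`: `gene_id`, `A` (mean of the
#'   two stages' log2 normalized means), `M` (log2 fold change, B over
#'   A), `p_value`, `significant`; the stage pair and threshold are
#'   attached as attributes.
#' @export
pairwise_ma <- function(counts, samples, stage_a, stage_b,
                        size_factors = NULL, pseudocount = 1,
                        p_threshold = 1e-6) {
  if (identical(stage_a, stage_b)) abort("the two stages must differ")
  for (s in c(stage_a, stage_b)) {
    if (!any(samples$stage == s)) abort(sprintf("no samples at stage %s", s))
  }
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  norm <- normalize_counts(counts, size_factors, pseudocount = pseudocount)
  mat <- count_matrix(norm)
  cols_a <- samples$sample_id[samples$stage == stage_a]
  cols_b <- samples$sample_id[samples$stage == stage_b]
  xa <- mat[, cols_a, drop = FALSE]
  xb <- mat[, cols_b, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  la <- log2(ma + pseudocount)
  lb <- log2(mb + pseudocount)

  # method-of-moments common NB dispersion per gene, pooled within groups:
  # alpha = (s2 - mu) / mu^2, floored at 0 (Poisson)
  alpha_grp <- function(x) {
    mu <- rowMeans(x)
    s2 <- apply(x, 1, var)
    ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  }
  n_a <- ncol(xa)
  n_b <- ncol(xb)
  alpha <- (alpha_grp(xa) + alpha_grp(xb)) / 2
  # delta-method variance of log(mean + pc) with NB per-sample variance
  vlog <- function(mu, n) (mu + alpha * mu^2) / n / (mu + pseudocount)^2
  se <- sqrt(vlog(ma, n_a) + vlog(mb, n_b))
  z <- (log(mb + pseudocount) - log(ma + pseudocount)) / se
  p <- 2 * pnorm(-abs(z))
  p[se == 0] <- 1   # identical flat genes: no evidence

  out <- tibble::tibble(
    gene_id = norm$gene_id,
    A = unname((la + lb) / 2),
    M = unname(lb - la),
    p_value = unname(p),
    significant = unname(p < p_threshold)
  )
  attr(out, "stage_a") <- stage_a
  attr(out, "stage_b") <- stage_b
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("ma_comparison", class(out))
  out
}

#' Top genes from a pairwise comparison
#'
#' Selects the `k` genes with either the largest absolute log2 fold
#' change or the smallest p-values, with deterministic ties broken by
#' gene id. These are the input gene lists a downstream functional
#' enrichment analysis would consume.
#'
#' @param comparison An `ma_comparison` tibble from [pairwise_ma()].
#' @param k Number of genes (default 500); must not exceed the gene
#'   count.
#' @param by `"fold_change"` (largest `|M|`) or `"p_value"` (ascending).
#'
#' @return A tibble of the selected rows, in selection order.
#' @export
top_k <- function(comparison, k = 500, by = c("fold_change", "p_value")) {
  by <- match.arg(by)
  if (k > nrow(comparison)) {
    abort(sprintf("k = %d exceeds the %d genes available", k, nrow(comparison)))
  }
  ord <- if (by == "fold_change") {
    order(-abs(comparison$M), comparison$gene_id)
  } else {
    order(comparison$p_value, comparison$gene_id)
  }
  comparison[ord[seq_len(k)], ]
}
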