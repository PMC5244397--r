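#' Sample-level principal component analysis
#'
#' Runs PCA with samples as observations on (optionally log2) normalized
#' expression, centered per transcript. Per-transcript contributions to a
#' component are reported as the Pearson correlation between the
#' transcript's expression vector across samples and the component's
#' score vector (transcripts with zero variance get `NA`).
#'
#' @param norm Normalized matrix from [normalize_counts()] (or any tibble
#'   of `gene_id` + sample columns).
#' @param log2 Work on `log2(value + pseudocount)`? Default `TRUE`.
#' @param pseudocount Pseudocount for the log transform; defaults to the
#'   one recorded on `norm`.
#'
#' @return An object of class `antdev_pca`: list with `scores` (tibble,
#'   one row per sample), `loadings` (tibble, per-transcript correlation
#'   with each component), `variance` (tibble: `component`,
#'   `variance_explained`), and the settings used. `tidy()` extracts the
#'   tables (`matrix = "scores"`, `"loadings"` or `"variance"`).
#' @export
run_pca <- function(norm, log2 = TRUE, pseudocount = NULL) {
  mat <- count_matrix(norm)   # genes x samples
  if (ncol(mat) < 2) abort("PCA requires at least 2 samples")
  pc <- pseudocount %||% attr(norm, "pseudocount") %||% 1
  if (log2) mat <- base::log2(mat + pc)
  x <- t(mat)                 # samples x transcripts
  keep_var <- apply(x, 2, var)
  if (all(keep_var == 0)) abort("constant matrix: no variance for PCA")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  comp_names <- paste0("PC", seq_along(fit$sdev))
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(x)),
    tibble::as_tibble(stats::setNames(as.data.frame(fit$x), comp_names))
  )
  # per-transcript correlation with each component's score vector
  cors <- suppressWarnings(cor(x, fit$x))
  loadings <- dplyr::bind_cols(
    tibble::tibble(gene_id = colnames(x)),
    tibble::as_tibble(stats::setNames(as.data.frame(cors), comp_names))
  )
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  out <- list(
    scores = scores, loadings = loadings,
    variance = tibble::tibble(component = comp_names,
                              variance_explained = ve),
    log2 = log2, pseudocount = pc, prcomp = fit
  )
  class(out) <- "antdev_pca"
  out
}

#' @export
print.antdev_pca <- function(x, ...) {
  cat(sprintf("<antdev_pca> %d samples, %d transcripts, log2 = %s\n",
              nrow(x$scores), nrow(x$loadings), x$log2))
  print(utils::head(x$variance, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.antdev_pca <- function(x, matrix = c("scores", "loadings", "variance"), ...) {
  matrix <- match.arg(matrix)
  x[[matrix]]
}

#' @exportS3Method generics::glance
glance.antdev_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_transcripts = nrow(x$loadings),
    n_components = nrow(x$variance),
    pc1_variance = x$variance$variance_explained[1]
  )
}

#' Transcripts contributing to a principal component
#'
#' Filters transcripts whose loading correlation with the chosen
#' component exceeds a threshold. The signed filter (`loading >
#' threshold`) is the default; `mode = "absolute"` filters on
#' `|loading| > threshold` instead, and the mode used is recorded in the
#' output.
#'
#' @param pca An `antdev_pca` object.
#' @param component Component index (1-based) or name ("PC1").
#' @param threshold Correlation threshold (default 0.1).
#' @param mode `"signed"` (default) or `"absolute"`.
#'
#' @return A tibble: `gene_id`, `loading`, `component`, `mode`, sorted by
#'   decreasing (absolute) loading then gene id.
#' @export
loading_contributors <- function(pca, component = 1, threshold = 0.1,
                                 mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  comp <- if (is.numeric(component)) paste0("PC", component) else component
  if (!comp %in% names(pca$loadings)) {
    abort(sprintf("component %s not computed", comp))
  }
  load <- pca$loadings[[comp]]
  keep <- if (mode == "signed") {
    !is.na(load) & load > threshold
  } else {
    !is.na(load) & abs(load) > threshold
  }
  tibble::tibble(gene_id = pca$loadings$gene_id[keep],
                 loading = load[keep], component = comp, mode = mode) |>
    dplyr::arrange(dplyr::desc(abs(.data$loading)), .data$gene_id)
}
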