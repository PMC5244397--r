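#' Hierarchical clustering of temporal expression profiles
#'
#' Clusters genes by the shape of their stage-mean expression profile
#' with agglomerative hierarchical clustering, emulating the grouping of
#' transcription factors by developmental expression pattern. The default
#' distance is `1 - Pearson correlation` between log2 stage-mean
#' profiles with average linkage, which groups by profile shape across
#' stages irrespective of overall expression level; Euclidean distance on
#' z-scored profiles is offered as an alternative. Profiles are sorted by
#' gene id before clustering so the result is invariant to input order
#' (ties in merge heights are broken by the deterministic input order).
#'
#' @param profiles Tibble from [stage_means()]: `gene_id` plus one
#'   numeric column per stage.
#' @param k Number of clusters to cut the tree into (default 11).
#' @param metric `"correlation"` (default) or `"euclidean"` (on z-scored
#'   profiles).
#' @param linkage Linkage method passed to [stats::hclust()].
#'
#' @return An object of class `profile_clusters`: a list with
#'   `assignments` (tibble: `gene_id`, `cluster`), `tree` (the hclust
#'   object), and the parameters used. `tidy()` returns the assignments,
#'   `glance()` the parameters and cluster sizes summary.
#' @export
#'
#' @examples
#' prof <- archetype_profiles_default(11) |>
#'   dplyr::mutate(gene_id = shape) |>
#'   dplyr::select(gene_id, `3L`, p8, p40, adult)
#' cl <- cluster_profiles(prof, k = 11)
#' table(tidy(cl)$cluster)
cluster_profiles <- function(profiles, k = 11,
                             metric = c("correlation", "euclidean"),
                             linkage = "average") {
  metric <- match.arg(metric)
  if (nrow(profiles) < k) {
    abort(sprintf("%d profiles cannot be cut into k = %d clusters",
                  nrow(profiles), k))
  }
  profiles <- dplyr::arrange(profiles, .data$gene_id)
  mat <- count_matrix(profiles)
  if (any(!is.finite(mat))) abort("profiles must be finite")
  d <- if (metric == "correlation") {
    cc <- suppressWarnings(cor(t(mat)))
    cc[!is.finite(cc)] <- 0  # zero-variance profiles have no defined shape
    as.dist(1 - cc)
  } else {
    z <- t(scale(t(mat)))
    z[!is.finite(z)] <- 0
    stats::dist(z)
  }
  tree <- hclust(d, method = linkage)
  cl <- cutree(tree, k = k)
  out <- list(
    assignments = tibble::tibble(gene_id = profiles$gene_id,
                                 cluster = unname(cl)),
    tree = tree,
    k = k, metric = metric, linkage = linkage
  )
  class(out) <- "profile_clusters"
  out
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("<profile_clusters> %d genes, k = %d, %s distance, %s linkage\n",
              nrow(x$assignments), x$k, x$metric, x$linkage))
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.profile_clusters <- function(x, ...) {
  dplyr::mutate(x$assignments, k = x$k, metric = x$metric,
                linkage = x$linkage)
}

#' @exportS3Method generics::glance
glance.profile_clusters <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  tibble::tibble(
    n_genes = nrow(x$assignments), k = x$k, metric = x$metric,
    linkage = x$linkage,
    min_cluster_size = as.integer(min(sizes)),
    max_cluster_size = as.integer(max(sizes))
  )
}

#' Export a clustering dendrogram in Newick format
#'
#' @param clusters A `profile_clusters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clusters, path) {
  phy <- ape::as.phylo(clusters$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Classify the temporal trend of an expression profile
#'
#' Labels each four-stage profile as expressed early, late, constant
#' (expressed throughout) or unclassified, with an explicit margin rule:
#' early if the mean of the two early stages exceeds the mean of the two
#' late stages by at least `delta` log2 units; late for the converse;
#' constant if the profile's range is at most `delta` and its maximum is
#' above the expression `floor`; otherwise unclassified. Labels are
#' mutually exclusive and exhaustive by construction.
#'
#' @param profiles Tibble from [stage_means()] with four stage columns in
#'   developmental order.
#' @param delta Margin in log2 units (default 1).
#' @param floor Minimum log2 expression for a constant call (default 1).
#'
#' @return A tibble: `gene_id`, `trend`, plus the rule parameters.
#' @export
#'
#' @examples
#' prof <- tibble::tibble(gene_id = c("flat", "early"),
#'                        `3L` = c(8, 8), p8 = c(8, 7),
#'                        p40 = c(8, 1), adult = c(8, 0))
#' classify_trend(prof)
classify_trend <- function(profiles, delta = 1, floor = 1) {
  mat <- count_matrix(profiles)
  if (ncol(mat) != 4) abort("trend classification expects a 4-stage profile")
  early_mean <- rowMeans(mat[, 1:2, drop = FALSE])
  late_mean <- rowMeans(mat[, 3:4, drop = FALSE])
  rng <- apply(mat, 1, max) - apply(mat, 1, min)
  peak <- apply(mat, 1, max)
  trend <- dplyr::case_when(
    early_mean >= late_mean + delta ~ "early",
    late_mean >= early_mean + delta ~ "late",
    rng <= delta & peak >= floor ~ "constant",
    TRUE ~ "unclassified"
  )
  tibble::tibble(gene_id = profiles$gene_id, trend = trend,
                 delta = delta, floor = floor)
}
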