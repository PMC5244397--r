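#' Fit the per-stage negative-binomial background null
#'
#' Calibrates, for each developmental stage, the count distribution
#' expected of a gene that is not truly expressed in the antenna, using
#' the raw counts of a negative-control gene family (by default the
#' non-antennal gustatory receptors, which should see only experimental
#' noise in antennal libraries). The null is a negative binomial with
#' mean `mu` and size `k` (variance `mu + mu^2/k`), fitted by the method
#' of moments on the pooled per-replicate control counts:
#' `mu = mean`, `k = mu^2 / (s^2 - mu)`. When the sample variance does
#' not exceed the mean the fit falls back to Poisson(`mu`) and is tagged.
#' A maximum-likelihood fit is available as `method = "mle"`.
#'
#' @param counts Raw count matrix tibble (`gene_id` + sample columns).
#'   Fits must use the same scale (raw or normalized) as the queries that
#'   will be tested against them; the scale is recorded on the result.
#' @param samples Sample metadata tibble.
#' @param annotation Gene annotation tibble with `gene_class`.
#' @param control_class Gene class forming the negative-control set.
#' @param method `"moments"` (default) or `"mle"`.
#' @param stages Stages to fit; default all stages present.
#' @param scale Tag recording the count scale; informational.
#'
#' @return A tibble of class `nb_background` with one row per stage:
#'   `stage`, `mu`, `size` (`Inf` for the Poisson fallback),
#'   `fit_method`, `n_obs`.
#' @export
#'
#' @examples
#' sim <- simulate_counts(sim_config(n_tfs = 11, n_other_genes = 0))
#' fit_background(sim$counts, sim$samples, sim$annotation)
fit_background <- function(counts, samples, annotation,
                           control_class = "GR_nonantennal",
                           method = c("moments", "mle"),
                           stages = unique(samples$stage),
                           scale = "raw") {
  method <- match.arg(method)
  ctrl_ids <- annotation$gene_id[annotation$gene_class %in% control_class]
  if (length(ctrl_ids) == 0) {
    abort(sprintf("no genes of class %s in the annotation",
                  paste(control_class, collapse = "/")))
  }
  mat <- count_matrix(counts)
  ctrl_ids <- intersect(rownames(mat), ctrl_ids)
  fits <- purrr::map(stages, function(s) {
    cols <- samples$sample_id[samples$stage == s]
    x <- as.vector(mat[ctrl_ids, cols, drop = FALSE])
    fit_nb_null(x, method = method, stage = s)
  })
  out <- dplyr::bind_rows(fits)
  attr(out, "control_class") <- control_class
  attr(out, "scale") <- scale
  attr(out, "replicates") <- stats::setNames(
    vapply(stages, function(s) sum(samples$stage == s), integer(1)), stages
  )
  class(out) <- c("nb_background", class(out))
  out
}

fit_nb_null <- function(x, method, stage) {
  n <- length(x)
  if (n < 2) {
    abort(sprintf("stage %s: fewer than 2 control observations; the null cannot be calibrated", stage))
  }
  m <- mean(x)
  if (m == 0) {
    abort(sprintf("stage %s: all control counts are zero; the null cannot be calibrated", stage))
  }
  s2 <- var(x)
  if (method == "mle" && s2 > m) {
    fit <- suppressWarnings(MASS::fitdistr(x, "negative binomial"))
    return(tibble::tibble(stage = stage, mu = unname(fit$estimate["mu"]),
                          size = unname(fit$estimate["size"]),
                          fit_method = "mle", n_obs = n))
  }
  if (s2 <= m) {
    return(tibble::tibble(stage = stage, mu = m, size = Inf,
                          fit_method = "poisson", n_obs = n))
  }
  tibble::tibble(stage = stage, mu = m, size = m^2 / (s2 - m),
                 fit_method = "moments", n_obs = n)
}

#' @exportS3Method generics::tidy
tidy.nb_background <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.nb_background <- function(x, ...) {
  tibble::tibble(
    n_stages = nrow(x),
    control_class = paste(attr(x, "control_class"), collapse = ";"),
    scale = attr(x, "scale") %||% "raw",
    n_poisson_fallback = sum(x$fit_method == "poisson")
  )
}

#' Upper-tail detection p-value under the background null
#'
#' Probability that a count at least as large as the one observed arises
#' from the background distribution: `p = P(X >= count)` under
#' NB(`mu`, `size`), or Poisson(`mu`) when `size = Inf`. `p(0) = 1`, and
#' `p` is strictly decreasing in the count wherever the pmf is positive.
#'
#' @param count Non-negative integer count(s).
#' @param mu Background mean (> 0).
#' @param size NB size parameter; `Inf` selects the Poisson null.
#'
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
#'
#' @examples
#' detection_pvalue(0, mu = 2, size = 1)    # 1
#' detection_pvalue(30, mu = 2, size = 1)   # far tail
detection_pvalue <- function(count, mu, size = Inf) {
  if (any(count < 0)) abort("counts must be non-negative")
  if (any(count != round(count))) abort("counts must be integers")
  if (any(mu <= 0)) abort("`mu` must be strictly positive")
  p <- if (all(is.finite(size))) {
    pnbinom(count - 1, mu = mu, size = size, lower.tail = FALSE)
  } else if (all(!is.finite(size))) {
    ppois(count - 1, lambda = mu, lower.tail = FALSE)
  } else {
    ifelse(is.finite(size),
           pnbinom(count - 1, mu = mu, size = pmax(size, 1e-300),
                   lower.tail = FALSE),
           ppois(count - 1, lambda = mu, lower.tail = FALSE))
  }
  p[count == 0] <- 1
  p
}

#' Call genes expressed above background
#'
#' Tests every query gene at every fitted stage against the stage's
#' background null and calls it expressed when the upper-tail p-value
#' falls below `alpha`. Two replicate rules are provided:
#' \describe{
#'   \item{`"sum"` (default)}{raw counts are summed over the stage's
#'     replicates and tested against the summed-count null, which for a
#'     sum of `r` independent NB(`mu`, `k`) draws is exactly
#'     NB(`r*mu`, `r*k`). Summing pools the replicates and maximizes
#'     power at two replicates.}
#'   \item{`"all"`}{each replicate is tested individually against the
#'     per-replicate null and the gene is called expressed only if every
#'     replicate is significant; the reported p-value is the maximum over
#'     replicates.}
#' }
#' No multiple-testing correction is applied by default;
#' `adjust = "BH"` or `"bonferroni"` apply [stats::p.adjust()] across the
#' whole gene-by-stage table and the call is then made on the adjusted
#' p-value.
#'
#' @param counts Raw count matrix tibble (same scale as the background).
#' @param samples Sample metadata tibble.
#' @param annotation Gene annotation tibble.
#' @param background `nb_background` from [fit_background()].
#' @param query_class Gene classes to test (default OR and IR).
#' @param query_ids Optional explicit gene ids; overrides `query_class`.
#'   Queries absent from the matrix are reported with `missing = TRUE`,
#'   not dropped.
#' @param alpha Significance level.
#' @param rule Replicate rule, `"sum"` or `"all"`.
#' @param adjust Multiple-testing adjustment: `"none"`, `"BH"` or
#'   `"bonferroni"`.
#'
#' @return A tibble sorted by stage then gene: `gene_id`, `stage`,
#'   `counts` (semicolon-joined per-replicate), `total_count`, `p_value`,
#'   `p_adjusted`, `expressed`, `alpha`, `rule`, `fit_method`, `missing`.
#' @export
call_expressed <- function(counts, samples, annotation, background,
                           query_class = c("OR", "IR"), query_ids = NULL,
                           alpha = 0.05, rule = c("sum", "all"),
                           adjust = c("none", "BH", "bonferroni")) {
  rule <- match.arg(rule)
  adjust <- match.arg(adjust)
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (is.null(query_ids)) {
    query_ids <- annotation$gene_id[annotation$gene_class %in% query_class]
  }
  mat <- count_matrix(counts)
  stages <- background$stage
  rows <- list()
  for (s in stages) {
    bg <- background[background$stage == s, ]
    cols <- samples$sample_id[samples$stage == s]
    r <- length(cols)
    for (g in query_ids) {
      present <- g %in% rownames(mat)
      if (!present) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = g, stage = s, counts = NA_character_,
          total_count = NA_real_, p_value = NA_real_, missing = TRUE
        )
        next
      }
      x <- mat[g, cols]
      p <- if (rule == "sum") {
        detection_pvalue(sum(x), mu = r * bg$mu, size = r * bg$size)
      } else {
        max(detection_pvalue(x, mu = bg$mu, size = bg$size))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = g, stage = s,
        counts = paste(x, collapse = ";"), total_count = sum(x),
        p_value = p, missing = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (adjust == "none") out$p_value else p.adjust(out$p_value, method = adjust)
  out$expressed <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out$alpha <- alpha
  out$rule <- rule
  out$adjust <- adjust
  out$fit_method <- background$fit_method[match(out$stage, background$stage)]
  out$stage <- factor(out$stage, levels = stages)
  dplyr::arrange(out, .data$stage, .data$gene_id) |>
    dplyr::mutate(stage = as.character(.data$stage)) |>
    dplyr::select("gene_id", "stage", "counts", "total_count", "p_value",
                  "p_adjusted", "expressed", "alpha", "rule", "adjust",
                  "fit_method", "missing")
}
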