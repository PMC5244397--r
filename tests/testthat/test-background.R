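make_ctrl_dataset <- function(x_by_stage) {
  # one control gene per observation, one replicate, stages as given
  stages <- names(x_by_stage)
  counts <- tibble::tibble(gene_id = sprintf("nGR%02d", seq_along(x_by_stage[[1]])))
  for (s in stages) counts[[paste0(s, "_r1")]] <- as.integer(x_by_stage[[s]])
  samples <- tibble::tibble(sample_id = paste0(stages, "_r1"),
                            stage = stages, replicate = 1L)
  ann <- tibble::tibble(gene_id = counts$gene_id,
                        gene_class = "GR_nonantennal",
                        sensilla = NA_character_, notch_state = "unknown")
  list(counts = counts, samples = samples, annotation = ann)
}

test_that("moment fit reproduces the hand-computed example", {
  d <- make_ctrl_dataset(list(p40 = c(0, 1, 2, 3, 4, 5)))
  bg <- fit_background(d$counts, d$samples, d$annotation)
  expect_equal(bg$mu, 2.5)
  # s^2 = 3.5, k = mu^2 / (s^2 - mu) = 6.25 / 1 = 6.25
  expect_equal(bg$size, 6.25)
  expect_equal(bg$fit_method, "moments")
  expect_equal(bg$n_obs, 6L)
})

test_that("degenerate variance falls back to Poisson and is tagged", {
  d <- make_ctrl_dataset(list(p40 = c(2, 2, 2, 2)))
  bg <- fit_background(d$counts, d$samples, d$annotation)
  expect_equal(bg$mu, 2)
  expect_equal(bg$size, Inf)
  expect_equal(bg$fit_method, "poisson")
})

test_that("uncalibratable nulls raise errors", {
  d <- make_ctrl_dataset(list(p40 = c(0, 0, 0, 0)))
  expect_error(fit_background(d$counts, d$samples, d$annotation),
               "all control counts are zero")
  d1 <- make_ctrl_dataset(list(p40 = 3))
  expect_error(fit_background(d1$counts, d1$samples, d1$annotation),
               "fewer than 2 control observations")
})

test_that("moment and MLE fits are consistent for the planted parameters", {
  mu <- 3; k <- 2
  fits <- list(moments = NULL, mle = NULL)
  set.seed(101)
  for (method in names(fits)) {
    est <- replicate(60, {
      d <- make_ctrl_dataset(list(p40 = rnbinom(500, mu = mu, size = k)))
      bg <- fit_background(d$counts, d$samples, d$annotation, method = method)
      c(bg$mu, bg$size)
    })
    est <- est[, is.finite(est[2, ]), drop = FALSE]
    expect_lt(abs(mean(est[1, ]) - mu) / mu, 0.1)
    expect_lt(abs(mean(est[2, ]) - k) / k, 0.1)
  }
})

test_that("detection p-values satisfy the boundary and tail properties", {
  expect_equal(detection_pvalue(0, mu = 5, size = 2), 1)
  expect_equal(detection_pvalue(0, mu = 0.3, size = Inf), 1)
  expect_lt(detection_pvalue(50, mu = 5, size = 50), 0.05)  # 10x mean, tight
  expect_error(detection_pvalue(-1, mu = 2), "non-negative")
  expect_error(detection_pvalue(2.5, mu = 2), "integers")
  # strictly decreasing wherever the pmf is positive
  p <- detection_pvalue(0:100, mu = 2, size = 1)
  expect_true(all(diff(p) < 0))
})

test_that("detection p-values match brute-force pmf summation", {
  for (mu in c(0.7, 2, 10)) {
    for (size in c(1, 5, Inf)) {
      counts <- c(0:5, 20, 57)
      expect_equal(detection_pvalue(counts, mu = mu, size = size),
                   vapply(counts, brute_tail, numeric(1), mu = mu, size = size),
                   tolerance = 1e-12)
    }
  }
  # spot value: the near-geometric case NB(mu = 2, k = 1), count 3
  expect_equal(detection_pvalue(3, mu = 2, size = 1), brute_tail(3, 2, 1),
               tolerance = 1e-12)
})

test_that("p-values are valid (conservative) under the exact null", {
  set.seed(77)
  x <- rnbinom(20000, mu = 4, size = 2)
  p <- detection_pvalue(x, mu = 4, size = 2)
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    mc <- 3 * sqrt(alpha * (1 - alpha) / length(x))
    expect_lte(mean(p <= alpha), alpha + mc)
  }
})

test_that("background-level receptors are rarely called, planted ones reliably", {
  set.seed(202)
  # type I: queries drawn from the background distribution itself
  d <- background_only_dataset(n_ctrl = 500, n_query = 2000, mu = 3, size = 2)
  bg <- fit_background(d$counts, d$samples, d$annotation)
  calls <- call_expressed(d$counts, d$samples, d$annotation, bg, alpha = 0.05)
  expect_lte(mean(calls$expressed), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))

  # power: planted receptors at 20x background, default generator conditions
  hits <- replicate(30, {
    cfg <- small_config(rng_seed = sample.int(1e6, 1))
    sim <- simulate_counts(cfg)
    fit <- fit_background(sim$counts, sim$samples, sim$annotation)
    cl <- call_expressed(sim$counts, sim$samples, sim$annotation, fit,
                         alpha = 0.05)
    tr <- sim$truth[match(cl$gene_id, sim$truth$gene_id), ]
    on <- match(tr$onset_stage, cfg$stages) <= match(cl$stage, cfg$stages)
    mean(cl$expressed[on])   # sensitivity at/after planted onset
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the replicate rules and alpha boundaries behave", {
  sim <- simulate_counts(small_config(rng_seed = 23L))
  bg <- fit_background(sim$counts, sim$samples, sim$annotation)
  none <- call_expressed(sim$counts, sim$samples, sim$annotation, bg, alpha = 0)
  expect_equal(sum(none$expressed), 0L)

  both <- call_expressed(sim$counts, sim$samples, sim$annotation, bg,
                         rule = "all")
  expect_true(all(both$rule == "all"))
  # the all-replicates rule is no more permissive than the sum rule's
  # per-replicate components: its p is a maximum over replicates
  expect_true(all(both$p_value >= 0 & both$p_value <= 1))

  # a query missing from the matrix is recorded, not dropped
  ann2 <- dplyr::add_row(sim$annotation, gene_id = "ghost", gene_class = "OR",
                         sensilla = NA, notch_state = "unknown")
  calls <- call_expressed(sim$counts, sim$samples, ann2, bg)
  ghost <- calls[calls$gene_id == "ghost", ]
  expect_equal(nrow(ghost), 4L)
  expect_true(all(ghost$missing))
  expect_true(all(!ghost$expressed))
})
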