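# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# upper-tail probability by term-by-term pmf summation via the NB/Poisson
# pmf recurrence, independent of pnbinom/ppois
brute_tail <- function(count, mu, size = Inf) {
  if (count == 0) return(1)
  if (is.finite(size)) {
    f <- (size / (size + mu))^size
    ratio <- function(x) (x + size) / (x + 1) * (mu / (mu + size))
  } else {
    f <- exp(-mu)
    ratio <- function(x) mu / (x + 1)
  }
  acc <- 0
  for (x in 0:(count - 1)) {
    acc <- acc + f
    f <- f * ratio(x)
  }
  max(0, 1 - acc)
}

# naive median-of-ratios on a plain matrix, written as explicit loops
naive_size_factors <- function(mat) {
  ref <- rep(NA_real_, nrow(mat))
  for (g in seq_len(nrow(mat))) {
    if (all(mat[g, ] > 0)) ref[g] <- prod(mat[g, ])^(1 / ncol(mat))
  }
  keep <- which(!is.na(ref))
  sf <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    sf[s] <- median(mat[keep, s] / ref[keep])
  }
  sf
}

# adjusted Rand index (closed form over the contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small count set: one stage, one replicate; n_ctrl control genes and
# n_query OR genes all drawn from NB(mu, size)
background_only_dataset <- function(n_ctrl, n_query, mu, size, stage = "p40") {
  counts <- tibble::tibble(
    gene_id = c(sprintf("ctrl%04d", seq_len(n_ctrl)),
                sprintf("or%05d", seq_len(n_query))),
    s1 = rnbinom(n_ctrl + n_query, mu = mu, size = size)
  )
  list(
    counts = counts,
    samples = tibble::tibble(sample_id = "s1", stage = stage, replicate = 1L),
    annotation = tibble::tibble(
      gene_id = counts$gene_id,
      gene_class = rep(c("GR_nonantennal", "OR"), c(n_ctrl, n_query)),
      sensilla = NA_character_, notch_state = "unknown"
    )
  )
}

# one-stage dataset whose control set is exactly n NB(mu, size) draws
make_fit_data <- function(n, mu, size, stage = "p40") {
  background_only_dataset(n_ctrl = n, n_query = 1, mu = mu, size = size,
                          stage = stage)
}

# quick simulation config for tests that do not need the full gene load
small_config <- function(...) {
  args <- list(n_tfs = 11, n_other_genes = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
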