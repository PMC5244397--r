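test_that("simulation is deterministic and stable under gene addition", {
  cfg <- small_config(n_control_genes = 5, replicates_per_stage = 1,
                      background_mean_per_stage = c(2, 2, 2, 2),
                      rng_seed = 7L)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  ctrl <- a$counts[startsWith(a$counts$gene_id, "nGR"), ]
  expect_equal(nrow(ctrl), 5)
  expect_true(all(as.matrix(ctrl[-1]) < 50))  # small background counts

  # adding filler genes must not reshuffle existing genes' streams
  cfg2 <- small_config(n_control_genes = 5, replicates_per_stage = 1,
                       background_mean_per_stage = c(2, 2, 2, 2),
                       rng_seed = 7L, n_other_genes = 10)
  c2 <- simulate_counts(cfg2)
  shared <- a$counts$gene_id
  expect_identical(a$counts,
                   c2$counts[match(shared, c2$counts$gene_id), ])
})

test_that("counts are non-negative integers and truth covers every gene once", {
  sim <- simulate_counts(small_config(rng_seed = 3L))
  mat <- as.matrix(sim$counts[-1])
  expect_true(all(mat >= 0))
  expect_true(all(mat == round(mat)))
  expect_identical(sort(sim$truth$gene_id), sort(sim$counts$gene_id))
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  # control genes are background everywhere: no onset
  ctrl <- sim$truth[sim$truth$gene_class == "GR_nonantennal", ]
  expect_true(all(ctrl$onset_stage == "none"))
})

test_that("adult receptor expression sits two orders of magnitude above p40", {
  sched <- tibble::tibble(
    gene_id = "OR01", gene_class = "OR", onset_stage = "p40",
    expressed_mean = 30, sensilla = "ab1", notch_state = "On"
  )
  cfg <- small_config(n_receptors = 1, onset_schedule = sched,
                      replicates_per_stage = 200, adult_fold_increase = 100,
                      rng_seed = 11L)
  sim <- simulate_counts(cfg)
  x <- as.numeric(sim$counts[sim$counts$gene_id == "OR01", -1])
  p40_mean <- mean(x[sim$samples$stage == "p40"])
  adult_mean <- mean(x[sim$samples$stage == "adult"])
  # expectations 30 and 3000; NB(3000, k=20) has sd ~672, n = 200
  se_adult <- 3 * sqrt((3000 + 3000^2 / 20) / 200)
  expect_lt(abs(adult_mean - 3000), se_adult)
  expect_lt(abs(p40_mean - 30), 3 * sqrt((30 + 30^2 / 20) / 200))
})

test_that("control-gene draws match NB moments within Monte-Carlo error", {
  cfg <- small_config(n_control_genes = 5000, replicates_per_stage = 2,
                      background_mean_per_stage = c(2, 3, 4, 6),
                      background_dispersion = 2, rng_seed = 5L)
  sim <- simulate_counts(cfg)
  cols <- sim$samples$sample_id[sim$samples$stage == "p8"]
  x <- as.vector(as.matrix(sim$counts[startsWith(sim$counts$gene_id, "nGR"), cols]))
  n <- length(x)
  expect_equal(n, 10000)
  mu <- 3; k <- 2
  v_theory <- mu + mu^2 / k
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v_theory / n))
  dev2 <- (x - mean(x))^2
  expect_lt(abs(var(x) - v_theory), 3 * sd(dev2) / sqrt(n))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(replicates_per_stage = 0), "replicates_per_stage")
  expect_error(sim_config(background_mean_per_stage = c(-1, 2, 3, 4)),
               "background_mean_per_stage")
  expect_error(sim_config(background_dispersion = 0), "background_dispersion")
  bad_sched <- default_onset_schedule()
  bad_sched$onset_stage[1] <- "p99"
  expect_error(sim_config(onset_schedule = bad_sched), "onset_schedule")
  expect_error(sim_config(library_size_factors = c(1, 2)),
               "library_size_factors")
})

test_that("library size factors scale NB means multiplicatively", {
  lsf <- c(1, 1, 1, 1, 1, 1, 4, 4)  # inflate the adult libraries
  cfg <- small_config(n_control_genes = 4000, library_size_factors = lsf,
                      rng_seed = 13L)
  sim <- simulate_counts(cfg)
  ctrl <- sim$counts[startsWith(sim$counts$gene_id, "nGR"), ]
  adult_cols <- sim$samples$sample_id[sim$samples$stage == "adult"]
  x <- as.vector(as.matrix(ctrl[adult_cols]))
  # background mean 6 scaled by factor 4 -> 24
  expect_lt(abs(mean(x) - 24), 3 * sqrt((24 + 24^2 / 2) / length(x)))
})

test_that("default archetype library is distinct and shaped as documented", {
  prof <- archetype_profiles_default(11)
  expect_equal(nrow(prof), 11)
  mat <- as.matrix(prof[, default_stages()])
  cc <- cor(t(mat))
  diag(cc) <- 0
  expect_lt(max(cc), 0.95)

  two <- archetype_profiles_default(2)
  m2 <- as.matrix(two[, default_stages()])
  expect_gt(m2[1, 1], m2[1, 4])  # early-declining
  expect_lt(m2[2, 1], m2[2, 4])  # late-rising

  expect_error(archetype_profiles_default(1), "k")
  expect_error(archetype_profiles_default(50), "library")
})

test_that("noise-free archetypes round-trip through the clustering", {
  prof <- archetype_profiles_default(11)
  profiles <- dplyr::bind_cols(tibble::tibble(gene_id = prof$shape),
                               prof[, default_stages()])
  cl <- cluster_profiles(profiles, k = 11)
  expect_equal(sort(unique(tidy(cl)$cluster)), 1:11)
  expect_equal(max(table(tidy(cl)$cluster)), 1L)  # all singletons
})
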