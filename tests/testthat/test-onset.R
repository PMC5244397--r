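stage_order <- c("3L", "p8", "p40", "adult")

mk_calls <- function(gene_id, expressed) {
  tibble::tibble(gene_id = gene_id, stage = stage_order,
                 expressed = expressed, missing = FALSE)
}

test_that("onset is the earliest expressed stage, or none", {
  calls <- dplyr::bind_rows(
    mk_calls("a", c(FALSE, FALSE, TRUE, TRUE)),
    mk_calls("b", c(FALSE, FALSE, FALSE, FALSE)),
    mk_calls("c", c(TRUE, FALSE, TRUE, TRUE))   # onset = first TRUE
  )
  tab <- onset_table(calls, stage_order)
  expect_equal(tab$onset_stage[tab$gene_id == "a"], "p40")
  expect_equal(tab$stages_expressed[tab$gene_id == "a"], "p40;adult")
  expect_equal(tab$onset_stage[tab$gene_id == "b"], "none")
  expect_equal(tab$onset_stage[tab$gene_id == "c"], "3L")
})

test_that("a missing stage is an error naming the gene and stage", {
  calls <- mk_calls("a", c(FALSE, FALSE, TRUE, TRUE))[-2, ]
  expect_error(onset_table(calls, stage_order), "a@p8")
})

test_that("stricter alpha can only delay or remove onsets", {
  sim <- simulate_counts(small_config(rng_seed = 31L))
  bg <- fit_background(sim$counts, sim$samples, sim$annotation)
  loose <- onset_table(call_expressed(sim$counts, sim$samples, sim$annotation,
                                      bg, alpha = 0.05), stage_order)
  strict <- onset_table(call_expressed(sim$counts, sim$samples, sim$annotation,
                                       bg, alpha = 1e-4), stage_order)
  idx <- function(s) ifelse(s == "none", length(stage_order) + 1L,
                            match(s, stage_order))
  m <- match(loose$gene_id, strict$gene_id)
  expect_true(all(idx(strict$onset_stage[m]) >= idx(loose$onset_stage)))
})

test_that("the sensillum report counts expressed members and typicality", {
  ann <- tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    gene_class = "OR",
    sensilla = c("ab1", "ab1", "ab1", "ab2"),
    notch_state = c("On", "Off", "Off", "unknown")
  )
  onsets <- tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    onset_stage = c("p40", "none", "none", "none"),
    stages_expressed = c("p40;adult", "", "", "adult"),
    missing = FALSE
  )
  rep_ <- sensillum_report(onsets, ann, "p40")
  ab1 <- rep_[rep_$sensillum == "ab1", ]
  expect_equal(ab1$n_members, 3L)
  expect_equal(ab1$n_expressed, 1L)
  expect_equal(ab1$expressed_members, "A")
  expect_true(ab1$typical)
  expect_equal(attr(rep_, "typicality"), 0.5)  # ab1 typical, ab2 empty

  # empty focal stage: all zero, typicality 0
  rep0 <- sensillum_report(onsets, ann, "3L")
  expect_true(all(rep0$n_expressed == 0))
  expect_equal(attr(rep0, "typicality"), 0)
})

test_that("multi-sensillum receptors count once per housing, once per gene", {
  ann <- tibble::tibble(
    gene_id = c("IRx", "Z"),
    gene_class = c("IR", "OR"),
    sensilla = c("ac2;ac3", "ac3"),
    notch_state = c("unknown", "On")
  )
  onsets <- tibble::tibble(
    gene_id = c("IRx", "Z"), onset_stage = "p8",
    stages_expressed = "p8;p40", missing = FALSE
  )
  rep_ <- sensillum_report(onsets, ann, "p40")
  expect_equal(rep_$n_expressed[rep_$sensillum == "ac2"], 1L)
  expect_equal(rep_$n_expressed[rep_$sensillum == "ac3"], 2L)
  tal <- notch_tally(onsets, ann, "p40")
  expect_equal(tal$n_expressed, 2L)   # IRx counted once despite two sensilla
  expect_equal(tal$n_notch_on, 1L)
  expect_equal(tal$n_unknown, 1L)
})

test_that("notch tallies partition the expressed set and ignore order", {
  ann <- tibble::tibble(gene_id = c("a", "b", "c"), gene_class = "OR",
                        sensilla = "ab1",
                        notch_state = c("On", "On", "Off"))
  onsets <- tibble::tibble(gene_id = c("a", "b", "c"), onset_stage = "p40",
                           stages_expressed = "p40", missing = FALSE)
  tal <- notch_tally(onsets, ann, "p40")
  expect_equal(c(tal$n_notch_on, tal$n_notch_off, tal$n_unknown), c(2L, 1L, 0L))
  expect_equal(tal$n_notch_on + tal$n_notch_off + tal$n_unknown,
               tal$n_expressed)
  shuffled <- notch_tally(onsets[c(3, 1, 2), ], ann[c(2, 3, 1), ], "p40")
  expect_equal(tal, shuffled)
})

test_that("the default simulation's planted truth reproduces the study tallies", {
  cfg <- small_config(rng_seed = 1L)
  sim <- simulate_counts(cfg)
  truth_onsets <- sim$truth |>
    dplyr::filter(.data$gene_class %in% c("OR", "IR")) |>
    dplyr::mutate(
      stages_expressed = purrr::map_chr(.data$onset_stage, function(on) {
        i <- match(on, cfg$stages)
        paste(cfg$stages[seq(i, length(cfg$stages))], collapse = ";")
      }),
      missing = FALSE
    )
  tal <- notch_tally(truth_onsets, sim$annotation, "p40")
  expect_equal(tal$n_expressed, 21L)
  expect_equal(tal$n_notch_on, 9L)
  expect_equal(tal$n_notch_off, 8L)
  expect_equal(tal$n_unknown, 4L)
})

test_that("a planted one-early-receptor-per-sensillum design yields its typicality", {
  # 20 sensilla, 18 with exactly one member expressed at the focal stage
  ann <- tibble::tibble(
    gene_id = sprintf("r%02d", 1:40),
    gene_class = "OR",
    sensilla = rep(sprintf("s%02d", 1:20), each = 2),
    notch_state = "unknown"
  )
  expressed <- c(sprintf("r%02d", seq(1, 35, by = 2)),  # first member of each
                 "r04")                                  # second of sensillum 2
  onsets <- tibble::tibble(
    gene_id = ann$gene_id,
    onset_stage = ifelse(ann$gene_id %in% expressed, "p40", "none"),
    stages_expressed = ifelse(ann$gene_id %in% expressed, "p40", ""),
    missing = FALSE
  )
  rep_ <- sensillum_report(onsets, ann, "p40")
  expect_equal(sum(rep_$multi), 1L)   # s02 carries two expressed members
  expect_equal(attr(rep_, "typicality"), 17 / 20)
})

test_that("unmapped receptors produce a warning, not a failure", {
  ann <- tibble::tibble(gene_id = "a", gene_class = "OR",
                        sensilla = NA_character_, notch_state = "On")
  onsets <- tibble::tibble(gene_id = "a", onset_stage = "p40",
                           stages_expressed = "p40", missing = FALSE)
  expect_warning(rep_ <- sensillum_report(onsets, ann, "p40"), "a")
  expect_equal(attr(rep_, "unmapped"), "a")
})
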