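# antdev

Developmental transcriptome analysis of the Drosophila antenna: when
does each olfactory receptor turn on, and which transcription factors
accompany each phase of ORN specification?

The antenna is profiled by bulk RNA-seq at four stages — third-instar
larva (3L, prepatterning), 8 h after puparium formation (p8, precursor
selection), 40 h (p40, neurogenesis) and adult — with two replicates
each. Receptor transcripts at p40 sit barely above sequencing noise
(~100-fold below adult levels), so "expressed" cannot be read off the
counts directly. `antdev` implements the decision as a calibrated test
plus the pipeline around it:

* **Background null** — for each stage, a negative binomial
  NB(μ, k), Var = μ + μ²/k, is fitted by the method of moments to the
  raw counts of non-antennal gustatory receptors (a gene family not
  expressed in the antenna, so its counts are pure noise). A query gene
  with summed stage count *c* is called expressed when the upper-tail
  probability P(X ≥ c) under the summed-replicate null NB(rμ, rk)
  falls below α. Poisson fallback, MLE fitting, an all-replicates rule,
  and BH/Bonferroni adjustment are available and tagged in the output.
* **Onset and sensilla** — earliest expressed stage per receptor,
  per-sensillum tallies at a focal stage (typicality = fraction of
  sensilla with exactly one expressed receptor), and Notch-On/Off fate
  counts.
* **Temporal profiles** — log2 stage-mean profiles, hierarchical
  clustering (1 − Pearson correlation, average linkage, cut at k = 11
  by default) with Newick dendrogram export, and early/late/constant
  trend labels.
* **Sample structure** — PCA with per-transcript loading correlations
  and a `> 0.1` contributor filter, MA statistics per stage pair with a
  simple (clearly labeled) two-group NB Wald stand-in test, and top-500
  gene lists by fold change or p-value.
* **Simulator** — a negative-binomial generator that emulates the
  study design (62 receptors with planted onsets, ~100× adult increase,
  400 TFs from 11 planted cluster archetypes, 50 negative-control GRs)
  with per-gene RNG streams for full reproducibility.

All functions take tibbles first and return tibbles; fitted objects
have `tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(antdev)

sim <- simulate_counts(sim_config(rng_seed = 42))
bg  <- fit_background(sim$counts, sim$samples, sim$annotation)
tidy(bg)
#> # A tibble: 4 × 5
#>   stage    mu  size fit_method n_obs
#>   <chr> <dbl> <dbl> <chr>      <int>
#> 1 3L     2.24  1.95 moments      100
#> 2 p8     2.64  1.46 moments      100
#> 3 p40    4.18  1.21 moments      100
#> 4 adult  6.1   2.20 moments      100
```

Each row is one stage's noise distribution, estimated from 100 control
observations (50 non-antennal GRs × 2 replicates): mean noise of a few
reads, strongly overdispersed (size ~1–2). Receptor onsets are then
called with family-wise control (one false early call would corrupt a
receptor's onset):

```r
calls  <- call_expressed(sim$counts, sim$samples, sim$annotation, bg,
                         alpha = 0.01, adjust = "bonferroni")
onsets <- onset_table(calls, unique(sim$samples$stage))
dplyr::count(onsets, onset_stage)
#> # A tibble: 4 × 2
#>   onset_stage     n
#>   <chr>       <int>
#> 1 3L              3
#> 2 adult          41
#> 3 p40            17
#> 4 p8              1

notch_tally(onsets, sim$annotation, "p40")
#> # A tibble: 1 × 5
#>   focal_stage n_expressed n_notch_on n_notch_off n_unknown
#>   <chr>             <int>      <int>       <int>     <int>
#> 1 p40                  20          8           8         4
```

The planted truth has 21 receptors expressed by p40 (17 ORs split
9 Notch-On / 8 Notch-Off, plus 4 coeloconic-group receptors); at this
seed the pipeline recovers 20 of them, missing one marginal receptor —
the kind of near-threshold loss the detection test is designed to trade
against false positives. TF clustering and PCA:

```r
norm <- normalize_counts(sim$counts)
prof <- stage_means(norm, sim$samples)
cl   <- cluster_profiles(prof[startsWith(prof$gene_id, "TF"), ], k = 11)
glance(cl)
#> # A tibble: 1 × 6
#>   n_genes     k metric      linkage min_cluster_size max_cluster_size
#>     <int> <dbl> <chr>       <chr>              <int>            <int>
#> 1     400    11 correlation average               36               37

head(tidy(run_pca(norm), "variance"), 2)
#> # A tibble: 2 × 2
#>   component variance_explained
#>   <chr>                  <dbl>
#> 1 PC1                    0.614
#> 2 PC2                    0.272
```

The 400 simulated TFs fall cleanly back into their 11 planted
archetypes, and PC1 carries the dominant developmental axis.
`run_pipeline(sim_config(), out_dir, seed = 1)` runs every stage and
writes deterministic TSVs; a thin CLI over the same functions lives at
`inst/cli/antdev.R`. The methods vignette
(`vignettes/antdev-methods.Rmd`) documents the model, the simulator's
assumptions, and every tunable parameter.

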