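# segscreen

Analysis toolkit for multi-parameter ordinal phenotype screens of the kind
used to find small molecules perturbing embryonic segmentation in zebrafish.
Such screens test a compound library across concentrations (2/10/50 µM) and
genetic backgrounds (two wild-type replicates plus sensitized segmentation
clock mutants, *her1* and *hes6*), scoring every treatment on a
12-parameter **phenotypic vector**: six general-morphology parameters
(E, H, Y, D, A, T) and six segmentation parameters (S, BD, AD, TD, PD, BS),
each an integer 0 (like untreated control) to 3 (strong difference).

The package is for screeners and analysts who have (or want to simulate)
such score tables and need the downstream statistics:

* **Data model & I/O** — validated TSV score tables, embryo-level consensus
  calling ("phenotype shown by ≥ 3 of 5 embryos"), removal of lethal and
  unscored treatments, design-completeness validation with JSON reports.
* **Replicate QC** — pointwise Pearson correlation and normalized Hamming
  distance between replicate experiments.
* **Hit selection** — per-treatment statistics and two rankings: the
  modified strictly standardized mean difference

  SSMD = (x̄_seg − x̄_morph) / √(s²_seg + s²_morph)

  with the standard exclusions (x̄_seg < 0.2, x̄_morph > 2), and the plain
  mean difference Δ = x̄_seg − x̄_morph (kept when x̄_morph < 2, Δ > 0);
  compound-level hit calls with a wild-type reproducibility filter,
  genotype classes (her1-only / her1-enhanced / hes6-suppressed / …) and
  concentration-masking summaries.
* **Clustering** — correlation-distance (1 − r) average-linkage clustering
  of phenotypic vectors with deterministic tie-breaks, flat clusters at a
  correlation cutoff (default 0.6), cluster characterization (first-class /
  secondary-tail / seg-plus-morph), random pulse-retest candidate
  selection, Newick export.
* **Profiles & networks** — lethal / any-defect / no-defect concentration
  profiles with a two-way ANOVA on lethal counts, and bipartite
  compound–parameter networks exported as Cytoscape-readable SIF/GraphML.
* **Synthetic screens** — a fully seeded generator planting known hit
  classes, dose windows, genotype modifiers and lethality, with ground
  truth for recovery testing.

## Worked example

```r
library(segscreen)

sim    <- simulate_screen(sim_config(seed = 1))   # 243 x 3 x 4 = 2916 treatments
screen <- sim$table

qc_report(screen)
#> <qc_report> wt_A vs wt_B
#>   r = 0.962 (p = 0, n = 8016)
#>   Hamming = 0.023 (n = 8016)

hits <- call_hits(screen)
sum(hits$is_hit)
#> [1] 25
table(hits$genotype_class[hits$is_hit])
#>   her1_enhanced       her1_only hes6_suppressed           mixed
#>               4               7              10               4
concentration_masking(hits)$fraction_single
#> [1] 0.6

# every called hit is a planted direct-segmentation compound
mean(hits$compound_id[hits$is_hit] %in% truth_hits(sim$truth))
#> [1] 1

head(rank_by_ssmd(screen)[, c("compound_id", "concentration_uM",
                              "experiment", "ssmd", "mean_diff")], 5)
#>   compound_id concentration_uM experiment     ssmd mean_diff
#> 1        C188               50       her1 1.290994 0.6666667
#> 2        C039               10       her1 1.224745 1.5000000
#> 3        C039               10       wt_B 1.224745 1.5000000
#> 4        C039               50       her1 1.224745 1.5000000
#> 5        C112               10       her1 1.224745 1.5000000
```

Reading the numbers: the replicate QC shows the synthetic wild-type
replicates agree closely (noise is the only difference between them). Of
243 compounds, 25 are called hits, all of them planted direct-segmentation
compounds; 7 qualify only in the sensitized *her1* mutant (the enhancer
module's contribution), 10 are suppressed in *hes6*, and 60% of hits are
active at a single concentration — the dose-masking signature. The SSMD
ranking puts segmentation-specific treatments (positive SSMD, zero
morphology scores) at the top.

Clustering and network export:

```r
d    <- distance_matrix(treatment_vectors(screen))
dend <- average_linkage(d)
cl   <- cut_clusters(dend, cutoff_correlation = 0.6)
prof <- cluster_profiles(cl, screen)
candidates <- select_pulse_candidates(cl, prof, "seg_plus_morph",
                                      k = 10, seed = 1)

net <- build_network(screen, experiment = "wt_A", concentration = 10)
export_network(net, "wtA_10uM.graphml", "graphml")
```

## Command line

A CLI wrapping the pipeline ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "segscreen.R", package = "segscreen"))')
Rscript "$CLI" simulate --seed 1 --out out/
Rscript "$CLI" qc --table out/screen.tsv --a wt_A --b wt_B --out out/qc.json
Rscript "$CLI" rank --table out/screen.tsv --method ssmd --out out/ranking.tsv
Rscript "$CLI" hits --table out/screen.tsv --out out/hits.tsv
Rscript "$CLI" cluster --table out/screen.tsv --cutoff 0.6 --out out/clusters
```

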