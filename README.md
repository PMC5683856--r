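# biclustsig

Bicluster-derived gene signatures and dose-effect enrichment for
toxicogenomics compendia.

## What it does

Exposure studies (nanomaterials, particulates, drugs) accumulate as
gene-by-condition log2 fold-change matrices across many experiments and
platforms. `biclustsig` is for researchers who want to (1) mine such a
compendium for *gene signatures* — groups of genes coherently 2-fold up- or
down-regulated across a group of exposure conditions — and (2) test whether
those signatures respond to dose in a new multi-dose experiment.

**Discovery phase.** Normalized log2 intensities are collapsed by median
(technical replicate probes → gene symbols, biological replicates →
conditions), standardized to matched controls as log2 fold changes, and
merged across studies on gene symbol. The matrix is binarized at a 2-fold
threshold, separately for up- and down-regulation, and each binary matrix is
searched exhaustively for **inclusion-maximal all-ones biclusters** (the
Bimax model): submatrices `(G, C)` with every cell 1 such that no gene or
condition can be added without breaking the pattern, subject to size
constraints (defaults `|G| >= 15`, `5 <= |C| <= 15`).

**Application phase.** In a new experiment with dose groups
`d = 1, ..., k`, each gene's dose effect is the one-way ANOVA statistic

    F_g = (SSB_g / (k - 1)) / (SSW_g / (N - k)),

dose treated as an unordered factor. A gene set `S` is enriched when its
`log2 F` values are skewed towards larger values than the population's,
assessed by the Welch unequal-variance t-test of `mean(log2 F | S)` against
`mean(log2 F | all genes)` with Welch–Satterthwaite degrees of freedom
(one-sided "greater" by default).

A synthetic-data module generates multi-study compendia with planted
biclusters and multi-dose experiments with planted responsive gene sets, so
the whole pipeline is testable without any download. Heatmap presentation
(per-group medians ordered by average linkage on 1 − Spearman ρ), TSV/GMT/
JSON readers and writers, and a subcommand CLI round out the package.

## Worked example

```r
library(biclustsig)

genes <- sprintf("g%04d", 1:500); conds <- sprintf("study1|cond%02d", 1:20)
cfg <- sim_config(500, 20, noise_sd = 0.2, seed = 42, planted = list(
  planted_bicluster(genes[1:30],  conds[1:8],  "up"),
  planted_bicluster(genes[31:50], conds[9:14], "up"),
  planted_bicluster(genes[51:75], conds[15:19], "down", effect_mean = -2)
))
comp <- simulate_compendium(cfg)

biclusters <- run_discovery(comp$fc, min_rows = 15, min_cols = 5, max_cols = 15)
biclusters
#> # A tibble: 3 × 6
#>   bicluster direction n_genes n_conditions genes      conditions
#>       <int> <chr>       <int>        <int> <list>     <list>
#> 1         1 up             30            8 <chr [30]> <chr [8]>
#> 2         2 up             20            6 <chr [20]> <chr [6]>
#> 3         3 down           25            5 <chr [25]> <chr [5]>
```

All three planted signatures are recovered exactly. Now expose the first
signature to a dose response (vehicle + 18/54/162 µg, 3 replicates, mean
log2 shifts 0/1/2/3) and score all discovered signatures:

```r
sim <- simulate_dose_experiment(500, dose_design(seed = 42),
                                universe = rownames(comp$fc$values),
                                responsive_genes = comp$truth$genes[[1]])
enrichment_report(sim$experiment, biclusters_as_gene_sets(biclusters))
#>   set_name          t_statistic    df   p_value mean_in_set mean_background
#> 1 bicluster_01_up        25.33  49.07 3.904e-30      4.566         -0.02202
#> 2 bicluster_02_up        -0.62  22.12 7.294e-01     -0.223         -0.02202
#> 3 bicluster_03_down      -1.33  28.80 9.030e-01     -0.415         -0.02202
```

The dosed signature's mean log2 F sits 4.6 log2 units above the all-gene
background (`t = 25.3`, one-sided `p ≈ 4e-30`); the two unexposed
signatures stay at the background level with p ≫ 0.05. `autoplot()` on the
report draws the −log10 p bar chart, and
`plot_set_heatmap(sim$experiment, comp$truth$genes[[1]])` shows the
clustered per-dose medians for the responsive set.

A command-line interface wraps the same functions
(`inst/cli/biclustsig simulate|preprocess|binarize|bicluster|enrich|heatmap|pipeline`),
and `run_pipeline()` executes the whole two-phase workflow from a YAML
config with provenance sidecars and byte-reproducible outputs.

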