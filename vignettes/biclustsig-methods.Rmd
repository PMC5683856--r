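---
title: "Methods: bicluster-derived gene signatures and dose-effect enrichment"
author: "biclustsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bicluster-derived gene signatures and dose-effect enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biclustsig)
```

## The workflow

`biclustsig` implements a two-phase workflow for toxicogenomics compendia.

**Discovery.** Several transcriptomics studies, each a gene/probe-by-sample
matrix of normalized log2 intensities with per-sample metadata, are reduced
to a single gene-by-condition matrix of log2 fold changes versus matched
controls, binarized at a 2-fold threshold (separately for up- and
down-regulation), and mined for *inclusion-maximal all-ones biclusters*:
groups of genes that respond coherently across a group of exposure
conditions. Each bicluster's gene list is a candidate signature.

**Application.** In a new multi-dose exposure experiment, each gene's dose
effect is summarized by the overall one-way ANOVA F statistic with dose as
an unordered factor. A gene set is called enriched when its log2 F values
are skewed towards larger values than the gene population's: a Welch
two-sample t-test compares the mean log2 F inside the set with the mean
over all measured genes.

The package starts from already-normalized log2 intensities (or synthetic
data); platform-specific raw-array normalization (LOWESS, RMA, quantile) is
deliberately out of scope, as is fetching public repositories or calling
annotation web services — gene lists are exported in paste-ready plain text
instead.

## Preprocessing

All replicate collapsing uses the **median** — of technical replicate
probes mapping to a gene symbol, then of biological replicate samples
within a condition. The median is robust to single outlying spots or
animals, which matters for small-n designs. Conventions the package fixes
where the procedure is otherwise underdetermined:

* **Even counts**: the median of an even number of values is the mean of
  the two middle values (the standard sample median).
* **Multi-mapping probes**: a probe annotated with several gene symbols
  contributes its value to each symbol before the per-gene median; the
  count of such probes is reported. Probes with no symbol are dropped and
  counted.
* **Control matching**: the "appropriate control" for a condition is
  study-specific and cannot be inferred in general, so `fold_change_vs_control()`
  takes an explicit `control_map`; when a study has exactly one
  control condition (per the `is_control` metadata flag) it is matched
  automatically. A condition with no resolvable control is a hard error
  naming the condition — silently dropping it would bias the compendium.
* **Merging studies**: gene symbols are matched case-sensitively (an
  opt-in `fold_case` flag uppercases first) and the merged universe is the
  **intersection** of the studies' symbols, so every condition column is
  complete; a `genes = "union"` flag keeps all symbols with `NA` where a
  study did not measure a gene, but binarization refuses `NA`s, so the
  union path is for inspection rather than discovery. Merged columns are
  sorted lexicographically by (study, condition) so that downstream
  binarization and bicluster output are reproducible regardless of input
  order.
* **Missing values** are rejected at ingestion; imputation is the caller's
  responsibility and must be explicit.

## Binarization

A cell of the up-matrix is 1 iff `log2FC >= threshold`, of the down-matrix
iff `log2FC <= -threshold`; the default threshold of 1 log2 unit is a
2-fold change. The boundary is **inclusive**: a gene exactly 2-fold up *is*
2-fold up-regulated. Two consequences are enforced as invariants and
tested: for any positive threshold the up- and down-matrices are
elementwise disjoint, and raising the threshold only turns 1s into 0s.

## The bicluster model and its enumeration

A bicluster is a pair (row set, column set) whose submatrix is all ones and
which is *inclusion-maximal*: no further gene is 1 on all the bicluster's
conditions and no further condition is 1 on all its genes. Maximality is
judged on the unconstrained matrix; the size constraints (defaults: at
least 15 genes, 5–15 conditions) are then applied as a filter. In
particular a maximal bicluster wider than `max_cols` is **discarded, not
truncated** — truncating would emit non-maximal, arbitrarily chosen
sub-biclusters and make the output ill-defined.

The enumeration is a Close-by-One search over column sets: starting from
the full row set, columns are added in index order, the row extent is
intersected with the new column, and the column closure (all columns
all-ones on that extent) is computed; a canonicity test — the closure may
not add any column with a smaller index than the one just added — ensures
every closed pair is generated exactly once. This yields exactly the
inclusion-maximal all-ones submatrices with no duplicate emission and no
memo table, and the recursion depth is bounded by the number of columns.
We chose this formulation over the divide-and-conquer with row-set
memoization usually associated with the Bimax name because its correctness
argument is a two-line induction and duplicates are impossible by
construction; the output set is identical, which the test suite verifies
against a brute-force column-subset enumeration on hundreds of random
matrices.

Because the number of maximal biclusters can grow exponentially in
pathological dense matrices, the search carries a configurable cap
(`max_biclusters`, default 100 000); exceeding it is a hard error, never a
silent truncation. Overlapping biclusters are inherent to the model and
all reported. Output order is deterministic: area descending, ties broken
lexicographically on the sorted gene then condition labels.

## Dose-effect enrichment

Per gene, the one-way ANOVA decomposition over dose groups gives
`F = (SSB / (k - 1)) / (SSW / (N - k))`. Dose is treated as an **unordered
factor** — the overall F captures any dose-dependent profile, monotone or
not, which is why the synthetic designs are free to use non-monotone
per-dose shifts. No trend test is attempted. Degenerate genes are resolved
explicitly: no between-group signal (`SSB = 0`, including fully constant
genes) gives `F = 0`; perfect separation (`SSW = 0` with signal) gives
`F = Inf`. Neither has a finite `log2 F`, so both are excluded from the
enrichment groups and counted in `n_excluded_nonfinite`.

The enrichment test is competitive: group A is the set's log2 F values,
group B the log2 F of **all measured genes, set members included** — the
background is literally "all genes"; a set-excluded background is
available behind `background = "rest"`. The Welch statistic
`t = (mean_A - mean_B) / sqrt(s2_A/n_A + s2_B/n_B)` with
Welch–Satterthwaite degrees of freedom makes no equal-variance assumption,
which matters because a responsive set's log2 F spread differs from the
population's. The default alternative is one-sided `greater`, because
enrichment is defined as F skewed towards *larger* values; `two.sided` is
available since a depletion question is occasionally of interest. Raw
p-values are reported with no multiple-testing correction by default
(each experiment/time point is a separate question); `adjust = TRUE` adds
a clearly-labelled Benjamini–Hochberg column. Time points are analyzed as
separate experiments.

The Welch computation is authored in closed form inside the package and is
checked in the tests against `stats::t.test` to 1e-10 in t and 1e-8 in p
on a thousand random group pairs; the vectorized per-gene F is checked
against `stats::oneway.test` and against the `t^2` identity in the
two-group pooled case.

## Heatmap ordering

For presentation, biological replicates are collapsed to per-group medians
and the groups (and genes, when they have rank variance) are ordered by
agglomerative clustering with **average (UPGMA) linkage** on the
dissimilarity `1 - rho`, `rho` the Spearman rank correlation with the
midrank convention for ties. Spearman makes the ordering invariant to any
strictly increasing transform of an item; a constant item has no rank
variance and is rejected by name. Items are sorted lexicographically
before clustering so that tie-breaking inside `stats::hclust` is
deterministic. The tested artifact is the ordered matrix and the merge
history (heights are non-decreasing for UPGMA on a proper dissimilarity);
the ggplot heatmap itself is a thin optional layer.

## The synthetic-data generator

Real discovery inputs are a dozen public studies across four array
platforms; the generator replaces them with fixtures whose ground truth is
known, so every stage is testable offline.

* **Compendium**: background cells are Gaussian `N(0, noise_sd^2)` on the
  log2 fold-change scale — the standard noise model for log-intensity
  data — and each planted bicluster cell is `N(effect_mean, effect_sd^2)`.
  Overlapping planted blocks resolve last-writer-wins, which keeps
  generation simple and the ground truth well-defined. Defaults:
  `noise_sd = 0.2`, `effect_mean = ±2` (a 4-fold effect), `effect_sd = 0.2`.
  A fixture is *recoverable* when `|effect_mean| - 2·effect_sd >= 1`, i.e.
  planted cells clear the 2-fold threshold with high probability; the
  defaults sit safely inside that regime, mirroring how clearly the strong
  inflammation signatures separate in real exposure data.
* **Dose experiments**: the default design is a vehicle control plus
  18, 54 and 162 µg doses with three replicates per dose — the typical
  intratracheal-instillation design of the application studies — and the
  default per-dose shifts `(0, 1, 2, 3)` log2 units with residual SD 0.5
  on a 50-gene responsive set constitute the package's *power fixture*.
  Setting every shift to 0 gives the *null fixture* used for
  type-I-error calibration.
* **Raw studies**: `simulate_raw_study()` embeds the compendium's fold
  changes around a flat 8-log2-unit baseline, adds per-study control
  samples, technical replicate probes and biological replicates with
  Gaussian measurement noise, so that preprocessing reproduces the
  compendium exactly at zero noise and up to the noise scale otherwise.

Every generator call uses one seeded RNG scope that restores the caller's
RNG state, so a config's seed fully determines its output and concurrent
test runs cannot interact; multi-stage runs derive per-stage child seeds
deterministically from the master seed.

What the generator does **not** emulate: correlated background genes,
heavy-tailed or intensity-dependent noise, platform/batch effects, probe
artifacts, or realistic effect-size distributions (neither the noise
magnitude nor the effect sizes of the real compendium are published).
Passing the recovery and calibration tests therefore demonstrates
algorithmic correctness and statistical calibration under a clean additive
Gaussian model — not performance on any particular real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by the package's own choice
of fixture sizes: 500 genes × 20 conditions compendia with three planted
blocks (30×8 up, 20×6 up, 25×5 down) over 50–100 seeds; 2000-gene dose
experiments with 4 dose groups × 3 replicates; 1000 null gene sets for the
uniformity check (rejection rate at α = 0.05 expected in [0.03, 0.07],
Kolmogorov–Smirnov uniformity at α = 0.01); 100–200 seeds for power and
decoy-ranking checks. Exact-agreement oracles (brute-force bicluster
enumeration, `t.test`/`oneway.test` references, hand-worked F = 4.5 and
Welch t = 3/√1.5 examples) are held to 1e-8–1e-12 tolerances; stochastic
rates to the bands above.

## Known limitations

* The bicluster search is exact and therefore exponential in the worst
  case; it is intended for thresholded fold-change matrices, which are
  sparse. Dense matrices hit the `max_biclusters` guard.
* The competitive enrichment test treats genes as independent; correlated
  gene sets inflate the effective type-I error, as for any
  gene-randomizing set test. The null calibration shown by the tests is
  under independence.
* The union-merge path produces `NA`s that downstream discovery refuses by
  design; it exists for data inspection.
* `log2 F` is undefined for F = 0 or F = ∞; such genes are excluded and
  counted rather than imputed, so sets dominated by perfectly-separating
  genes lose members in the test.
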