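---
title: "Methods: desiccation-tolerance physiology, differential expression and thresholded co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desiccation-tolerance physiology, differential expression and thresholded co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desiccnet)
```

## The scientific setting

Resurrection grasses with *modified* desiccation tolerance do not survive
sudden drying: tolerance has to be induced during a gradual dry-down, and
the protective programme is in place by roughly 60% relative water content
(RWC). `desiccnet` implements the analysis pipeline for experiments probing
that switch point in a two-tissue (shoot/root), six-state design —
hydrated, ~80%, ~60%, ~40%, <10% RWC and rehydrated — with biological
triplicates:

1. **Physiology**: RWC scoring, survival of rapid drying per pre-drying RWC
   band, and an Evans Blue cell-death index.
2. **Differential expression**: each dehydration state against the same
   tissue's hydrated reference, with the enrichment rule |fold change| ≥ 2
   and Benjamini–Hochberg adjusted p < 0.05.
3. **Co-expression networks**: per tissue, the top 10,000 genes by
   coefficient of variation, all-pairs Pearson correlation, and an edge
   for every pair with |r| > 0.964; per-state up/down node overlays and
   cross-state comparison.
4. **Metabolomics**: fold changes versus hydrated, heatmap clustering
   orders, PCA.
5. **Phytohormones**: one-way ANOVA per hormone across states with a
   Tukey-based compact letter display.

Every stage runs on the output of a seeded synthetic-data generator, so
the full pipeline is testable end to end without external data.

## Physiology

RWC is the standard fresh/dry/turgid weight ratio,
$\mathrm{RWC} = 100\,(FW - DW)/(TW - DW)$. Values slightly outside
\[0, 100\] are real (turgid-weight measurement error), so `compute_rwc()`
warns rather than clamps; $TW \le DW$ is an error because the quantity is
undefined.

`survival_threshold()` scans bands from wettest to driest and returns the
wettest band from which *every* band at and below reaches the required
resurrection fraction. Resurrection in this design is all-or-nothing per
band, hence the default `min_frac = 1`; the parameter is exposed for
designs with partial survival.

Raw Evans Blue absorbances depend on instrument and extraction, so
`cell_death_index()` rescales mean A600 between the assay's own controls —
0 at the hydrated-negative mean, 1 at the boiled-positive mean, clipped to
\[0, 1\]. Degenerate controls (positive ≤ negative) abort the computation.

## Differential expression

The per-gene test is a two-sided Welch two-sample t-test on log2 values.
With triplicates there is no information to justify equal-variance pooling,
and Welch is the minimal defensible choice; it is implemented row-wise
(vectorised over genes) and checked against `stats::t.test()` per gene in
the test suite. This is a deliberate swap-point: a moderated-variance test
could be substituted behind the same interface.

Genes with zero variance *and* zero difference are flagged non-testable
(`p = NA`) and excluded from the number of BH tests m, rather than being
assigned p = 1 — assigning 1 would dilute the correction with entries that
carry no evidence either way. BH adjustment is applied within each
tissue × state contrast (one data set per RWC level), not across the whole
design.

Boundary semantics are literal: fold change ≥ 2 **inclusive**
(|log2FC| ≥ 1) and adjusted p **strictly** < 0.05.

## Co-expression networks

**Gene selection.** CV = SD/|mean| is computed per gene across *all* of a
tissue's samples, states pooled — pooling maximises the dynamic-range
signal CV is meant to capture. The matrix is consumed on the scale
provided (log2 in the bundled generator); |mean| keeps the denominator
positive for log-scale values, and genes with |mean| < 1e-8 are excluded
with a warning because CV is numerically meaningless there. Ranking ties
break lexicographically by gene ID, so selection is deterministic and
seed-free. Constant genes are dropped before correlation (r undefined).

**Thresholding.** An edge is a pair with |Pearson r| strictly greater than
the threshold (default 0.964); a pair exactly at the threshold is not an
edge. Isolated genes are excluded from the node set — the network is what
an edge-list import into a graph viewer produces. The test suite holds the
edge set equal to a brute-force all-pairs computation from the raw-sum
correlation formula, exactly, over randomized instances.

**State overlays and comparison.** Nodes are colored per state from the
DEG table (up/down/unchanged); "active" edges join two nodes of equal
non-unchanged status. The "distinct sections" a state lights up are
operationalized as connected components of the active subgraph; community
detection is deliberately *not* used — components are assumption-free and
need no algorithm choice to defend. Cross-state
turnover is quantified by Jaccard similarity of active node sets. Networks
export as an edge-list TSV plus GraphML with per-state status attributes
(openable in Cytoscape); `read_network()` restores them losslessly.

## Metabolomics

Fold change is the ratio of raw-scale group means against the same
tissue's hydrated samples; the significance test runs on log2 abundances
through the same Welch + BH machinery as the expression stage, for
internal consistency. Metabolite tables of this kind are
commonly reported at unadjusted p < 0.05, so a raw-p mode
(`adjust = "none"`) is exposed alongside the default BH adjustment. Zeros are replaced by half the metabolite's smallest positive
value (a detection-limit surrogate) before logs, with a warning.

Heatmap ordering uses Euclidean distance on row-z-scored values with
average linkage — a common default for mixed-magnitude GC–MS panels; both
are arguments. Leaf orders may reflect at any merge (dendrogram
reflections are not identifiable), so the invariance the tests assert is
of the tree itself (cophenetic distances), not of the printed order.

PCA runs on the centered sample × metabolite table with unit-variance
scaling per metabolite by default (panels span orders of magnitude);
`scale. = FALSE` gives covariance PCA. Scores are checked against an
independent eigendecomposition of the covariance matrix, and variance
fractions must sum to one at full rank.

## Phytohormones

Classical one-way fixed-effects ANOVA per hormone across states, with the
recovery time point treated as an ordinary factor level. The all-equal
degenerate case (0/0 F ratio) is reported as F = 0, p = 1. The post-hoc
generator of the letter display is Tukey HSD — the conventional source of
compact letter displays — with pairwise Welch + BH available as an
alternative mode. Letters are assigned by insert-and-absorb over states
ordered by descending mean: start from one letter covering all states; for
each significant pair, split every letter column containing both members;
then absorb columns contained in others. By construction two states share
a letter exactly when their comparison is non-significant, and the test
suite asserts that equivalence pair-by-pair on every instance it generates.

## The synthetic-data generator

The generator emulates the study conditions, not generic expression data.
Defaults, chosen once:

* **Design**: 2 tissues × 6 states × 3 replicates; 2,000 genes;
  20 named metabolites.
* **Scale**: expression is generated directly on log2 scale (the upstream
  normalisation of real matrices is out of scope and undeclared; declaring
  the scale is the honest alternative). Gene baselines are uniform on
  4–12 log2 units; residual noise SD is 0.3, a typical replicate-level
  spread for moderately expressed genes.
* **Modules**: each planted module has one unit-variance latent Gaussian
  factor with loading $\sigma\sqrt{\rho/(1-\rho)}$, so the expected
  within-module Pearson correlation is the target $\rho$ (default 0.9).
  The factor splits into a state-level component (constant within a
  tissue × state cell; share `module_state_frac`, default 0.75) and a
  sample-level component. The split reflects what a dehydration-response
  module is: activity co-varies mainly with the dehydration state, with a
  smaller replicate-to-replicate fluctuation. A purely sample-level factor
  would put the whole factor variance inside replicate groups and make
  planted effects statistically invisible at n = 3 — a property of the
  generator, not of the analysis.
* **Planted effects**: module genes shift by ±`deg_log2fc` (default 8,
  ~250-fold — the scale on which strong desiccation-response genes switch
  on or off) only in their active (tissue, state) cells, so a gene can be
  down at 40% RWC and unchanged elsewhere, as the per-state overlays
  require.
* **Metabolites**: the early set (sucrose, raffinose, myo-inositol,
  proline, aromatic amino acids, …) rises 4-fold in shoots from 60% RWC
  through drying; the late set (lysine, methionine, alanine, …) rises only
  in roots at <10% RWC; noise is multiplicative lognormal (sdlog 0.25).
* **Hormones**: ABA highest hydrated (primed state) and low from 60% RWC;
  SA rising from 60% RWC onward; JA-Ile declining through drying; Gaussian
  noise of 1 pmol/mg, truncated at zero.
* **Physiology**: weight triples drawn inside each declared RWC band (so
  recomputed RWC falls in-band by construction); A600 high for plants
  rapidly dried from ≥80% RWC and low once acclimated to ≤60%; survival
  0/5 above the 70–60 band and 5/5 at and below it.
* **Seeding**: every generator draws from a fixed-offset substream of one
  root seed, so regenerating one table never perturbs another, and
  identical configs give bit-identical output.

What the generator does **not** emulate: count-level overdispersion
(negative-binomial mean–variance coupling), library-size artefacts,
batch effects, missing values, or correlated noise between tissues.
Passing tests therefore demonstrate that the pipeline's logic and
statistics behave as specified under clean Gaussian conditions — not that
the thresholds are optimal for any particular real data set.

## Numerical choices and degenerate inputs

* Welch test: zero variance with unequal means gives p = 0; with equal
  means, p = NA (non-testable).
* BH: NA entries preserved, m = number of non-NA tests.
* CV: |mean| < 1e-8 excluded; ties lexicographic.
* Correlation: constant genes are an error at `pearson_all_pairs()` and a
  logged drop in `drop_constant_genes()`/`tissue_network()`.
* Thresholds: |r| strictly >, fold change ≥, adjusted p strictly < — all
  deliberate; the pipeline accepts
  `corr_threshold` up to 1.0, which yields an empty network.
* Hierarchical clustering of a constant matrix: warning, input order
  returned.
* ANOVA with no variation: F = 0, p = 1, all states share one letter.
* RWC outside \[0, 100\]: warning, value returned unclamped.

## Problem sizes used in the tests

The test and acceptance runs scale the design down from the real study's
~30,000-gene transcriptome so the whole suite re-runs in well under a
minute on one core: 550–650 genes for network-recovery scenarios (a
50-gene module against 500 independent noise genes, 18 samples per
tissue), 1,000 genes × 200 replicates for the null false-discovery check,
and a 250-gene demo for end-to-end determinism. These sizes were chosen so
that every Monte-Carlo check has enough replication for a stable verdict
(20 seeds for module recovery, 10 scenario replicates for the tissue
contrast, 200 replicates for FDR) while the full suite remains quick to
iterate on. None of the statistics depend on problem size for
correctness — the oracle-equivalence checks are exact at any size.

## Known limitations

* The Welch-on-triplicates test is noisy at n = 3; real analyses would
  typically prefer a moderated-variance method. The module surface keeps
  that swap trivial.
* CV ranking on log2 data mixes scale and variability; it is kept because it is
  the established selection statistic for this network construction, and
  it is configurable at the call site.
* The 0.964 correlation threshold is a fixed convention of this network
  construction; with only
  18 samples per tissue the null tail beyond 0.964 is ~5e-11, so the
  networks are conservative by construction.
* GraphML round-trips preserve weights to double precision as printed by
  igraph (~1e-9 agreement asserted), not bit-exactly.
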