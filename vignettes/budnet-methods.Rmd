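---
title: "Methods: environmental traits, co-expression modules and DAM/SVP networks in winter buds"
author: "budnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmental traits, co-expression modules and DAM/SVP networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budnet)
```

# Scope and scientific setting

Temperate fruit trees such as peach carry two kinds of axillary buds through
winter: flower buds, which keep differentiating slowly during chilling
accumulation, and vegetative buds, long assumed to sit dormant. Comparing the
two organs' transcriptional programs over a chilling time course requires a
chain of analyses: quantifying the environmental covariates (accumulated
chilling and photoperiod), normalizing and filtering RNA-seq counts from a
multi-season sampling design, classifying genes by organ bias, grouping
co-regulated genes into modules and correlating them with the environment,
reducing the module genes to an interpretable co-expression graph, and
inferring which DAM/SVP MADS-box transcription factors regulate which
targets. `budnet` implements that chain as composable functions plus a
single-call pipeline, and ships a synthetic-data generator with planted
ground truth so each stage can be validated end to end without any external
download.

# Environmental covariates

**Chilling units (CU).** We use the Utah model: each hourly temperature
reading contributes a banded weight (1 CU for 2.5–9.1 °C, 0.5 CU for the
flanking bands, 0 for neutral temperatures, −0.5/−1 CU above 16 °C), and
contributions are accumulated from a configured start date
(`utah_chill_hourly()`, `accumulate_chill()`). Band edges follow the
published one-decimal resolution. Negative accumulation is *not* clamped by
default — the convention is not universal, so a `clamp_daily_negative` flag
is provided. Daily min/max records are first expanded to hourly values by a
sine curve (minimum near sunrise, maximum at 14:00), standard practice when
station data are daily.

**Day length (LOD, hours).** `day_length()` evaluates the standard sunrise
equation with the solar declination of the day (Spencer's Fourier series)
and an effective zenith of 90.833°, which folds in atmospheric refraction
and the solar radius. Longitude shifts sunrise and sunset but not their
difference, so only latitude matters. Polar latitudes (|φ| ≥ 66.5°) are
rejected rather than approximated. Against a published sampling calendar
for Legnaro, Italy (45.35° N), computed values agree within 0.1 h; the
largest deviation (≈0.1 h in early September) is consistent with calendars
derived from sunrise/sunset tables rounded to whole minutes.

# Expression preparation

**Normalization.** Between-sample factors are trimmed means of M-values
(TMM): the reference sample is the one whose upper quartile of non-zero
relative counts is closest to the mean upper quartile; per sample, gene-wise
log2 ratios (M) and mean log2 abundances (A) against the reference are
double-trimmed (30 % tails on M, 5 % on A, rank-based) and the factor is
2^mean(M) over the survivors, rescaled to unit geometric mean. We implement
the unweighted form directly — the package's tests require exact agreement
with the literal trimmed-mean formula — and cross-check it against
`edgeR::calcNormFactors(doWeighting = FALSE)` in the test suite.
Expression is then taken to log2(CPM + 1) on TMM-effective library sizes;
the pseudocount of 1 on the CPM scale keeps zero counts finite without
distorting moderately expressed genes.

**Batch structure.** Multi-season designs leave a batch imprint. We use an
ANOVA-decomposition correction: per-gene biological group (organ ×
timepoint) means are fitted and preserved exactly; the residual matrix is
decomposed by SVD and any leading component whose sample scores correlate
with the batch indicator beyond |r| = 0.7 is subtracted. The default
examines the two leading components. A design in which every group was
collected in a single batch is *perfectly confounded*: the batch signal is
then indistinguishable from biology, absorbed into the group means, and the
function warns and returns the input unchanged rather than guessing.

**Differential expression.** The original study ran its DE step through an
external platform; `budnet::test_de()` deliberately uses a transparent
surrogate — a per-gene one-way F-test across timepoints on log2 expression,
per-contrast log2 fold changes against the first timepoint, and
Benjamini–Hochberg adjustment across genes (BH is used everywhere an
"adjusted P" is needed). `filter_deg()` applies the two published gates:
the global set at fold change ≥ 1.4 with FDR ≤ 0.05, and the more stringent
network input set at fold change ≥ 1.5 with FDR ≤ 0.01. "Overall fold
change" is read as the maximum absolute contrast against the first
timepoint, and both boundaries are inclusive. On synthetic data at the
generator's default noise (dispersion 0.05, three replicates) this chain
recovers planted differential genes with mean sensitivity ≈ 0.95 and mean
empirical FDR ≈ 0.08 across seeds.

# Organ-bias classification and projection PCA

Each gene is fitted with `expression ~ Condition + Timepoint`, where the
Condition coefficient is **flower minus vegetative** (the sign convention
used everywhere downstream). A gene is flower- or vegetative-biased when
|coefficient| ≥ log2(1.5) with BH-adjusted p < 0.05 (boundary inclusive),
otherwise balanced. These thresholds are explicit, configurable defaults.

The PCA treats *genes as observations*. Features are organ × timepoint mean
expressions (per-sample features are also supported; group means are the
default because they are what the bias question is about). Each gene's
feature vector is first centred on its own mean, so components capture
profile *shape* rather than absolute expression level; the PCA is trained
on shared genes only (`pca_shared()`) and organ-specific genes — expressed
(CPM ≥ 1 in ≥ 2 samples) in exactly one organ — are projected afterwards
into the same space (`project_specific()`), reproducing training scores
exactly when reapplied. With planted organ bias, PC1 aligns with the organ
axis and correlates almost perfectly (|r| > 0.95) with the condition
coefficient, mirroring the strong PC1–coefficient coupling seen in real
bud data.

# Co-expression modules

Adjacency is soft-thresholded correlation. The package default is the
**signed** form, a_ij = ((1 + r)/2)^β. This is a deliberate choice: the
study design correlates modules with two *anti-correlated* environmental
cues (chilling rises while day length falls), so biologically opposite
modules have strongly negative inter-module correlation. Unsigned adjacency
(|r|^β) maps r = −1 to maximal similarity and such opposite modules
collapse into one cluster by construction; the signed form keeps them
apart. Unsigned remains available via `type = "unsigned"` for users who
want it.

β can be fixed (6, the conventional default) or chosen as the smallest
power whose scale-free topology fit reaches R² ≥ 0.8 with negative slope
(`soft_threshold_power()`, with a warned fallback to 6). The topological
overlap TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij) is
clamped to [0, 1] with unit diagonal, and modules come from average-linkage
clustering of 1 − TOM with a *static* cut at height 0.95 — just below the
top of the tree, separating major branches while leaving diffuse background
genes in the unassigned ("grey") pool — followed by removal of clusters
smaller than 30 genes and iterative merging of modules whose eigengenes
correlate above 0.75. Labels are assigned in decreasing size with a
configurable prefix (V for vegetative, F for flower runs). There is no RNG
anywhere in this stage, so module labels are deterministic.

A module eigengene is the first principal component of the module's
standardized expression across samples, sign-oriented to correlate
positively with the module mean profile; a single-gene module's eigengene
is the standardized gene. Module–trait association is the Pearson
correlation of each eigengene with each covariate, with p from the t
distribution on n − 2 degrees of freedom (checked against a permutation p
in the tests). GO enrichment per module is the one-sided hypergeometric
tail with BH adjustment across terms; annotations are user input.

# The reduced co-expression graph

For a functionally selected gene subset, `build_topk_graph()` applies the
reduction rule literally: every gene nominates its five most highly
correlated partners (signed r, descending, ties broken by lexicographic
partner id), the union of nominations forms the candidate edge set, edges
below r = 0.75 are discarded (boundary kept), and isolated nodes are
dropped. The union — rather than mutual — rule is what allows hub genes to
exceed degree 5 with k = 5, which is exactly how published bud networks
show nodes with ten or more connections. Ranking by signed r is the literal
reading of "most highly correlated"; since r ≥ 0.75 excludes all negative
edges anyway, an absolute-value ranking is offered only behind the
`rank_abs` flag. Degrees are binned as 1, 2–4, 5–6, 7–9 and ≥10; the
degree-1 bin is our documented extension below the smallest published size
class.

# DAM/SVP regulatory networks

Genes are first partitioned into shared / flower-specific /
vegetative-specific sets by expression presence (`partition_genes()`). For
each target gene, `genie3_importances()` fits a Random-Forest regression of
the standardized target profile on the regulator profiles (500 trees,
⌊√p⌋ candidate features per split, seeded per target) and attributes to
each regulator its share of the total impurity reduction, normalized to sum
to one per target. Standardizing targets makes importances comparable
across targets. On planted networks (8 regulators, 40 true targets among
400 decoys) the ranked edge list attains an average precision tens of times
the planted-edge density, and the top of the ranking is essentially pure.

A practical note on scale: with impurity-share normalization and √p
candidate features, even a target that is an exact copy of one regulator
yields a share around 0.4–0.5 for that regulator, because deep trees always
attribute some residual impurity reduction to irrelevant features. This is
why meaningful importance thresholds sit far below 1: edges are retained by
strict inequality against per-context cutoffs (flower 0.30, vegetative
0.36, shared 0.27 — taken as given parameters, since the empirical
derivation behind them is not reproducible without the original weight
distributions), and edge strength is displayed as weak (< 0.3), moderate
(0.3–0.5, boundaries inclusive) or strong (> 0.5).

Dimer annotation makes the narrative logic of DAM/SVP complex formation
explicit, since only outcomes, not an algorithm, are stated in the
literature: within a network context, the regulators retained for a target
are combined so that every BiFC-positive pair becomes a single heterodimer
edge (carrying both ids, mean weight, validated flag), remaining regulators
stay as homodimer edges, and BiFC-negative pairs are never merged. The
bundled default interaction table encodes positives SVP1–DAM3, SVP1–DAM5,
SVP1–DAM6 and DAM5–DAM6 and the negative DAM6–DAM3, with everything else
untested; it is plain data and fully overridable. Finally,
`go_filter_targets()` marks the "visual" edge subset whose targets carry at
least one term enriched (BH-adjusted p < 0.05) among the network's
targets; the full edge list is always preserved alongside.

# The synthetic-data generator

`simulate_expression()` emulates the statistical structure the analysis
assumes: a two-organ × six-timepoint × three-replicate design over two
seasons, negative-binomial counts (the standard count emulation; dispersion
0.05 by default) around

μ = library_factor × exp(baseline + module_loading × driver + organ_bias +
batch_offset + regulator_effect),

with linear, anti-correlated CHILLING (0 → 930 CU) and LOD (12.85 → 8.72 h)
trait curves matching a real winter sampling window; planted co-expression
modules loaded on either cue in either direction; a configurable fraction
of organ-biased genes at a log2-scale offset; gene-wise Gaussian per-batch
offsets shared across organs (the simplest structure the batch correction
is designed to remove); and a regulator→target layer in which each target's
log-mean receives an additive contribution from its regulator's noise-free
latent profile, so importance-based recovery is well-posed. By default
batches are crossed with timepoints (replicates split across seasons, as
when a timepoint is sampled in both years); the fully season-nested design
is available as `batch_design = "by_timepoint"` and is exactly the
confounded case the batch correction refuses to touch. Replicate count is
exposed (3–4) since real designs vary between three and four trees.

Everything is a pure function of (configuration, seed); the pipeline fans a
single global seed into per-stage sub-seeds through a fixed affine map
(`derive_seed()`), keeping every stage independently reproducible.

What the generator does **not** emulate: read-level artifacts (mapping,
isoforms, GC bias), heavy-tailed count outliers, non-linear trait
responses, gene-length effects, and correlated dispersion structure. A
passing recovery test therefore demonstrates internal consistency of the
method chain under the assumed model, not performance on any particular
real dataset.

# Numerical choices and degenerate inputs

* Utah bands are evaluated at one-decimal resolution with midpoint cutoffs,
  so any float in a band maps to that band's weight.
* Flat genes in `test_de()` (zero within- and between-group variance) get
  p = 1 rather than NaN; timepoints with one replicate are dropped with a
  warning.
* Zero-variance genes pass through batch correction untouched; constant
  genes are rejected by name in correlation-based stages.
* PCA uses `prcomp`/SVD throughout; projection idempotence is exact to
  1e−10.
* Boundary decisions, all documented at the function level: DEG gates
  inclusive; bias threshold inclusive; graph r ≥ 0.75 kept; GRN thresholds
  strict (>); strength boundaries 0.3 and 0.5 belong to "moderate".
* Top-k ties are broken by lexicographic gene id, making edge lists
  deterministic including order.

# Problem sizes

The shipped tests and examples run at desk scale, chosen to exercise every
code path with comfortable statistical margins: recovery checks use
100–500 genes, 36 samples, and for the regulatory network 8 regulators
with 440 candidate targets at 500 trees per target. These sizes complete a
full test run in well under a minute of compute while leaving the measured
margins (accuracy ≥ 0.9, ARI ≈ 1, average precision ≫ baseline) far from
their thresholds. Scaling to transcriptome-wide inputs (~20k genes) is
linear in genes for everything except the TOM (quadratic memory in the
module-stage gene count), which is why module detection operates on the
stringent DEG subset, as in the original design.

# Known limitations

* The DE statistic is a transparent surrogate, not a reimplementation of
  the original platform's noise model; absolute DEG counts from real data
  will differ even at identical gates.
* The static tree cut is simpler than dynamic hybrid cutting; very uneven
  module sizes may require adjusting `cut_height`/`min_module_size`.
* GRN thresholds are taken as given; they should be re-derived from the
  weight distribution for any new dataset.
* The dimer rule is an explicit interpretation of narrative statements and
  marks predictions, not physical complexes; only the BiFC table carries
  experimental support.

# Session info

```{r}
sessionInfo()
```
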