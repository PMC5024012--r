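---
title: "Methods: modular transcriptome analysis with coexmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular transcriptome analysis with coexmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmap)
```

# Scope and data model

`coexmap` analyses designed log2-intensity expression experiments of two
shapes: a **multi-tissue reference design** (several vegetative tissues,
biological replicates nested in tissues, optional dye-swap technical
replicates of each biological replicate) and a **seasonal design** (two
species crossed with a handful of time-points, several trees per cell).
Everything operates on a `coex_experiment`: a genes x samples matrix plus
per-sample metadata (`tissue`, `tree`, `dye`, `species`, `timepoint`).

The pipeline's stages are: detection, assumption screening and mixed-model
classification of genes as tissue-variable or invariant; module detection
among high-confidence variable genes; splitting of each module into two
anticorrelated coexpression groups; template-matching assignment of the
remaining variable genes; hypergeometric representation analysis of gene
sets across partitions; unweighted signed correlation-threshold networks
with hub statistics; and an integration of seasonal clusters with
tissue-based groups that phases genes as earlywood- or latewood-associated.

# Gene classification

## The balanced mixed model

For each gene the model is

$$y_{tjd} = \mu + \tau_t + b_{j(t)} + \delta_d + (\tau\delta)_{td} +
\varepsilon_{tjd},$$

with tissue $\tau$, dye $\delta$ and their interaction fixed, and the tree
within tissue $b_{j(t)}$ a random intercept. The design is balanced and
complete (every tissue x tree x dye cell observed exactly once), so the
sums of squares decompose in closed form and the expected mean squares
dictate the F ratios: tissue is tested against the tree-within-tissue mean
square on $(a-1,\ a(b-1))$ degrees of freedom, while dye and tissue x dye
are tested against the residual (tree x dye within tissue) mean square.
`fit_mixed_anova()` implements exactly this decomposition; it refuses
unbalanced layouts rather than silently fitting a different model, because
the closed-form F ratios are only exact under balance. Iterative REML adds
nothing for a balanced design and is deliberately not used. Dye-swap
technical replicates enter as separate observations, with the biological
replicate captured by the nested random effect; this is one of two
readings of a two-colour design and the one that keeps the dye factor
testable.

Genes are categorised from Benjamini-Hochberg adjusted tissue p-values in
a single family per experiment: `variable_high` below $10^{-4}$,
`variable_low` in $[10^{-4}, 0.05)$, `invariant` at or above 0.05. These
thresholds are the reference constants of the pipeline and are exposed as
parameters.

## Assumption screening

Before classification each gene passes four screens: Anderson-Darling
normality of the model residuals, Levene homogeneity of variances across
tissue groups (classical mean-centred form, with the Brown-Forsythe
median variant available), and the dye and tissue x dye fixed-effect
tests. Whether screening should examine raw values or residuals is an
open choice; residuals are used for the normality screen because the
planted tissue effects would otherwise dominate the test, and raw
tissue-grouped values for the variance screen because that is the
hypothesis Levene's test addresses.

Each rule's p-values are BH-adjusted **across genes** (one family per
rule) and a rule fires at adjusted $p < 0.05$. The unadjusted alternative
is available (`screen_adjust = "none"`) but is a poor default: Levene's
classical test is liberal at eight observations per group, and four
simultaneous 0.05-level screens would discard roughly a fifth of
perfectly well-behaved genes, an exclusion rate far above what designed
microarray experiments report. With the adjusted default, screening
removes only genes with strong, reproducible violations - in the
synthetic benchmark, planted Cauchy-noise genes and planted dye-effect
genes fall out while clean genes essentially never do.

# Module detection

High-confidence variable genes are clustered on the
technical-replicate-averaged matrix:

1. Pearson correlation matrix (pairwise-complete over missing values).
2. Unsigned soft-thresholded adjacency $a_{ij} = |r_{ij}|^\beta$. The
   unsigned form is essential here: a module is defined as a cluster of
   strongly positively *and negatively* correlated genes, and the
   unsigned adjacency lets the two halves co-cluster. Reference powers
   are $\beta = 14$ for the tissue experiment and $\beta = 18$ for the
   seasonal one. A signed transform is exposed but off by default.
3. Topological overlap
   $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
   (\min(k_i,k_j) + 1 - a_{ij})$, and dissimilarity $1 - \mathrm{TOM}$.
4. Average-linkage hierarchical clustering with a **static cut**. The
   cut height defaults to 0.5: TOM similarities scale down uniformly as
   $\beta$ grows, and a 0.25 cut - natural-looking at small powers -
   fragments cleanly planted modules into singletons at $\beta = 18$,
   while 0.5 separates planted modules across the whole tested range of
   powers (14-18) and noise levels (0.1-0.3). Clusters below
   `min_module_size` are pooled into an unassigned bin. The static cut
   is the principal simplification relative to dynamic tree-cut module
   detection, and no claim is made of reproducing any particular
   published module count.

Each module's **eigengene** is the first principal component of its
gene-standardised submatrix (computed by SVD; the reported
variance-explained equals the top eigenvalue fraction of the spectral
decomposition). Its sign is oriented so most members correlate
positively, with a deterministic lexicographic tie-break. Members with
non-negative eigengene correlation form group `a`, the rest group `b`
(a correlation of exactly zero goes to `a` by the stated tie rule), and
each group's **template** is its per-sample mean profile. Group-tissue
association is summarised by the Pearson correlation between the group
eigengene (negated for `b` groups) and each 0/1 tissue indicator.

# Template matching

Low-confidence variable genes are assigned to groups by correlating each
gene with every template and testing only the best candidate with the
t-transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$. Best-candidate p-values are
BH-adjusted in one family across all candidate genes; a gene is assigned
iff its adjusted p-value is below 0.05 **and** the correlation is
positive, since groups are defined by positively correlated profiles.
Testing only the best template (rather than all 22) keeps the family one
test per gene; this is a deliberate resolution of an ambiguity in the
original procedure. Ties between templates are broken towards the larger
group and then lexicographically - a probability-zero event on
continuous data, fixed only for determinism.

# Representation analysis

Over/under-representation of a gene set in a partition cell uses the
exact hypergeometric tails $P(X \ge k)$ and $P(X \le k)$ with population
$N$, set size $K$ and cell size $n$. Two one-tailed tests are computed
per cell, matching the convention of flagging over- and
under-representation separately. BH families are configurable: per set
across cells and tails (default), per cell across sets (the by-column
mode used for expression-class tables), or global. A cell is called
`over` only when the observation also exceeds its expectation
$Kn/N$ (symmetrically for `under`).

Invariant genes are partitioned into four expression classes by ranking
their mean expression and splitting at the quartiles; class sizes differ
by at most one, with any remainder allocated to the lowest classes first
(4805 genes give 1202/1201/1201/1201). Ties are resolved by stable gene
id order so the partition is deterministic.

# Signed correlation networks

An unweighted signed network connects two genes when the absolute Pearson
correlation of their (replicate-averaged) profiles **strictly exceeds**
the threshold, 0.9 by default; each edge carries the correlation's sign.
Degree counts incident edges of both signs, and hub ranks are tie-aware:
equal degrees share the minimum rank and subsequent ranks are skipped.
Network intersection keeps shared same-sign edges (conflicting signs are
dropped with a message) and restricts nodes to those incident to a shared
edge. Scale-free topology is assessed by regressing log10 frequency on
log10 mean degree over 10 logarithmic bins; the binning count is a
convention, not a fitted quantity.

# Seasonal analysis and phase integration

Temporally variable genes are called by a per-probe two-way fixed-effects
ANOVA (species x time), BH adjustment of the time-effect p-values across
all probes, and the any-probe rule: a gene is variable iff at least one
of its probes is significant. Variable genes are clustered with the same
module machinery at $\beta = 18$ into `T`-labelled clusters.

Phase integration treats each temporal cluster group as a gene set and
runs representation analysis across the tissue-based group partition.
Genes of June-July-preferential clusters lying in tissue groups where
those clusters are significantly overrepresented are called
**earlywood**; September-preferential cluster members in their
overrepresented groups are called **latewood**; everything else is
unphased. Which clusters count as June-July- or September-preferential
is determined automatically by the argmax of the cluster template over
time-points (configurable, since the original assignment was by visual
inspection of profiles). Earlywood and latewood sets are disjoint by
construction because a gene belongs to exactly one temporal cluster.

# The synthetic-data generator

The generator is first-class, tested code: it is the source of ground
truth for every recovery claim the test suite makes.

The tissue generator emulates the reference design - seven vegetative
tissues, four trees per tissue, dye-swap pairs per tree, i.e. 56 arrays -
with three planted gene classes: anticorrelated module pairs (group `a`
follows `amplitude * tissue_profile` added to a gene-specific baseline,
group `b` its negation), invariant genes (zero shift), and assumption
violators of two kinds (Cauchy-tailed noise emulating spike-like
artifacts, and a strong additive dye main effect), so both screening
branches are exercised. The noise model is independent Gaussian on the
log2 scale plus a Gaussian tree random intercept shared by the two dye
replicates of a biological replicate - exactly the nested random effect
the downstream ANOVA assumes - and an optional per-gene dye effect split
symmetrically across dyes (which averaging technical replicates cancels
identically). Baselines are uniform over a configurable log2 interval so
expression-quartile operations have spread. Default magnitudes (noise sd
0.2, tree sd 0.1, amplitude 2 log2 units) are plausible for well-behaved
two-colour array data; within- vs between-tissue variance magnitudes are
not calibrated to any public dataset and are tunable. Planted module
profiles drawn by `random_module_specs()` use columns of a random
orthonormal basis so distinct modules are nearly uncorrelated.

The seasonal generator plants temporal clusters over four time-points in
two species; the defaults are the two canonical growing-season shapes -
stable through August then a sharp September change, and a progressive
decline - as mirrored anticorrelated pairs, with the preferred time-point
of each profile recorded in truth as its earlywood/latewood phase.

All draws descend deterministically from a single seed through per-gene
sub-streams, so regeneration is bit-identical and partial regeneration is
stable.

What the generator does **not** emulate: probe-level spatial artifacts,
background and flagging, intensity-dependent (loess-shaped) dye bias,
correlated noise between genes beyond planted modules, and
mean-variance coupling. Passing recovery tests therefore demonstrates
correctness of the statistical machinery under its stated model, not
robustness to every failure mode of real arrays.

# Numerical and degenerate-case conventions

* All-equal profiles report p = 1 for every effect rather than NaN.
* Zero-variance genes are rejected by correlation operations by name;
  network construction keeps them as isolated nodes.
* Missing values: correlations are pairwise-complete; sample clustering
  and eigengenes impute per-gene means (announced); a gene with missing
  design cells is excluded from the ANOVA as incomplete.
* `|r| = 1` template correlations return the smallest positive double
  rather than zero.
* TOM values are clipped to [0, 1] against floating-point drift and the
  matrix is symmetrised after computation.
* Sample dendrograms use Euclidean distance with the `ward.D2`
  implementation of Ward's criterion and export to Newick via `ape`.

# Problem sizes in the test suite

The bundled tests run planted datasets of roughly 2000 genes by 56
arrays for classification and recovery (20 seeded replicates spanning
2-6 modules and noise sd 0.1-0.3), 200-gene instances for brute-force
network verification, and exhaustive hypergeometric verification for all
populations up to N = 30. These sizes were chosen so the whole suite
gives tight Monte-Carlo checks in about a minute on one CPU; all
machinery scales to full-platform gene counts, where the module and
network stages are dominated by one genes x genes matrix product.

# Known limitations

* The static tree cut replaces dynamic tree cutting and eigengene-based
  module merging; very close planted profiles can merge into one module.
* The detection rule (`detect_expressed`) is a simple quantile stand-in
  for platform-specific positive-probe calling.
* Quantile normalisation is intentionally not applied anywhere by
  default; inputs are assumed normalised upstream.
* The mixed ANOVA is exact only for balanced complete designs; there is
  no generic unbalanced fallback, by design.
* Screening combines four tests; its BH-adjusted default controls false
  exclusion but the exact screening protocol of any given published
  analysis (alphas, adjustment, residual vs raw values) is rarely
  stated, so reported excluded-gene counts are not expected to match
  other implementations exactly.
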