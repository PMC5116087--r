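---
title: "Pathway activation scoring with ipanda: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation scoring with ipanda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipanda)
```

# The model

`ipanda` turns a case/control expression study into one signed activation
value per pathway and case sample. Three ingredients multiply inside each
pathway unit (a gene, or a collapsed gene module):

1. **Log2 fold change** of the case sample against the mean log2
   intensity of the normal group. Expression intensities are treated as
   log-normal, so the reference is a geometric mean on the linear scale
   and effects are additive on the log scale. Linear-scale input is
   log-transformed after adding a pseudo-count of half the smallest
   positive value when zeros are present; strictly negative intensities
   are rejected.

2. **Statistical weight** $w^S(p) \in [0,1]$, a smooth transform of the
   gene's two-sided Welch t-test P value between the full case and normal
   groups:
   $$w^S(p) = \tfrac12\left(1 + \cos \pi
     \frac{\ln p - \ln p_{\min}}{\ln p_{\max} - \ln p_{\min}}\right),$$
   clamped to 1 below $p_{\min} = 10^{-7}$ and 0 above
   $p_{\max} = 10^{-1}$. The half-cosine on the log scale replaces a hard
   P-value cutoff; scores respond continuously as evidence accumulates,
   which is what makes them reproducible across cohorts where individual
   genes hover near any fixed threshold.

3. **Topological weight** $w^T \in [0,1]$: all simple walks (no node
   repeated) from the pathway graph's zero-in-degree nodes to its
   zero-out-degree nodes are counted; a unit's weight is its walk count
   divided by the pathway maximum. Units on the main signal-transduction
   backbone therefore dominate; dead-end periphery contributes little.
   An isolated node is both a start and an end and lies on exactly one
   walk, so topology-free gene sets (GMT input) degenerate gracefully to
   uniform weights.

A unit's contribution is `sign * w^T * mean(w^S * log2fc)` over its
member genes, with sign $\pm 1$ for activators/repressors; the pathway
score is the sum over units, by default divided by the number of pathway
genes present in the data.

**Modules.** Groups of coexpressed or co-regulated genes carry largely
redundant evidence; left alone they are counted once per member, so a
correlated block can dominate a pathway by multiplicity alone. `ipanda`
builds disjoint gene modules from a coexpression matrix (plus optional
TF-target sets), contracts each module to a single graph node before walk
counting, and aggregates member genes by their *mean* weighted fold
change. The mean (rather than the sum) keeps a module commensurate with a
single gene and yields an exact exchangeability property: two genes with
identical weight and fold change in parallel graph positions produce the
same pathway score whether they are scored separately or as one collapsed
unit (this is pinned by a unit test).

**Significance.** Unit-level differential evidence is combined per
pathway by a weighted Fisher test: $X = -2\sum_i w_i \ln p_i$ with
$w_i = w_i^S w_i^T$, referred to a Gamma$(\sum_i w_i,\,2)$ null. At unit
weights this is exactly Fisher's $\chi^2_{2N}$ combination (asserted to
1e-10 against the `pchisq` oracle); with fractional weights the Gamma
null matches the statistic's mean. Units whose weight is zero carry no
usable evidence and are excluded; if all weights vanish the combined P
value is 1 with a warning. A module unit's P value is the Welch t-test of
the mean log2 profile of its member genes — the module treated as one
collective variable — and its $w^S$ is the cosine weight of that P value.

**Markers and the CMP index.** A pathway's value as a phenotype marker is
its ROC AUC (rank-based, half-credit for ties) against e.g. a
responder/non-responder label, computed per dataset. Because activated
and repressed pathways are equally valid markers, ranking and the marker
rule use the symmetric AUC $\max(\mathrm{AUC}, 1-\mathrm{AUC})$; the raw
orientation is also reported. Pathways exceeding 0.75 in *every* dataset
are common markers, and
$$\mathrm{CMP} = \sum_{i \in \text{common}} \ln N_i \cdot
  \frac{1}{n}\sum_j (\mathrm{AUC}_{ij} - 0.5),$$
with $N_i$ the pathway's gene count ($\ln N_i$ up-weights large pathways,
which are less likely to reach a high AUC by chance). CMP is zero exactly
when no pathway is a marker everywhere.

# Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `pMin`, `pMax` | 1e-7, 1e-1 | P value | Ends of the smooth weighting window; genes beyond them saturate at 1/0. |
| `sizeNormalize` | `TRUE` | — | Divide by pathway genes present; equates 5-gene and 400-gene pathways with uniform signal (pinned by test). |
| `moduleAgg` | `"mean"` | mean/sum | Mean preserves exchangeability; sum restores per-gene counting. |
| `useTopology` | `TRUE` | — | `FALSE` sets all $w^T = 1$ (ablation / GMT-equivalent). |
| `maxWalks` | 1e6 | walks | Simple-path counting is exponential in the worst case; the guard converts blow-ups into an actionable error. |
| `cutHeight` | 1.0 | distance | Hierarchical tree cut; distance 1.0 corresponds to correlation 0.5 under $d=\sqrt{2(1-r)}$. |
| `eps`, `minPts` | 1.0, 3 | distance, count | DBSCAN neighbourhood; `minPts` counts the point itself. |
| `minCorr` | 0.3 | correlation | Strict lower bound on a module's mean internal pairwise correlation. |
| `minOverlap` | 0.7 | Jaccard | Strict merge threshold for near-duplicate clusters. |
| `threshold` | 0.75 | symmetric AUC | Marker rule, applied in every dataset. |

# Numerical conventions and degenerate inputs

- **Welch t-test**, two-sided, vectorized over genes; validated per gene
  against `stats::t.test` to 1e-10. Genes with zero variance in both
  groups get $p = p_{\min}$ when means differ (unmistakable signal,
  weight 1) and $p = 1$ when equal; P values are clamped above 1e-300 so
  the log-scale weight stays defined.
- **Walk counting** uses dynamic programming (walks-into × walks-out-of
  per node, by Kahn topological order) on acyclic graphs and an explicit
  visited-set depth-first enumeration when cycles are present; the two
  are asserted identical on random DAGs. Strict simple-path semantics
  implements the rule that loops are forbidden; cyclic-graph alternatives
  (e.g. contracting strongly connected components first) would change
  counts and are not used. A graph with no complete start-to-end walk
  (possible only with cycles) falls back to uniform weights with a
  warning.
- **Module collapse** contracts all nodes intersecting a module,
  inherits the union of edges, drops self-edges; the contracted sign is
  the majority sign, and an exact tie splits the module into one
  per-sign sub-unit (a tied module genuinely contains two opposing
  parts). A node intersecting several modules joins the one sharing the
  most genes (ties: lexicographic module id).
- **Merging and disjointness**: candidate clusters from both detectors
  are pooled and pairs above the overlap threshold are unioned to a
  fixpoint (re-merging the output is a no-op, tested). The intersection
  level is Jaccard by default (`metric = "min"` gives the overlap
  coefficient). A gene surviving in several modules is assigned to the
  module with the higher mean internal correlation (ties: larger module,
  then lexicographic id); modules shrunk below two genes are dropped.
- **Average-linkage heights** can lose monotonicity to floating-point
  jitter; they are sorted before `cutree`, which is exact in the
  monotone case.
- **Z-normalization** of scores is per dataset and pathway: centered by
  the mean of per-phenotype means when labels exist (removing the
  dependence of the expectation on class balance), otherwise the plain
  mean; scaled by the population (n-denominator) standard deviation;
  zero-variance rows map to 0; single-sample datasets are an error.
- **Determinism**: mean-AUC ranking breaks ties by larger pathway then
  lexicographic id; all generators are pure functions of their seed.
- Score TSVs are written at full double precision (`%.17g`) and
  round-trip within 1e-12.

# What the synthetic data emulate

`simulationConfig()` describes a reference study: 2000 log-normally
expressed genes (baseline mean 7 log2 units, SD 1), 20 pathways drawn as
layered random DAGs of 5–50 genes with ~10% repressor nodes, 20 case and
20 normal samples, an effect of 2 log2 units planted sign-consistently in
designated pathways, coexpression blocks with internal correlation 0.8,
and platform noise of 1 log2 unit. Three designs build on it:

- **Null and recovery** (`simulateExpression`): with effect 0 the gene
  t-tests are calibrated (the fraction below p = 0.05 sits inside
  binomial 99% bounds); with effect 2 the planted pathway is expected to
  dominate mean |score| and the mean-AUC marker ranking. The validation
  suite runs the recovery at 400 genes, 10 ten-gene pathways, 20 cases
  (half responders), 10 normals, 2 datasets, 100 seeds.
- **Dual-platform pairs** (`simulatePlatformPair`): one biological log2
  matrix is "measured" twice, each platform adding a fixed per-gene
  offset (probe effect) and per-cell Gaussian noise, both of SD
  `platformNoiseSd`. Per-sample correlation across platforms of pathway
  score vectors is compared with that of gene-level fold-change vectors
  (20 pairs of 8 case samples at SD 1.0 in the validation suite). Scores
  win because statistical weighting suppresses platform-only genes and
  within-pathway aggregation averages incoherent technical noise while
  the planted biology is coherent across member genes.
- **Multi-dataset marker study** (`simulateMarkerStudy`): 4 independent
  cohorts (500 genes, 8 pathways of 12–25 genes, 15 responders + 15
  non-responders vs 15 normals) share three planted pathways. Each
  planted pathway carries its responder signal on core genes scaled by
  their topological weight (a perturbation propagating along the
  cascade) plus two kinds of disease-responsive but
  phenotype-uninformative nuisance: a coexpression block on a random
  subset of units (correlated noise only module collapse can count
  once) and scattered peripheral genes at the least-travelled units
  (high statistical weight only topological weighting can suppress).
  The CMP index of the full model is compared against ablations with
  modules or topology disabled over 50 seeded replicates. The two
  nuisances are deliberately orthogonal: without the peripheral genes,
  a responder effect that tracks $w^T$ is already "learned" by $w^S$
  from the data and the explicit topology factor would be redundant.

**What they do not emulate.** No probe-level physics (background,
cross-hybridization, GC effects), no batch structure beyond the platform
offsets, no correlated gene networks outside the declared blocks, no
missingness, and pathway topologies are random layered DAGs rather than
curated signalling maps. Passing the simulation-based checks therefore
demonstrates internal consistency of the machinery and the direction of
the claimed noise-reduction and robustness effects under the stated
generative assumptions — not performance on any particular real dataset.

# Design choices made under genuine freedom

- **Distance transform** $d = \sqrt{2(1-r)}$: the Euclidean distance
  between standardized expression vectors; the natural companion of a
  correlation matrix destined for Euclidean-space clustering.
- **Welch rather than Student** t-test: robust to unequal group sizes
  and variances, the common case in case/control designs; both the test
  and the log base (2) are fixed conventions documented here because
  scores scale linearly with the base.
- **Size normalization by present gene count** rather than unit count:
  the unit count changes when modules collapse, which would break the
  exchangeability property; the gene count is invariant and delivers the
  intended size-independence.
- **Gamma null** for the weighted Fisher statistic: matches the mean of
  the weighted sum, is exact in the unweighted case, and avoids
  Monte-Carlo nulls in a per-pathway inner loop.
- **Symmetric AUC** for the marker rule: up- and down-regulated pathways
  are treated alike; the raw orientation stays available for directional
  interpretation.
- **CMP functional form**: uses exactly the named ingredients — the
  common-marker intersection across all $n$ datasets, $\ln N_i$, and the
  mean AUC excess over the random classifier's 0.5 — and satisfies the
  zero-iff-empty-intersection property by construction.

# Validation scale

The shipped test suite and `scripts/acceptance.R` run at desk scale on a
single CPU (about a minute each): 200 random 12-node DAGs for the
walk-count oracle, a 1000-point grid for the weight function, 20
chi-squared comparisons, 20 dual-platform pairs, 50 marker-study
replicates, and 100 recovery simulations. These sizes are the package's
validation conventions; all of them are plain arguments and scale up
linearly if stronger evidence is wanted.

# Known limitations

- Simple-path counting is exponential in the worst case; `maxWalks`
  makes this explicit rather than silent. Very dense curated pathways
  may need module collapse (which shrinks the graph) before weighting.
- Statistical weights depend on group sizes through the t-test, so very
  small cohorts push many genes into the zero-weight region and scores
  toward zero; the smooth window's location, not the method, is the
  binding constraint there.
- The module pipeline assumes the coexpression matrix is estimated (or
  given) on a scale compatible with the data; it is filtered only
  through the internal-correlation rule.
- Pathway-level P values are not adjusted for multiple testing across
  pathways, by design: they feed marker ranking, which is rank-based.
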