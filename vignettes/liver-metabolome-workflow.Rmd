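---
title: "Methods: allometric liver growth and period-resolved metabolome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometric liver growth and period-resolved metabolome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomet)
```

# Overview

`allomet` implements a complete workflow for studying how the liver
metabolome reorganizes during early post-hatch growth in chickens. The
biological backbone is the *allometric ratio* — liver mass divided by body
mass — whose trajectory over post-hatch days partitions the schedule into
three periods:

- **Period A** (days 4–8): positive allometry, liver growth outpacing the
  body, fueled largely by yolk-derived lipids;
- **Period B** (days 10–14): transition;
- **Period C** (days 16–20): negative allometry, the liver receding
  relative to the body as feed-derived carbohydrate metabolism dominates.

The workflow asks three statistical questions about a samples ×
metabolites peak-height table annotated with these periods:

1. **Discrimination** — do periods A and C have separable metabolomes,
   and which metabolites carry the separation? (O-PLS-DA, VIP, univariate
   statistics, random-forest importance.)
2. **Network persistence** — which metabolite–metabolite correlations
   survive in every period ("core" metabolites), and how does the
   correlation topology change between periods?
3. **Growth coupling** — which metabolites track the allometric ratio or
   total liver mass?

Because every operation is exercised against a synthetic-study generator
with planted ground truth, the statistical machinery is testable
end-to-end: planted differential metabolites must be recovered, planted
correlation cliques must appear as the core network, and null
configurations must yield calibrated p-values.

# The synthetic-study generator

`generateStudy(syntheticConfig())` simulates the full study design: 9
sampling days (4, 6, …, 20), 12 birds per day, 204 metabolites.

**Growth.** Body mass follows a Gompertz curve; the allometric ratio
follows a fixed day-anchored template whose sign pattern (rising to day 6,
falling to day 12, a brief rise at day 14, falling thereafter) defines the
periods. Per-bird noise is multiplicative with coefficient of variation
`growthCV`; `growthCV = 0` reproduces the template exactly, which is used
as an exact oracle in the tests.

**Metabolites.** Log intensities are generated as

$$\log x_{ij} = \mu_j + \delta_j(\text{day}_i) + a_j f_i + s_j
\varepsilon_{ij},$$

with metabolite baselines $\mu_j$, a planted day ramp $\delta_j$, optional
latent clique factors $f_i$, and Gaussian residuals. The ramp is linear in
day and scaled so that the period A versus period C mean difference equals
exactly `effectSizeD` standard deviations on the log scale — group-1
metabolites (e.g. fatty acids, α-tocopherol) are elevated early and decay;
group-2 metabolites (e.g. glucose-6-phosphate, adenine) mirror them.
Clique members share a latent factor with loading $a$, giving pairwise
log-scale correlation $a^2 / (a^2 + s^2)$ — a closed form the tests verify
by Monte-Carlo. Xenometabolite columns are zero-inflated
(Bernoulli-detected) to mimic sporadically observed environmental
compounds.

Everything is seed-deterministic: each stage draws from a named substream
of the master seed, so generating growth alone reproduces exactly the
growth portion of a full study.

# Preprocessing

- `normalizeTIC()` scales each sample so its total ion current equals the
  cohort mean total; the operation is idempotent.
- `zScores()` standardizes each metabolite across samples (sample SD,
  $n-1$); constant metabolites map to 0 with a warning.
- `compositeZScore()` averages Z-scores over metabolite groups per day,
  producing the group trajectories used to visualize coordinated shifts.
- `hclusterMetabolome()` wraps average-linkage hierarchical clustering of
  samples or metabolites, optionally aggregating metabolites to pathway
  means first.

By default the pipeline models normalized peak heights directly. Because
peak heights are approximately log-normal, the `log2BeforeZscore` option
switches Z-scoring and latent-variable modeling to `log2(x + 1)`
intensities, which substantially sharpens effect recovery on log-normal
data; fold changes are always computed from raw normalized means.

# O-PLS-DA and model validation

`fitOplsda()` implements orthogonal projections to latent structures for a
two-class response. Labels are coded $+1/-1$ (sorted class order),
mean-centered; predictors are centered and scaled (unit-variance by
default). Each orthogonal component is extracted by deflating the weight
vector of its label-covariance component, removing class-orthogonal
variation; a single predictive component is then fit to the deflated
matrix. Reported statistics:

- $R^2Y = 1 - SS_{res}/SS_{tot}$, in-sample explained label variance;
- $RMSEE = \sqrt{SS_{res} / (n - 1 - a)}$ with $a$ = number of model
  components;
- **VIP** for a single predictive component reduces to
  $\sqrt{m}\,|w_j|$, so $\text{mean}(VIP^2) = 1$ exactly — a structural
  invariant the acceptance tests check to 1e-10.

Validation (`validateOplsda()`) has three prongs:

1. **Cross-validated $Q^2$** — stratified $k$-fold (default 10),
   $Q^2 = 1 - PRESS / SS_{tot}$, with centering/scaling re-estimated
   inside every training fold.
2. **Permutation testing** — labels permuted, model refit;
   $p = (\#\{\text{permuted} \ge \text{observed}\} + 1)/(n_{perm}+1)$,
   so the smallest attainable p is $1/(n_{perm}+1)$.
3. **CV-ANOVA** — a one-way ANOVA of the out-of-fold predictions grouped
   by class: $F = SS_B / (SS_W / (n-2))$, $p$ from $F_{1,n-2}$,
   $\eta^2 = SS_B / SS_T$ as effect size.

A methodological caveat worth stating plainly: CV-ANOVA is an
*approximate* significance heuristic. Out-of-fold predictions are not
independent across samples (they share training folds), which inflates the
F statistic under the null — in simulations the fraction of null runs with
$p < 0.05$ is roughly 0.15 rather than 0.05, across scalings, fold counts
and component settings. The permutation test does not share this problem
(its null p-values are uniform on their support) and should be preferred
for formal significance; CV-ANOVA is reported for comparability with
common practice.

# Univariate and machine-learning statistics

`univariateStats()` computes, per metabolite: log2 fold change of raw
group means (undefined, with warning, if a mean is non-positive), Cohen's
d on Z-scored values (pooled SD), one-way ANOVA F and p, and BH-FDR across
metabolites. `rfImportance()` adds random-forest Gini importance.
`differentialTable()` joins these, filters to VIP > 1 and sorts by VIP —
the package's analogue of a differential-metabolite table, annotated with
the period (A or C) each metabolite is enriched in.

# Correlation networks

For each period, `pairwiseCorrelations()` computes Pearson (or Spearman)
correlations with p-values from the t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$. `buildPeriodNetwork()` applies BH-FDR over
all pairs within the period and keeps edges with $|r| > 0.85$ and
FDR < 0.05; nodes without qualifying edges are dropped.

- `coreNetwork()` intersects the three period networks. Edge mode (the
  default) keeps edges present in all periods, with `r` averaged and
  `p`/`fdr` the most conservative (maximum) across periods; node mode
  keeps metabolites that carry at least one edge in every period.
- `firstNeighbors()` expands the core within one period to all adjacent
  nodes — the period-specific pathway context of the persistent core.
- `topologyMetrics()` reports ten descriptive statistics (nodes, edges,
  mean degree, diameter, radius, characteristic path length, clustering
  coefficient, density, degree heterogeneity, centralization, component
  count) with documented conventions: path statistics are computed over
  connected pairs (diameter/radius within the largest component), local
  clustering of degree < 2 nodes is 0, heterogeneity is the population SD
  of degrees over the mean, centralization is
  $\frac{N}{N-2}\left(\frac{\deg_{max}}{N-1} - \text{density}\right)$.
  All ten are verified against a brute-force BFS oracle on random graphs.

Networks export to SIF (topology + edge sign), GraphML (full attributes at
17 significant digits, exact round-trip) and edge TSV.

# Growth associations and xenometabolites

`growthAssociation()` correlates every metabolite with a growth phenotype
(allometric ratio or liver mass) pooled across days, with BH-FDR across
metabolites. `annotateXenometabolites()` flags compounds of likely
non-endogenous origin (feed components, environmental contaminants,
plastic-associated compounds) by case-insensitive name lookup.

# The pipeline

```{r pipeline, eval = FALSE}
config <- pipelineConfig(
  syntheticConfig = syntheticConfig(seed = 1),
  outdir = "run1",
  seed = 1
)
bundle <- runPipeline(config)
print(bundle)
```

`runPipeline()` chains every stage and writes a plain-text report bundle
(TSV/JSON/YAML/SIF/GraphML). Two design points matter for reproducibility:

- **Atomicity** — artifacts are staged in a temporary directory and copied
  to `outdir` only if every stage succeeds; a failure is reported with its
  stage name and leaves no partial outputs.
- **Determinism** — all numeric output is printed with fixed formats and
  all randomness derives from named substreams of the master seed, so two
  runs with the same configuration produce byte-identical bundles (only
  `run.log`, which carries wall-clock timestamps, differs).

A YAML configuration (`readPipelineConfig()`) and a command-line interface
(`allometCli()`; installed script `allomet`) expose the same pipeline with
subcommands `simulate`, `run`, `network`, `stats` and `report`.

# Session info

```{r session}
sessionInfo()
```
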