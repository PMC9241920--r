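---
title: "Quantifying assembly processes and co-occurrence structure in microbial metacommunities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying assembly processes and co-occurrence structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Microbial communities differ from place to place and from season to
season. Two broad families of mechanism can produce that turnover:
*deterministic* ones — environmental selection filtering taxa by their
niches — and *stochastic* ones — random birth, death and dispersal.
`driftnet` implements the null-model machinery that partitions observed
pairwise community turnover among five processes (heterogeneous
selection, homogeneous selection, dispersal limitation, homogenizing
dispersal, drift), the compositional correlation networks that describe
who co-occurs with whom, and the environmental-heterogeneity statistics
that link the two. Because field data come without ground truth, the
package also ships a metacommunity simulator whose generating regime is
known, so every inferential claim the package makes can be tested
against communities whose true assembly process is known by
construction.

## The null models

**Weighted βMNTD.** For samples $k$ and $m$ with relative abundances
$f_{ik}$ and patristic distances $d(i,j)$ on a shared phylogeny,

$$\beta\mathrm{MNTD}(k,m) = \frac{1}{2}\Big[
  \sum_{i \in k} f_{ik}\,\min_{j \in m} d(i,j) +
  \sum_{j \in m} f_{jm}\,\min_{i \in k} d(j,i)\Big],$$

the abundance-weighted mean distance from each taxon to its nearest
relative in the opposite community. It is small when the two communities
are drawn from the same clades, large when they occupy different parts
of the tree.

**βNTI.** The standardized effect size of βMNTD against a null in which
tip labels are shuffled uniformly across the *whole* tree while
abundances stay fixed: $\beta\mathrm{NTI} = (\text{obs} -
\mu_\text{null})/\sigma_\text{null}$. The shuffle covers every tip of
the supplied tree, not only the taxa present in the table: the tree
represents the regional pool, and clustering of the observed taxa is
measured against random draws from that pool. (Restricting the shuffle
to observed taxa would make a community drawn entirely from one clade
look unremarkable against itself.) Pairs whose null standard deviation
is zero — e.g. a star phylogeny with equal branch lengths — are
reported as `NA` with a `degenerate` flag rather than ±∞ or silent
zeros. Default 999 replicates; the replicate count and the seed are
explicit arguments everywhere, and a fixed seed gives bit-identical
matrices because all pairwise nulls are drawn from a single serial RNG
stream.

**Raup–Crick on Bray–Curtis.** For pairs not decided by βNTI, the
observed Bray–Curtis dissimilarity is compared with nulls that rebuild
both communities preserving each sample's richness and total abundance:
taxon identities are drawn without replacement with probability
proportional to occupancy, remaining individuals allocated by mean
relative abundance (an unweighted variant is available). With ties
counted half, $RC = 2\,[\#\{null < obs\} + \tfrac12\#\{null =
obs\}]/\text{reps} - 1 \in [-1, 1]$. Equality of two Bray–Curtis values
is judged at $10^{-12}$ to keep the tie count meaningful in floating
point.

**Classification.** βNTI $> +2$ → heterogeneous selection; βNTI $< -2$
→ homogeneous selection; otherwise $RC > +0.95$ → dispersal limitation,
$RC < -0.95$ → homogenizing dispersal, else drift. All comparisons are
strict, so boundary values (βNTI exactly 2, RC exactly 0.95) fall
through to the weaker category; the unit tests pin this down. Process
fractions are summarized per group (per season in a seasonal survey),
over within-group pairs only.

## SparCC

Relative-abundance data are compositional: closing counts to
proportions induces spurious negative correlation. The package's SparCC
estimator works from the log-ratio variation matrix $t_{ij} =
\operatorname{var}\log(x_i/x_j)$, solves the linear approximation for
basis variances $\omega_i$ under the assumption that most pairs are
uncorrelated, and converts to correlations $r_{ij} = (\omega_i +
\omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$, clipped to $[-1,1]$.
The sparsity assumption is relaxed by iteratively excluding the
strongest pair above a threshold (default 0.1, up to 10 rounds) from
the linear system and re-solving; exclusion stops early if a
component's equation count would drop below three, where the system
becomes ill-posed. Zeros are handled by resampling fractions from a
Dirichlet posterior with a unit prior (`counts + 1`) rather than a
fixed pseudocount — at high sparsity a fixed offset biases the
log-ratios deterministically, while posterior resampling propagates the
uncertainty; a deterministic pseudocount mode is available. The
estimate is the entrywise median over 20 resampling iterations.
Significance comes from a permutation bootstrap (default 100): each
round permutes every taxon's counts across samples independently and
the two-sided pseudo p-value is $(\#\{|r_b| \ge |r_{obs}|\} +
1)/(n_{boot} + 1)$.

On simulated compositional data with one planted basis correlation of
0.8 (50 taxa, 200 samples), the estimator lands within ±0.15 of the
truth while the median absolute off-target correlation stays below 0.1,
and on fully independent bases its mean |r| is well below that of
Pearson correlations on proportions — the artifact it exists to remove.
These checks run in the test suite and in `scripts/acceptance.R`.

## Networks

Edges are retained under strict thresholds (defaults |r| > 0.5 and
p < 0.05 for SparCC networks; |ρ| > 0.6 and BH-FDR q < 0.01 for
Spearman taxa–environment networks; q < 0.05 for cross-domain bipartite
networks), isolated nodes are dropped, and edge sign is kept as an
attribute. Topology (average degree, clustering, path length and
diameter on the largest component), Louvain modules (renamed `M1..Mk`
by decreasing size), the log–log least-squares power-law fit of the
degree distribution, G(n, m) Erdős–Rényi ensembles (default 1000
graphs) with z-scores, keystone selection (degree > 100 and
unnormalized betweenness < 5000 — betweenness must be unnormalized for
a fixed threshold of 5000 to be meaningful on networks of hundreds of
nodes), and per-sample induced subnetworks are all computed on the
*unweighted* simple graph; correlation-derived weights can be negative,
which path-based statistics do not admit. "Transitivity" of a
subnetwork is reported both as mean local clustering and as global
transitivity, since either reading is defensible; downstream
regressions here use the local-clustering average.

## Environmental heterogeneity and distance statistics

The heterogeneity index of a group is the mean pairwise Euclidean
distance between its samples' environmental vectors. Variables are
z-scored *across all samples* before within-group distances are taken:
mixed units (°C, psu, mg/L) need standardization, but standardizing
within each group would make every group's index scale-free and erase
exactly the between-group spread differences the index measures — an
error we made and caught during development, now pinned by a test.
Zero-variance variables are dropped with a warning; a variable known to
covary with another (e.g. dissolved oxygen with temperature) can be
excluded by name. Mantel tests (Pearson on off-diagonal entries,
permutation p-values with the +1 convention) provide the inferential
statistics for distance–distance relationships; the OLS
distance–distance regression is descriptive only, because pairwise
distances are dependent observations.

## The simulator and its regimes

`simulate_phylogeny()` draws ultrametric birth–death trees;
`evolve_optima()` evolves a one-dimensional environmental optimum along
the tree by Brownian motion (variance = rate × branch length), with an
optional early-burst (ACDC) mode in which the rate decays exponentially
with time since the root. Early-burst evolution concentrates niche
divergence on deep splits: clades carry distinct optima while close
relatives are nearly identical — the adaptive-radiation form of niche
conservatism. This matters quantitatively: on 150-tip trees,
single-rate Brownian optima leave trait-selected taxon sets only weakly
phylogenetically clustered, too weak for the homogeneous-selection
signature (|βNTI| rarely passes 2); with early-burst decay 6 the same
construction yields ideal-community βNTI means of −2 to −3. The regime
presets therefore use `eb_decay = 6`.

`assemble_metacommunity()` builds each local community by multinomial
sampling of J individuals with weight ∝ pool abundance ×
exp(−(optimum − E)²/(2w²)) — a Gaussian niche kernel, one parameter (w)
controlling determinism — followed by G generations of zero-sum Moran
drift (one generation = J single birth–death replacements, parent and
casualty drawn independently from the pre-step community). An optional
Dirichlet-multinomial "dispersal lottery" perturbs each site's sampling
weights with a small concentration parameter, modelling founder
effects; it is off by default. All randomness descends from one master
seed through fixed per-stage sub-seeds.

The three validation regimes (`simulate_regime()`, 150 taxa, 15 sites):

* **Heterogeneous selection** — strong filter (w = 1 against a tip
  optima SD ≈ 1.2), site environments spread with SD 3 around the
  pool's median optimum, J = 1000, no drift. Different sites select
  different clades; phylogenetic turnover exceeds the null.
* **Homogeneous selection** — every site sits at the centre of the
  pool's *tightest 40-taxon niche cluster*, with the filter width set to
  half that cluster's span (floor 0.1) and small communities (J = 50)
  over a nearly flat pool (lognormal SD 0.3). Small J makes multinomial
  sampling turn over membership *within* the selected clade — different
  members, same lineage — which is precisely the homogeneous-selection
  signature (observed turnover phylogenetically narrower than the
  pool-wide null). Targeting the tightest cluster rather than the
  median value keeps the eligible set a coherent clade across tree
  draws. Membership turnover generated instead by site-level lotteries
  or strong drift is genuinely dispersal limitation/drift and is
  classified as such — only sampling-scale turnover stays inside the
  Raup–Crick null envelope.
* **Drift** — no filter, J = 500, two complete community turnovers of
  Moran drift. Two turnovers leave compositional divergence within the
  Raup–Crick null envelope so pairs read as drift; with three or more,
  divergence exceeds the envelope and increasingly (and correctly, in
  the metric's terms) reads as dispersal limitation. Validated over 24
  random seeds: drift is the modal process in 96% and its fraction
  exceeds 0.5 in 92%.

`simulate_survey()` combines the pieces into a 4-season × 13-site
survey with season-dependent environmental spreads (wide in "winter",
narrow in "summer") plus correlated auxiliary variables, which is what
the end-to-end pipeline and the acceptance script consume.

**What the simulator does and does not emulate.** It produces realistic
*structure* — phylogenetically conserved niches, lognormal abundance
distributions, selection/drift mixtures, season-dependent environmental
spread — but not sequencing artifacts (PCR bias, chimeras, variable
library sizes beyond what `rarefy()` removes), nor multi-trait niches,
speciation, or spatially explicit dispersal. Passing the regime-recovery
tests shows the inference chain is mathematically sound and correctly
signed; it does not certify performance on real amplicon data, whose
pool sizes (tens of thousands of OTUs) and noise sources are far
larger.

## Problem sizes and runtime choices

The test suite exercises the chain at sizes chosen to make the
statistics meaningful while keeping a full run in minutes: oracle
equivalence on 50 random instances (≤ 8 taxa × 5 samples, tolerance
1e-12, cross-checked once against `picante::comdistnt`); null
calibration pooled over 20 datasets of 12 samples × 100 taxa at 199
replicates; regime recovery at 15 samples × 150 taxa × 199 replicates ×
3 seeds per regime; SparCC at 50 taxa × 200 samples; 1000-graph
Erdős–Rényi ensembles. The βMNTD kernel and the Moran process are
implemented in C++ (Rcpp); everything else is vectorized R over
`ape`, `vegan` and `igraph` primitives.

## Numerical and degenerate-input policy

* Strict inequalities everywhere a threshold is quoted; boundary cases
  are unit-tested.
* Degenerate βNTI pairs (zero null SD) → `NA` + flag + warning, and
  `"undefined"` labels are excluded from process fractions with a
  warning.
* Bray–Curtis ties in the Raup–Crick count at tolerance 1e-12, counted
  half.
* Basis variances in SparCC are floored at 1e-10 before the square
  root; estimates are clipped to [−1, 1].
* Constant columns in Spearman networks are skipped with a warning
  (rank correlation undefined), zero-variance environment variables are
  dropped with a warning under standardization.
* Every stochastic function takes an explicit `seed`; `NULL` uses the
  session RNG. Master seeds fan out to stage sub-seeds kept below
  2³¹ − 1.

## Known limitations

* βNTI requires the tree to cover the regional pool; with very small
  pools the tip-shuffle null is coarse (only $n!$ distinct relabelings,
  and far fewer distinct βMNTD values).
* The Raup–Crick null conditions on occupancy and mean abundance
  estimated *from the data*, so with few samples those estimates are
  noisy and RC values near ±0.95 are fragile.
* SparCC's sparsity assumption degrades when many strong correlations
  coexist; the exclusion loop mitigates but does not remove this.
* The power-law R² is a descriptive fit on binned log–log frequencies,
  not a likelihood-based test of scale-freeness, and simulated survey
  networks are generally not scale-free — the statistic is reported for
  completeness, not as evidence.
* Process fractions depend on the grouping: only within-group pairs are
  tallied, so group definitions change denominators.
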