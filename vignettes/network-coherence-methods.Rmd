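---
title: "Methods: metabolic network coherence and optimal-cutoff survival stratification"
author: "metcoherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic network coherence and optimal-cutoff survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its two procedures: how the
coherence statistic is defined and calibrated, how the survival
stratification works, what the synthetic-data generators emulate, and the
numerical and design choices that were genuinely open.

## 1. From a stoichiometric matrix to a gene-centric network

A genome-scale metabolic model is a bipartite graph: metabolites on one
side, reactions on the other, edges given by non-zero entries of the
stoichiometric matrix.  Three projections are built in sequence:

* **Metabolite-centric graph** — metabolites are adjacent when they
  co-occur in at least one reaction.  Coefficient signs and magnitudes are
  ignored throughout: the method is purely topological, and flux
  directions carry no information about co-membership.
* **Currency trimming** — a few ubiquitous metabolites (water, ATP,
  cofactors) participate in a large fraction of reactions.  They connect
  everything to everything and must be removed before the network's
  pathway structure becomes visible.  The package removes the top `pct`
  percent of metabolites by degree; 2–10 % removal (90–98 % retained) is
  the practically useful band, and `pct` is one axis of the scan.
* **Reaction-centric graph** — reactions are adjacent when they share a
  *retained* metabolite.
* **Gene-centric graph** — genes annotated to reactions become nodes; two
  genes are adjacent when they annotate the same reaction (rule a) or
  adjacent reactions (rule b).  Genes of one reaction are maximally
  metabolically coupled, which is why rule (a) is on by default; it can be
  disabled (`same_reaction = FALSE`) to study rule (b) alone.

Two details are not determined by the construction and were fixed as
follows:

* **Degree used for currency ranking.** The default ranks by degree in the
  metabolite-centric projection (number of distinct co-occurring
  metabolites).  The alternative — the raw bipartite count of reactions a
  metabolite participates in — is available via `degree = "bipartite"`.
  The two orderings agree on strong hubs and differ only in the tail.
* **Tie handling at the percentile boundary.** Exactly
  `ceiling(pct/100 * n)` metabolites are removed; ties at the boundary
  degree are broken by ascending lexicographic id.  Any deterministic rule
  would do; determinism itself is the requirement, because it makes
  currency sets nested across percentages and scans reproducible.

Boolean gene–reaction rules (isozymes vs complexes) are flattened to the
set of mentioned symbols when importing SBML: the coherence method uses
only membership, so AND/OR structure is irrelevant here.  Reactions
without gene annotations stay in the model — they still carry metabolite
connectivity — and simply contribute no gene nodes.  An SBML species
appearing on both sides of a reaction with equal stoichiometry would net
to zero; the importer keeps the product-side coefficient so the species
retains its co-membership, which is all downstream code uses.

## 2. The coherence statistic MC

Given a gene set $S$ (by default: genes with $|\log_2 FC| > t$ and
$p < p_{max}$, both strict, matching the usual "> 2", "< 0.05" reporting
conventions) and the gene-centric network $G$, the statistic is

$$ MC = \frac{C_{obs} - \langle C_{null} \rangle}{\mathrm{sd}(C_{null})} $$

where $C$ is the average local clustering coefficient of the subgraph of
$G$ spanned by the mapped genes (local value 0 for nodes of degree < 2),
and the null draws are gene sets of the same size sampled uniformly
without replacement from all nodes of $G$.

Numerical choices:

* `n_random = 1000` null draws by default: the null sd estimate is then
  stable to roughly 2 %, which is enough for a z-score read to one
  decimal.  `seed` fixes the draws; identical seeds reproduce MC
  bit-for-bit.
* The null sd uses the sample (n−1) estimator.
* **Degenerate cells.** When fewer than 3 set genes map onto the network,
  or the null sd is exactly 0 (e.g. the set covers the whole network, so
  every draw is the full node set), MC is reported as 0 with a
  `degenerate` flag instead of NaN.  This keeps scan grids rectangular
  and plottable; consumers must check the flag, not the value.
* Set genes absent from the network are dropped from scoring and reported
  as `n_unmapped`.
* **Null pool.** Sampling from *all* network nodes is the default; a
  `null = "measured"` switch restricts the pool to genes actually measured
  in the DE table, for sensitivity analysis.  With dense coverage the two
  nulls coincide; with sparse coverage the "measured" null is the more
  conservative comparison.
* The implementation computes local clustering from the dense adjacency
  submatrix (`diag(A³)` over `k(k−1)`), which makes the thousands of
  small-subgraph evaluations in a scan cheap; the test suite pins it to a
  brute-force triangle-enumeration oracle.

`coherence_scan()` evaluates MC over a grid of fold-change thresholds and
currency percentages (the two analysis parameters).  Each cell derives
its seed as `bitwXor(seed, cell_index)` with
`cell_index = (pct_index − 1) · n_thresholds + threshold_index`, and the
per-cell seed is stored in the result, so any cell can be reproduced by a
standalone `coherence_z()` call — the suite checks this equality
bit-for-bit.  Cells whose selection maps no genes are marked degenerate,
never fatal.  Raw $C$ is reported alongside MC per cell, since a z-score
alone hides the absolute connectivity level.

The spanned subnetwork at any grid point can be exported with node signs
(up iff $\log_2 FC > 0$) and edge labels (co-regulated iff endpoint signs
agree) for GraphML rendering.

## 3. Survival stratification by optimal cutoff

`km_fit()` is the product-limit estimator; censored patients leave risk
sets without contributing events.  `logrank_test()` is the two-group
Mantel–Haenszel test with hypergeometric variances and a $\chi^2_1$
p-value; with no events it returns $\chi^2 = 0$, $p = 1$.  Median
survival uses the *first time with* $\hat S \le 0.5$ convention, and the
median difference is reported as undefined whenever either group's curve
never reaches 0.5 — not as 0.

`best_cutoff_stratify()` scans every distinct observed marker value as a
cutoff (high group strictly above), keeps those where both groups hold at
least `floor(min_group_frac · n)` patients, and returns the cutoff with
the minimal log-rank p (ties → smaller cutoff).  Choices made here:

* `min_group_frac = 0.2` bounds the scan to the 20th–80th percentile
  band, the usual "best expression cutoff" convention.
* **No multiple-testing correction** across scanned cutoffs — this
  mirrors the established procedure.  The minimum over ~n correlated
  tests is optimistic: under a null marker its "significant at 0.05" rate
  is well above 0.05 (the suite measures this on null simulations).  The
  number of cutoffs scanned is always reported so readers can judge that
  optimism; treat the best-cutoff p as a ranking device, not a calibrated
  error rate.
* **Ratio markers.** For a two-gene ratio, patients with both genes at
  zero are excluded with a logged reason (the ratio is undefined), and a
  zero denominator with positive numerator yields +∞.  Infinite values
  participate in ranking and group assignment by order only — they are
  never used arithmetically — which keeps those patients in the analysis
  without inventing a pseudocount.  How to rank such patients is genuinely
  undetermined by the data; ranking them top is the only choice consistent
  with "highest ratio".
* Spearman correlations (on the uncensored subset, where survival time is
  exact) use mean ranks for ties and the t-approximation with n−2 df for
  the p-value at every n.  For the cohort sizes this targets (n ≥ 100)
  the approximation is accurate; below n ≈ 10 an exact method would be
  preferable, which is a documented limitation rather than a code path.

## 4. What the generators emulate — and what they do not

`simulate_model()` builds a bipartite model with `n_currency` designated
hub metabolites included in each reaction independently with probability
`currency_prob`, plus a backbone of uniformly drawn non-hub metabolites.
Defaults: 200 metabolites, 300 reactions, 250 genes, 6 hubs,
`currency_prob = 0.3`.  The free structural parameters were set once for
realism: `reaction_size = (2, 2)` non-hub participants (a
substrate/product backbone pair; with ~1.8 hubs per reaction on average a
reaction carries about four metabolites, as in curated genome-scale
models) and `genes_per_reaction = (1, 3)`.  Wider backbones at these
fixed model dimensions produce gene projections far denser than any real
model's — a 250-gene network where random gene sets are themselves
clustered, which no practitioner would accept as a stand-in for a
genome-scale model.  The hub tier is 3 % of metabolites at the defaults,
so the network used for planting removes the top 3 % — inside the 2–10 %
band used in practice.

`simulate_de()` plants a breadth-first ball of `cluster_size` genes
around a random seed gene (guaranteeing a connected, high-clustering
target, which is what the statistic is designed to detect), with
`log2fc ~ ±Normal(effect, 0.5)`, `p ~ U(0, p_planted)`, against a
`Normal(0, noise_sd)` / `U(0,1)` background; `noise_sd = 0.5` and
`p_planted = 0.01` keep background selections rare at the thresholds of
interest without making them impossible.

`simulate_cohort()` draws log-normal per-gene expression (defaults:
meanlog 1.5 for GCK — mostly low, as its RSEM distribution in liver
tumors is; 5 for HK2 — widely expressed; sdlog 1.5), an exponential death
time with rate `base_hazard · exp(−beta · z)` where `z` is the
standardized log ratio (+1 pseudocount, used *only* inside the simulator
so the latent model is defined at zero expression), independent
exponential censoring, and observed time `min(death, censoring)` rounded
to 0.1 months with a 0.1 floor.

Real data differ in ways the generators deliberately ignore: metabolite
reuse is power-law rather than uniform-plus-hubs, expression is
correlated across genes and confounded with stage and batch, censoring is
rarely independent of prognosis, and DE effect sizes are not homogeneous
within a pathway.  Passing the simulation suite therefore shows the
*procedures* are correct and calibrated under their stated assumptions —
not that any particular biological dataset will show coherent clusters or
prognostic ratios.

## 5. Test and calibration problem sizes

The suite exercises: exact oracle equality for clustering (200 random
graphs ≤ 12 nodes) and for all three projections (50 random models ≤ 30
reactions); null calibration of MC on a 200-node random graph (500
repeats; mean of the first 200 and the |MC| > 1.96 rate); planted-cluster
detection at generator defaults (seed 42, 1000 null draws) plus 100
paired planted-vs-random trials; Kaplan–Meier against hand-computed
curves and the log-rank p against a 10,000-permutation null on 100
cohorts of 20–40 patients; ratio-vs-single-gene power over 20 simulated
cohorts and the null optimism rate over 40; and byte-identity of every
pipeline output across repeated runs (no timestamps are ever written into
results — provenance records carry config, seeds and input checksums
instead).

## 6. Known limitations

* Only average clustering is implemented as the coherence measure; other
  subgraph statistics (density, component counts) would slot into the
  same null machinery but are out of scope.
* The null model is size-matched uniform sampling; it does not preserve
  the degree distribution of the observed set, so part of a high MC can
  reflect the set's degree profile rather than its cohesion.
* Compartments are kept verbatim from the model file; the same chemical
  species in two compartments is two nodes.
* The best-cutoff p-value is optimistically biased by construction (see
  §3); comparisons *between* markers on the same cohort are the intended
  use.
* The SBML importer covers species/reactions and fbc or notes-style gene
  associations, which is sufficient for the published genome-scale
  models; it is not a general SBML toolkit.
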