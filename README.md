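# metcoherence

Metabolic network coherence scoring and optimal-cutoff survival
stratification for expression data.

## What this package is for

Two questions recur when a transcriptomic perturbation touches cell
metabolism:

1. **Are the differentially expressed genes metabolically connected?**
   A list of regulated genes may scatter across a genome-scale metabolic
   model, or it may concentrate on a few linked pathways.  This package
   quantifies that concentration as the *metabolic network coherence*
   **MC**: project the bipartite metabolite–reaction network (the
   stoichiometric matrix *S*) into a gene-centric graph *G* via the
   gene–reaction associations, take the subgraph of *G* spanned by the
   gene set *S*, and compute its average clustering coefficient *C*.
   MC is the z-score of *C* against size-matched gene sets drawn
   uniformly at random from *G*:

   MC = (C_obs − ⟨C_null⟩) / sd(C_null)

   so MC says how many standard deviations away from randomness the
   observed clustering is.  Ubiquitous *currency metabolites* (H₂O, ATP,
   cofactors) are trimmed first by a degree percentile, since their
   connectivity obscures pathway structure; the percentage removed and
   the fold-change threshold defining the gene set are scan parameters.

2. **Does a gene — or a two-gene expression ratio — stratify patient
   survival?**  For a cohort with RSEM expression and overall survival,
   the package scans all admissible expression cutoffs, compares the
   resulting high/low groups with a Kaplan–Meier / log-rank test, and
   reports the best-separating cutoff (the Protein Atlas "best cutoff"
   convention).  Ratio markers such as *GCK*/*HK2* — the hexokinase
   isoenzyme switch of hepatocellular carcinoma — are first-class:
   patients with both genes undetectable are excluded (the ratio is
   undefined) and a zero denominator yields +∞, ranked above all finite
   values.  Rank correlations with survival are computed on the
   uncensored subset.

A synthetic-data module generates metabolic models with planted currency
hubs, DE tables with a planted network-adjacent cluster, and cohorts
whose hazard depends on the log expression ratio of two genes, so the
whole pipeline is testable without external downloads.

## Worked example

```r
library(metcoherence)

model <- simulate_model(seed = 42)          # or read_model_json()/read_model_sbml()
cur   <- currency_metabolites(metabolite_graph(model), 3)
gg    <- gene_graph(model, reaction_graph(model, cur))
de    <- simulate_de(gg, seed = 42)         # or read_de_table()
genes <- select_genes(de, log2fc_min = 3, p_max = 0.05)
coherence_z(gg, genes, n_random = 1000, seed = 1234)
```

```
Metabolic network coherence
  genes mapped: 11 (0 unmapped)
  observed C:   0.7475
  null C:       0.0776 (sd 0.1214, 1000 draws, seed 1234)
  MC (z-score): 5.5178
```

The 11 selected genes form a subgraph whose clustering (0.75) is 5.5
standard deviations above random same-size gene sets: the expression
change is strongly organised along metabolic connections.
`coherence_scan()` repeats this over a grid of fold-change thresholds and
currency percentages, and `extract_subnetwork()` exports the spanned
network with up/down node signs and co-/inverse-regulation edge labels.

```r
coh <- simulate_cohort(beta = 1, seed = 42)  # or read_cohort()
best_cutoff_stratify(coh, ratio_values(coh, "GCK", "HK2"))
```

```
Optimal-cutoff stratification: GCK/HK2
  cutoff 0.004664: high n=240, low n=60 (181 cutoffs scanned)
  log-rank chi2 = 109.239, p = 1.44e-25
  median survival high/low: 45.7 / 6.9 months; delta 38.8
```

Patients with a high GCK/HK2 ratio live a median 38.8 months longer in
this simulated cohort; the p-value is the minimum over 181 scanned
cutoffs and is reported uncorrected, with the scan count, as the
convention dictates.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","metcoherence.R",package="metcoherence"))')" \
    simulate --seed 42 --out-dir study
```

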