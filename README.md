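# phycoassembly

Community-assembly analysis for host-associated microbiomes — built for
the recurring question in phycosphere (alga-associated) and similar
systems: **does the host select microbial *taxa*, or only microbial
*functions*?** When functions are selected deterministically but the
taxa filling them are interchangeable, communities look taxonomically
divergent yet functionally convergent, and species-level assembly looks
neutral. `phycoassembly` packages the statistics needed to test this on
a sample-by-taxon table, together with a ground-truth synthetic
generator so every stage can be validated end to end.

For microbial ecologists working with amplicon/metagenomic count
tables; all inputs are plain TSV (samples as rows), Newick trees, and
YAML/R-list configs.

## What it computes

* **Sloan neutral community model** (`fit_ncm`): a taxon with
  metacommunity relative abundance *p* is detected above limit *d* in a
  fraction `1 − I_d(Nm·p, Nm·(1−p))` of local communities of size *N*
  with immigration rate *m*; the single dispersal parameter *Nm* is
  estimated by bounded least squares over taxa, with R², a
  1,000-replicate taxon bootstrap CI (`bootstrap_ncm`), and
  above/within/below classification against a Wilson envelope
  (`classify_partitions`). Returns a classed model object with
  `print`, `summary`, `coef`, `predict`, `plot`, `fitted`, `residuals`
  methods.
* **Co-occurrence networks** (`correlation_network`): Spearman
  thresholding (default |ρ| ≥ 0.75, p ≤ 0.01), topology metrics
  (`network_metrics`), stability under random node loss
  (`robustness`: largest-component fraction after removing 50% of
  nodes, 100 repetitions), and hub dependence (`vulnerability`:
  maximal relative contribution of a node to global efficiency), plus
  high-weight edge extraction with family-pair counts
  (`high_weight_edges`).
* **Diversity and ordination**: richness/Shannon/Pielou/Faith's PD
  (`alpha_diversity`), Bray-Curtis and binary Jaccard
  (`beta_diversity`), PCoA (`pcoa_ordination`).
* **Permutation statistics from their definitions**: `anosim_test`,
  `permanova_test`, `mantel_test` — seeded, with exact exhaustive
  enumeration on small designs and the (1+b)/(1+m) p-value convention.
* **Taxonomy–function decoupling** (`decoupling_analysis`): paired
  comparison of taxon-space vs function-space Bray-Curtis, Mantel
  correlation between the two, group statistics on both.
* **Core/accessory/specific partitioning** (`partition_taxa`,
  `intersection_counts`): exact UpSet-style subset counts under an
  explicit detection rule.
* **Synthetic generators**: `generate_neutral_dataset` (Moran-type
  death/immigration-or-birth process, compiled, seeded) and
  `generate_redundant_strains` (deterministic guild filter + stochastic
  within-guild taxon lottery) with all ground truth recorded.
* **One-config pipeline** (`run_pipeline`): all stages, per-stage
  derived seeds, TSV + JSON report.

## Worked example

Six synthetic host strains that share a functional target but draw
taxa stochastically from redundant guilds (redundancy 8):

```r
library(phycoassembly)
ds <- generate_redundant_strains(n_strains = 6, n_guilds = 20, redundancy = 8,
                                 samples_per_strain = 6, seed = 42)
groups <- setNames(ds$metadata$group, rownames(ds$metadata))
dec <- decoupling_analysis(ds$abundance, ds$function_table, groups,
                           n_perm = 999, seed = 42)
```

```
median Bray-Curtis  taxa: 0.587   functions: 0.021
Mantel r = 0.093, p = 0.075
ANOSIM R  taxa: 1.000 (p = 0.001)   functions: 0.009 (p = 0.427)
```

Taxonomic composition separates the strains completely (ANOSIM R = 1)
while functional profiles are statistically indistinguishable
(R ≈ 0, p = 0.43) and uncorrelated with taxonomy (Mantel p > 0.05) —
the decoupling signature, produced here by construction.

Fitting the neutral model to 50 communities simulated at N = 10,000,
m = 0.1:

```r
nd <- generate_neutral_dataset(N = 10000, m = 0.1, n_samples = 50, seed = 42)
fit <- bootstrap_ncm(fit_ncm(nd$abundance), n_boot = 1000, seed = 42)
summary(fit)
```

```
Sloan neutral community model fit
  Nm = 1355  (N = 1e+04, m = 0.1355, detection limit d = 0.0001)
  R^2 = 0.922 over 500 taxa, 50 samples
  bootstrap 95% CI for Nm: [1290, 1422]  (1000 replicates)
  taxa vs the 95% neutral envelope:
    above  150
    within 339
    below  11
```

The high R² reflects genuinely neutral assembly. Note that the fitted
Nm sits above the generating N·m = 1,000: the Sloan continuous
approximation systematically overestimates dispersal on finite-N
Moran-process data (see the methods vignette,
`vignettes/community-assembly.Rmd`, for the decomposition of this
offset). Fitted Nm values are best read as an effective dispersal
index.

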