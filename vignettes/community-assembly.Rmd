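---
title: "Methods: neutral models, network stability, and taxonomy-function decoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neutral models, network stability, and taxonomy-function decoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoassembly)
```

`phycoassembly` analyses how host-associated microbial communities
assemble, built around a question that recurs in phycosphere and other
host-microbiome systems: is community membership selected
deterministically by the host, or does it drift stochastically while
only the community's *function* is constrained? The package provides the
statistical machinery to ask that question of a sample-by-taxon table —
and, because the answer hinges on subtle model fits, a synthetic
generator whose ground truth is known, so every stage can be validated
before it touches real data.

## The Sloan neutral community model

The core estimator is the Sloan neutral model for prokaryotic
communities. Local communities of fixed size $N$ assemble from a shared
metacommunity; at each replacement event a random individual dies and is
replaced, with probability $m$, by an immigrant drawn from the
metacommunity (taxon $k$ with probability $p_k$), otherwise by
reproduction of a local individual. Under the model's continuous
(large-$N$, small-$m$) approximation, the local relative abundance $x_k$
of a taxon with metacommunity abundance $p_k$ is Beta-distributed,

$$x_k \sim \mathrm{Beta}\!\big(Nm\,p_k,\; Nm\,(1-p_k)\big),$$

so the probability of *detecting* the taxon above a detection limit $d$
is $1 - I_d(Nm\,p_k, Nm\,(1-p_k))$, with $I$ the regularized incomplete
beta function (`ncm_predict()`). `fit_ncm()` estimates the single
dispersal parameter $Nm$ by bounded least squares of this prediction
against the observed occurrence frequencies over taxa, reports
$R^2 = 1 - SS_{res}/SS_{tot}$, and `bootstrap_ncm()` attaches a
percentile confidence interval from resampling taxa — the fit's
observation units — with 1,000 replicates by default.
`classify_partitions()` wraps a Wilson binomial envelope around the
prediction and labels taxa `above`/`within`/`below`, the usual reading
of which taxa are host-selected or dispersal-limited relative to
neutrality.

Conventions that the literature leaves implicit are explicit,
logged arguments here:

* $N$ defaults to the mean per-sample total count, $d$ to $1/N$; a table
  of relative abundances is rejected unless $N$ is supplied, because
  silently normalised input would corrupt the $N$ estimate.
* The fit is on raw (unbinned, unweighted) frequencies.
* The optimizer minimises the SSE over $\log Nm$ on $(10^{-3}, 10N]$
  with a three-segment multi-start; log scaling keeps the optimum off
  the boundary, and the objective is unimodal in practice.
* Bootstrap refits that fail are tolerated up to a 20% failure rate,
  beyond which an error reports the rate rather than returning a
  quietly truncated interval.

### What the generator guarantees, and a known limitation

`simulate_local_communities()` implements the Moran-type event process
above *exactly* (in compiled code, seeded through R's RNG). Its
stationary count distribution can be derived in closed form: detailed
balance gives a beta-binomial with scale parameter $m(N-1)/(1-m)$, which
approaches the Sloan parameter $Nm$ only as $m \to 0$. Two further gaps
separate the fitted value from $N \cdot m$ on finite data: the
continuous beta integral at $d = 1/N$ is only an approximation to the
discrete probability of a zero count, and the regressor $p_k$ must
itself be estimated from the same samples (an errors-in-variables
effect). The practical consequence — visible in this package's own
tests — is that the fitted $Nm$ on Moran-simulated data sits
systematically *above* $N \cdot m$ at moderate immigration rates
(tens of percent at $m = 0.1$), even though the simulator is provably
at stationarity. The test suite therefore pins what the construction
actually guarantees: exact recovery on noiseless self-consistent input,
agreement with the exact beta-binomial stationary scale, and
monotonicity of the fitted $Nm$ in the generating $m$. Fitted dispersal
parameters should be read as an effective index of dispersal, not an
unbiased estimate of a mechanistic immigration probability — a caveat
that applies equally to published Sloan fits.

Burn-in: mean relative abundances relax on a timescale of $N/m$ events
and abundance variances on roughly $N/2m$; the default burn-in of $50N$
events is ample at $m \gtrsim 0.1$ for the community sizes used here
($N \le 10^4$) but should be raised toward several times $N/m$ when
simulating very low immigration rates.

## The redundant-strain generator

`generate_redundant_strains()` encodes the "function-first,
taxonomy-stochastic" hypothesis as a mechanism. All host strains share
one guild-level target composition (a lognormal over `n_guilds`
functional guilds — the deterministic functional filter). Within each
guild, each strain draws its own weights over the guild's `redundancy`
interchangeable taxa from a sparse symmetric Dirichlet (the taxon
lottery; concentration `lottery_alpha = 0.5`, chosen once as the sparse
regime in which different strains are dominated by different guild
members, producing strain-specific taxa without erasing shared ones).
Replicate samples are multinomial resamples at `depth` reads
(default 10,000, a typical amplicon depth), mimicking sequencing-depth
noise. Function tables come from `attach_functions()`, a guild-weighted
linear map; the default weights are binary (one function per guild), the
simplest structure that yields the decoupling signal.

What this emulates: neutral-like taxonomic turnover between hosts with
conserved functional profiles, replicate noise, and a tunable degree of
redundancy, with `redundancy = 1` as the coupled control in which taxon
and function spaces coincide. What it does not emulate: sequencing
artefacts (chimeras, primer bias), compositional correlations induced
by copy-number variation, temporal succession within a culture, or
partially overlapping guild membership. Passing tests on this generator
therefore demonstrate that the *statistics* behave as designed, not that
any particular real system is functionally redundant.

## Diversity, ordination and permutation statistics

Alpha diversity: richness, Shannon entropy, Pielou evenness
($J = H/\ln S$, defined as 0 for $S < 2$ so per-sample tables stay
total), and Faith's PD under the root-inclusive convention (branch
lengths on all paths from present leaves to the root), matching the
dominant amplicon toolchain behaviour; the choice is documented and
tested, including one-leaf trees. Beta diversity: Bray-Curtis on
abundances and *binary* Jaccard on presence/absence, from their
definitions; an all-zero sample pair is assigned distance 0 with a
warning rather than NaN. PCoA is classical Gower double-centering with
no Cailliez/Lingoes correction — negative eigenvalues are reported, not
hidden — and proportions explained are computed over positive
eigenvalues only.

ANOSIM, PERMANOVA (one factor) and the Mantel test are implemented from
their definitions rather than wrapped, because their permutation
machinery is load-bearing for the package's claims; the installed
community-ecology stack serves as an independent oracle in the test
suite instead. Shared conventions: the unbiased permutation p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$, which can never
be exactly zero; seeded permutation streams; and automatic exhaustive
enumeration whenever the requested permutation count covers all distinct
label assignments, so small designs give exact p-values. Ties in ANOSIM
ranks take average ranks. PERMANOVA permutes raw sample labels; with
Euclidean distances on univariate data its pseudo-F reduces to the
classical ANOVA F, which the tests assert to $10^{-10}$. The default
9,999 permutations balances p-value resolution against runtime and is a
plain argument everywhere.

## Co-occurrence networks and stability

`correlation_network()` applies the field's standard Spearman
thresholding ($|\rho| \ge 0.75$, $p \le 0.01$ by default), with the
t-approximation for the correlation p-value at $n \ge 10$ samples and
the exact small-sample null below that. Multiple-testing correction is
off by default — the raw-threshold convention — but any `p.adjust`
method can be switched on. Edge signs are stored so that reports can
*verify* rather than assume claims like "all interactions positive".
Constant taxa are excluded with a warning; they can never carry an
edge.

Stability metrics follow the definitions used in microbial network
studies:

* **Robustness**: remove $\lfloor fN \rfloor$ random nodes (default
  $f = 0.5$), record the fraction of survivors in the largest connected
  component, average over 100 repetitions. Isolated survivors count as
  singleton components, which is why the edgeless graph has robustness
  $1/\text{survivors}$ rather than 0; the studies this convention comes
  from report values in the same range. Robustness of the seed-averaged
  curve is non-increasing in $f$ on random graphs, but individual sparse
  graphs can deviate at extreme removal fractions — a property of the
  definition, not a bug.
* **Vulnerability**: global efficiency $E_{glob}$ is the mean inverse
  shortest-path length over unordered pairs (disconnected pairs
  contribute 0); node $i$'s vulnerability is
  $(E_{glob}(G) - E_{glob}(G-i))/E_{glob}(G)$ and the network's is the
  maximum — it can be negative for individual nodes whose removal
  *raises* efficiency, and is capped at 1.

Graph internals (BFS components and distances, triangle counts) are
implemented directly on the adjacency matrix; the installed graph
library is used only as a test oracle, keeping the dual-route check
honest.

## Partitioning and the pipeline

`partition_taxa()` classes taxa as core (detected in every group),
specific (exactly one group) or accessory (the rest), under an explicit
detection rule — count > 0 in at least `min_samples` samples of the
group, pooling replicates and timepoints by default, since published
"present in all groups" statements rarely state a replicate rule. With
a single group, core takes precedence and the specific set is empty.
`intersection_counts()` gives exact UpSet-style subset counts that
provably sum to the number of detected taxa.

`run_pipeline()` drives everything from one config (an R list or YAML
file) with a single global seed from which each stage derives its own
seed by hashing the stage name, so adding a stage never perturbs
another's random stream; the same config and seed reproduce every
reported number bit-identically. Each stage logs its input shape and
the defaults it filled in, so the conventions above are auditable in
any run.

## Problem sizes used in validation

The validation suite exercises: neutral simulations at $N = 10^4$ with
500 taxa and 50 samples (the scale at which dispersal recovery is
assessed) and $N \le 2000$ for property checks; a six-strain,
20-guild, redundancy-8 dataset of 36 samples for the decoupling
analyses; type-I error studies of 200 null replicates at 199
permutations; exhaustive permutation enumeration at $n = 6$; and
exact enumeration of all $\binom{9}{4}$ removal sets for the star-graph
robustness oracle. These sizes were chosen so that each check has the
statistical resolution it needs while the whole suite stays quick to
run routinely.
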