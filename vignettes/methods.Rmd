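---
title: "Methods: ensemble co-occurrence inference and food-web comparison for eDNA metabarcoding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble co-occurrence inference and food-web comparison for eDNA metabarcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Environmental DNA (eDNA) metabarcoding profiles whole communities from water
samples, but the read counts it produces are compositional: each sample sums
to its sequencing depth, so counts carry only relative information, and
amplification efficiency differs between taxa and primer sets. Naive
correlation of read counts across samples therefore produces spurious
associations. `ednaweb` implements the analysis chain used to infer species
co-occurrence networks from such data and to confront them with an
independently constructed food web: index transformation, ensemble
association scoring with a compositionality-aware permutation null, signed
network assembly under false-discovery-rate control, meta-web food-web
construction, topological characterization, and cross-network comparison.
A synthetic-community generator with planted associations provides ground
truth for validating every stage.

## From read counts to the eDNA index

For each primer set separately, counts are converted to within-sample
proportions $p_{ij} = c_{ij} / \sum_i c_{ij}$, and each OTU row is scaled by
its maximum: $I_{ij} = p_{ij} / \max_j p_{ij}$. Under the assumption that a
taxon's amplification efficiency is constant across samples, the unknown
efficiency multiplier cancels, and $I_{ij} \in [0, 1]$ tracks within-OTU
relative abundance across samples and is comparable between primer sets. An
all-zero OTU row maps to all zeros (0/0 is defined as 0 so the transform is
total; such OTUs are removed by the prevalence filter anyway). OTUs
amplified by two primer sets get the per-sample arithmetic mean of the two
indices; OTUs seen by one marker pass through unchanged.

Each analysis subset (early/late season by month; nearshore/offshore by a
distance-from-shore boundary) is indexed within the subset by default
(`index_scope = "subset"`): the subsetting precedes network construction,
so the row maximum is taken over the subset's samples. A `global` scope is
available since the original protocol does not state the order. The
prevalence filter (default: detected in at least 25% of the subset's
samples, presence being any nonzero count) is applied after subsetting and
before indexing. The nearshore boundary is deliberately a required
parameter: the source study states it inconsistently (1.2 km in the methods,
1000 m in the results), so both values ship as named presets
(`nearshore_presets()`) and neither is a silent default.

## Ensemble association scoring

Five measures are computed for every unordered OTU pair on the index
vectors: Pearson and Spearman correlations, Bray-Curtis dissimilarity
$\sum|x-y| / \sum(x+y)$, symmetrized Kullback-Leibler (Jeffreys) divergence
on pseudocount-renormalized vectors (pseudocount $10^{-8}$; symmetrization
makes the score well-defined for an unordered pair, the pseudocount makes it
finite with zeros), and plug-in mutual information in bits on
equal-frequency discretizations. The MI discretization uses 4 bins by
default, which keeps at least five expected observations per bin at the
20-60 sample sizes this design targets; ties are broken by stable sort on
sample order, and a constant vector carries zero information by convention
(forced splitting of identical values would fabricate some). Undefined
scores (constant vectors for correlations, two all-zero vectors for
Bray-Curtis) are skipped per metric and recorded, never imputed.

Candidate edges are the per-metric score tails: the `top_k` highest and
`bottom_k` lowest scoring pairs per metric (500/500 by default), ties at the
boundary resolved toward the lexicographically smaller pair. Directions
follow each metric's convention: correlations sign by the score;
dissimilarities sign by tail (low = co-presence, high = mutual exclusion);
mutual information is unsigned and contributes support only from its top
tail. When `top_k + bottom_k` exceeds the number of pairs a dissimilarity
can select a pair in both tails; such support is treated as unsigned, the
deterministic and conservative resolution. A pair survives to testing when
at least `min_support` (default 2) metrics selected it, its signed
directions are unanimous, and at least one signed metric gives it a sign —
unsigned support alone cannot, so a pair backed only by mutual information
and a both-tail dissimilarity is dropped.

## The ReBoot significance machinery

Each surviving candidate is tested against a permutation null designed for
compositional data. For each of `n_perm` (default 100) iterations, the two
OTUs' compositional profiles are permuted independently across samples, the
per-sample closure is recomputed over the whole community with the permuted
rows in place, the index max-scaling is re-applied, and the metric is
recomputed. Permuting a pair while re-closing the composition destroys the
pair's dependence but preserves the spurious correlation structure that
closure itself induces, which is what makes the null compositionality-aware.
The same permutations are scored by every supporting metric, so null
replicates are aligned across metrics.

Two numerical choices matter here. First, the tested statistic is evaluated
through the same renormalization functional as the null (the identity
permutation of the same code path): a permutation test requires the observed
and null statistics to be exchangeable under the null hypothesis. For
single-marker tables the compositional matrix is exactly column-stochastic
and this coincides with the plain index score; for ensemble tables (where
the merged composition is renormalized) it differs slightly, and using the
plain score there would systematically bias the shape-sensitive
dissimilarities. The edge table still reports the analysis-facing index
scores. Second, the p-value is the two-sided tail of a Gaussian fitted to
the null sample rather than an empirical rank: 100 permutations cap
empirical resolution at about 0.01, while Benjamini-Hochberg correction over
hundreds of candidates needs finer granularity.

Stability is screened with `n_boot` (default 100) bootstrap resamples of the
samples: an edge is kept only when the null mean lies outside the central
95% percentile interval of its bootstrap score distribution, per supporting
metric; an edge failing on any supporting metric is discarded. Per-metric
p-values are merged with Brown's method, the dependent-test generalization
of Fisher's: $X = -2\sum_i \ln p_i$ is referred to a scaled
$\chi^2$ with scale $c = V/(2E)$ and degrees of freedom $f = 2E^2/V$, where
$E = 2k$ and the variance $V$ is estimated empirically as the variance of
$X$ over the aligned null p-value replicates. The empirical estimate
replaces the textbook correlation polynomial because the aligned nulls are
already computed and handle the mixed metric types directly; with
independent metrics $V \to 4k$ and the method reduces to Fisher's, and with
perfectly duplicated p-values it returns the common p. Merged p-values are
BH-corrected within each network (the study reports networks per subset),
and edges with $q \le 0.05$ are retained, signed co-presence or mutual
exclusion.

Determinism: a single master seed is configured; per-pair RNG substreams are
derived by a stable polynomial hash of the pair's OTU ids, so results are
independent of iteration order and a rerun with the same configuration is
byte-identical.

## Food webs, topology and comparison

The meta-web approach takes a consumer-to-resource diet edge list (standing
in for database- and literature-derived diet records, resolved at the OTU
label's taxonomic rank with no fuzzy matching) and restricts it to the
detected, prevalence-filtered community. Nodes are all community OTUs —
isolated ones retained, since detected-species counts are what the food-web
node counts track. Edges point consumer to resource; the convention is
stored with the graph because directed path metrics depend on it. Trophic
levels: algae and fungi are level 1, invertebrates level 2, vertebrates take
their database-derived value, and an explicit metadata value always wins.
A co-occurrence edge is labelled trophic when its unordered pair appears in
the food web in either direction.

Topology reports follow the conventions needed to make the published
numbers internally consistent. Average neighbours counts distinct adjacent
nodes ignoring direction, so reciprocal consumer pairs count once:
$(2E - 2r)/N$ for a digraph with $r$ reciprocal pairs, exactly $2E/N$
undirected — the published food-web values fall below $2E/N$, which is what
identifies this convention. Density is $2E/(N(N-1))$ undirected and
$E/(N(N-1))$ directed. Eccentricities are computed over reachable nodes
only, following edge direction; the diameter is the maximum and the radius
the minimum positive eccentricity — the only convention under which a
directed food web with an apex consumer can have the published radius of 1.
Characteristic path length averages over ordered reachable pairs, and the
clustering coefficient averages local clustering over nodes of degree at
least 2 in the undirected projection. Displayed values are rounded half
away from zero at the table precision; internal values keep full precision.
Keystone candidates are the top-10 nodes by degree (closeness and
betweenness available as alternatives), with ties broken by closeness then
id; high centrality flags a candidate for ecological importance, not proof.

Cross-network comparison treats an edge as the unordered OTU pair and
ignores sign when matching across subsets (a pair positive in one subset
and negative in another still counts as shared; sign agreement is reported
separately), since overlap counts describe edge presence. Percentages are
displayed as half-up integer percents of the union. The abundance-degree
correlation uses each node's mean eDNA index over the subset's samples —
the analysis-facing abundance measure, not raw reads — against its degree,
with the two-sided t-test p-value.

## The synthetic generator and what it does (not) emulate

`generate_community()` builds latent log-abundances
$\log a_{ij} = b_i + \sum_g \lambda_{ig} e_{gj} + \sum_e \ell_e(i) f_{ej} +
\varepsilon_{ij}$: per-OTU baselines ($b_i \sim N(0, 1.2)$, a realistic
rank-abundance spread), optional shared environmental gradients with
random-sign loadings ($N(0, 0.15)$), planted pair factors, and Gaussian
noise (SD 0.5). A planted pair of strength $s$ shares a factor with loading
$1.8\,s$ (equal signs for co-presence, opposite for exclusion), a mapping
chosen so the latent Pearson correlation approximately equals $s$ at the
default noise levels. A configurable fraction of non-planted OTUs is
thinned to below 25% occupancy so the prevalence filter has real work.
Reads are multinomial per sample and marker, with probabilities
proportional to abundance times a lognormal per-OTU, per-marker
amplification efficiency, restricted to overlapping marker panels (defaults:
two markers covering 80% and 50% of OTUs, a 30% overlap, mirroring a
two-marker vertebrate design); per-sample depths are lognormal around
100,000 reads. The defaults mirror the study scale: 60 samples and ~120
OTUs.

The generator emulates compositionality, uneven amplification, panel
overlap, rarity and environmentally driven covariance. It does not emulate
sequence-level error, spatial autocorrelation of eDNA transport, age-class
mixtures or temporal dynamics — so passing recovery tests show the
inference machinery works on data satisfying its statistical assumptions,
not that those assumptions hold in any particular field dataset.

## Validation design and problem sizes

Three standardized experiments validate the engine
(`null_calibration()`, `pvalue_uniformity()`, `recovery_experiment()`);
they run the full pipeline from read sampling to network inference.

*Calibration null.* The error-rate experiments use fully independent
communities: no planted associations and no environmental gradients.
Gradients with random-sign loadings induce genuine abiotic associations —
exactly what co-occurrence networks are designed to detect — so they do not
belong in a false-positive count. On 20 independent 40-OTU, 60-sample
communities, the mean ratio of reported edges to candidate edges at
$q \le 0.05$ is the empirical false-discovery proxy (every reported edge is
false there); it comes out near 1-2%, well under the 10% the threshold
implies, because the stability screen discards most null candidates before
merging.

*P-value uniformity.* The per-metric ReBoot p-values are compared to the
uniform distribution by Kolmogorov-Smirnov distance over 200 pairs spread
across 10 independent replicate communities. Pairs within one community
share its compositional denominator — a dominant OTU's fluctuations
genuinely co-move every other OTU's relative abundance — so their p-values
are positively dependent, and a single-community KS statistic measures that
shared fluctuation (which varies several-fold between communities) rather
than the marginal calibration of the test. Spreading pairs across replicate
communities measures the marginal distribution; the residual deviation
(KS ~ 0.03-0.09) reflects the Gaussian tail approximation and the
third-party closure dependence that a pairwise permutation null cannot
remove, a known property of this family of methods.

*Recovery.* Twenty co-presence and ten exclusion pairs planted at strength
0.9 in a 120-OTU, 60-sample community are recovered with recall above 0.95
and sign accuracy 1.0 in both directions at the default configuration.

Problem sizes were chosen so each experiment completes in minutes on one
core at the protocol's full iteration counts (`n_perm = n_boot = 100`):
calibration ~2 minutes, uniformity ~40 seconds, recovery ~20 seconds.

## Known limitations

The per-metric tail selection bounds compute but means weak associations
supported by only one metric are never tested. Whether the original
protocol retained 500 edges per metric or overall is ambiguous in the
source; per-metric is implemented (the union interpretation is a config
switch away via `top_k`/`bottom_k`). The Gaussian-fit p-values are mildly
anticonservative in strongly dominated communities (see above); the
consensus, stability and BH layers keep the realized error rate low
regardless. Exact numerical replication of the original Cytoscape plugin's
outputs is a non-goal: its MI discretization and KLD pseudocount are not
recoverable from the published description, so this package's defaults are
declared, not asserted equivalent. Amplification-efficiency correction and
absolute abundance calibration are out of scope, as in the source protocol.
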