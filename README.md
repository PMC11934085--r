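# ednaweb

Co-occurrence networks and food webs from eDNA metabarcoding data.

## What this is for

Environmental DNA (eDNA) metabarcoding profiles whole communities — fish,
mammals, birds, invertebrates, algae — from water samples. Ecologists want
to read species *interactions* out of such surveys: which taxa co-occur
more (or less) often than chance across sites and seasons, whether those
co-occurrences correspond to known trophic links, and which taxa are
candidate keystones. Read counts, however, are compositional (each sample
sums to its sequencing depth) and amplification efficiency differs between
taxa, so naive correlations are biased. `ednaweb` implements the full
analysis chain for this problem:

* **eDNA index** — counts → within-sample proportions →
  `I[i,j] = p[i,j] / max_j p[i,j]`, a within-OTU relative abundance in
  [0, 1] comparable across samples and primer sets, with ensemble averaging
  of OTUs amplified by two markers.
* **Ensemble association inference** — five metrics per OTU pair (Pearson,
  Spearman, Bray-Curtis, symmetrized Kullback-Leibler, mutual information);
  per-metric score tails as candidates; edges kept only with ≥ 2 supporting
  metrics and unanimous sign.
* **ReBoot significance** — a permutation null that re-closes the
  composition after permuting each pair (so the null retains the spurious
  structure closure induces), bootstrap stability screening, Brown's method
  for merging the dependent per-metric p-values
  (`X = -2 Σ ln p_i` referred to a scaled chi-square with empirically
  estimated variance), and Benjamini-Hochberg FDR control, yielding a
  signed co-occurrence network (co-presence / mutual exclusion).
* **Meta-web food webs** — consumer→resource diet records restricted to the
  detected community, trophic-level assignment (algae/fungi = 1,
  invertebrates = 2, vertebrates from database values), and direction-blind
  matching of co-occurrence edges to trophic links.
* **Topology & comparison** — average neighbours, density, diameter/radius
  (reachable-only eccentricities), characteristic path length, clustering;
  degree/closeness/betweenness keystone rankings; edge overlap, sign
  fractions and abundance-degree correlations across spatial/temporal
  subsets.
* **Synthetic communities** — a generator with planted positive/negative
  associations, two overlapping marker panels, per-OTU amplification
  efficiencies and multinomial read sampling, plus ground-truth recovery
  scoring — first-class, tested code used to validate the engine.

## Worked example

```r
library(ednaweb)

# simulate a two-marker community with planted interactions
planted <- plant_random_edges(40, n_pos = 4, n_neg = 2, strength = 0.9, seed = 8)
params <- community_params(n_otus = 40, n_samples = 60,
                           planted_edges = planted, seed = 8)
truth <- generate_community(params)
tables <- sample_reads(truth)

# prevalence-filter, index, ensemble the two markers
filtered <- lapply(tables, prevalence_filter, min_prevalence = 0.25)
index <- Reduce(ensemble_index, lapply(filtered, compute_edna_index))
index
#> <index_table> 34 OTUs x 60 samples (markers: marker1, marker2)

# infer the signed co-occurrence network
net <- infer_network(index, cooc_config(seed = 8))
net
#> <cooc_network> 29 nodes, 43 edges (420 candidates, 377 unstable; community 34 OTUs)
head(net$edges[, c("otu_a", "otu_b", "sign", "support", "merged_p", "q_value")], 3)
#>    otu_a  otu_b       sign support     merged_p     q_value
#> 1 otu001 otu011  exclusion       5 0.0009137023 0.003801433
#> 2 otu003 otu032 copresence       5 0.0007416016 0.003801433
#> 3 otu004 otu007 copresence       5 0.0017380985 0.003801433

# how well did we do against the planted truth?
unlist(recovery_metrics(net, truth)[c("recall", "sign_accuracy")])
#>        recall sign_accuracy
#>             1             1

# food web from the planted meta-web, and network topology
web <- build_metaweb(planted_metaweb(truth, 1, 10), rownames(index$values))
tm <- trophic_match(net, web)
cat(sprintf("%d of %d edges (%d%%) match trophic records\n",
            tm$n_trophic, nrow(net$edges), tm$percent))
#> 6 of 43 edges (14%) match trophic records
topology_report(net)
#> <topology_report> (undirected)
#>   nodes 29  edges 43  avg. neighbours 2.966  density 0.11
#>   diameter 6  radius 1  CPL 2.7  clustering 0.4
```

Reading the numbers: of 34 OTUs surviving the 25% prevalence filter, 420
pairs were candidate edges (supported by ≥ 2 metrics with unanimous sign);
the bootstrap stability screen discarded 377 — under near-null conditions
most candidates are unstable, which is how the engine keeps false
discoveries rare — and 43 edges passed at q ≤ 0.05. All six planted
associations lie among them with the correct sign (`recall 1`,
`sign_accuracy 1`); the remaining edges mostly trace the shared
environmental gradients the generator builds in. Six edges match the
planted diet records, i.e., 14% of significant co-occurrences are
"trophic" — the same order as reported for real coastal communities, where
trophic links are a minority of significant co-occurrences.

For multi-subset studies, `run_pipeline()` drives the whole chain
(subsetting by month or distance-from-shore, per-subset filtering and
indexing, inference, food webs, topology, cross-subset comparison) from a
YAML config, writing edge tables, GraphML exports and a JSON report; a
thin CLI (`inst/scripts/edna-pipeline.R`) exposes each stage as a
subcommand (`simulate | index | infer | metaweb | topology | compare |
full`).

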