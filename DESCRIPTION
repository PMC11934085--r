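Package: ednaweb
Title: Co-Occurrence Networks and Food Webs from eDNA Metabarcoding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed species co-occurrence networks from environmental
    DNA (eDNA) metabarcoding OTU tables using an ensemble of five association
    metrics (Pearson and Spearman correlations, Bray-Curtis and symmetrized
    Kullback-Leibler dissimilarities, and mutual information) with a
    compositionality-aware permutation-renormalization (ReBoot) null model,
    bootstrap stability screening, Brown's method for merging dependent
    p-values and Benjamini-Hochberg control of the false discovery rate.
    Builds directed meta-web food webs from consumer-resource diet records
    restricted to the detected community, assigns trophic levels, computes
    network topology reports and degree/closeness/betweenness keystone
    rankings, and compares networks across spatial and temporal subsets
    (edge overlap, sign fractions, trophic-match fractions,
    abundance-degree correlation). Includes a synthetic-community generator
    with planted associations and a planted meta-web for validating the
    inference engine, and an end-to-end pipeline runner with deterministic
    seeding and machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
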