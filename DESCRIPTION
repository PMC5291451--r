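Package: seedcoex
Title: Seed-Centric Co-Expression Network Enrichment and Candidate
    Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds seed-centric gene co-expression networks from a
    compendium of expression datasets: per-seed correlate lists at a
    Pearson correlation threshold, an occurrence-ranked master transcript
    list, a Kolmogorov-Smirnov style running-sum enrichment score with a
    label-permutation null, and the seed50 intra-correlation statistic.
    The leading edge is cross-referenced against regulator-responsive and
    protein-protein-interaction gene sets with contingency statistics
    (one-sided Fisher exact, chi-square, EASE score), and recurrent
    candidate genes are prioritized by guilt-by-association pathway
    enrichment of their correlate lists. A synthetic-compendium generator
    with planted co-regulated modules, interaction edges, and annotations
    provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'contingency.R'
    'correlate.R'
    'crossref.R'
    'enrichment.R'
    'io.R'
    'network.R'
    'panel.R'
    'pipeline.R'
    'prioritize.R'
    'simulate.R'
    'utils.R'
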