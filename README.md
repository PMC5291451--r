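# seedcoex

Seed-centric co-expression network enrichment and candidate prioritization.

## The problem

Many proteins that modulate mitochondrial (or any organelle's) function are
not yet annotated as such. Because transcripts encoding functionally related
proteins are often co-regulated, a large, heterogeneous compendium of
expression datasets can nominate overlooked members of a cellular program: a
set of *seed* transcripts with known localization is used to query the
compendium for co-expressed transcripts, and genes that recur across many
seeds' correlate lists — yet are not themselves annotated — become
candidates. `seedcoex` implements this meta-analysis for anyone with a
collection of expression matrices, a seed gene set, and optional
cross-referencing resources (a regulator-responsive gene list, a
protein–protein interaction table, pathway term annotations, an independently
derived disease-module gene list).

## The method

1. **Correlate lists.** For each seed *s*, every gene *g* gets a combined
   Pearson correlation: per-dataset *r* values (computed where both genes are
   present and non-constant) are combined by a Fisher *z*-transform mean
   weighted by (samples − 3). Genes with *r* ≥ ρ (default ρ = 0.5, signed)
   form the seed's correlate list; seeds present in too few datasets are
   ineligible.
2. **Ranked master list.** All correlate lists are merged into a network and
   every transcript is ranked by its occurrence count across lists (ties:
   maximum *r*, then gene id).
3. **Running-sum enrichment.** Descending the ranked list, the walk gains
   √((N−G)/G) at each of the G seeds and loses √(G/(N−G)) at each non-seed,
   so it ends at 0. The walk's maximum is the enrichment score (ES); all
   transcripts at or before the earliest maximum are the *leading edge*
   (LE). Significance comes from B = 1,000 random reassignments of the seed
   labels over the fixed ordering, with the add-one estimator
   p = (1 + #{null ≥ observed})/(B + 1). The *seed50* statistic — the
   smallest top fraction of the list holding half the seeds — summarizes
   intra-correlation (smaller = tighter co-regulation).
4. **Cross-referencing.** Per-seed above-chance tests compare each list's
   seed-universe fraction with |U|/genome (one-sided Fisher exact,
   α = 10⁻⁴); LE enrichment of a flag set uses a 2×2 chi-square (with a
   seed-removed variant); interaction edges are filtered to those with
   exactly one annotated endpoint and the unannotated partners' LE
   over-representation is tested at partner-count thresholds 1, 2, 5, 10.
5. **Prioritization.** LE ∩ disease-module genes are re-queried and scored
   per required pathway term with the conservative EASE variant of the
   Fisher test (one gene removed from the overlap); candidates passing
   p ≤ 0.05 for every term are ranked by the summed −log₁₀ p.

A synthetic-compendium generator (`simulateCompendium`, `simulatePPI`,
`simulateAnnotations`) plants co-regulated modules of tunable strength,
interaction edges, and annotation sets, so the whole pipeline can be
validated against known ground truth.

## Worked example

```r
library(seedcoex)
sim <- simulateCompendium(simParams(
  nDatasets = 10, samplesPerDataset = 30, nGenes = 2000,
  moduleSpecs = data.frame(module_id = "mito", size = 100,
                           loading_mean = 0.5, loading_sd = 0),
  noiseSd = 1, seedOverlapFraction = 0.5, dropoutFraction = 0.5,
  rngSeed = 42))
truth <- simulateAnnotations(sim$truth, 0.8, 0.05, rngSeed = 43)
cfg <- pipelineConfig(rThreshold = 0.25, minSharedDatasets = 2,
                      genomeSize = 2000, rngSeed = 1)
res <- runPipeline(sim$compendium, seedSet(truth), cfg,
                   responsiveSet = regulatorResponsiveSet(truth))
res$profile
```

```
correlate: 50 seeds queried, 47 eligible
network: 852 nodes, 2108 edges
master list: 852 ranked transcripts
enrichment: max ES 176.5 at 120/852, seed50 6.57%, perm p 0.000999
above-chance: 39/47 seeds (83.0%)
LE responsive chi-square: p 1.669e-111 (all), p 2.935e-65 (seeds removed)
EnrichmentProfile: N=852, G=49, steps (4.048, -0.247)
  max ES 176.5 at position 120; leading edge 120 genes; seed50 = 6.57%
  permutation p = 0.000999 (B = 1000)
```

Reading the output: 47 of the 50 planted seeds were represented well enough
to yield correlate lists; the merged network ranks 852 transcripts. The walk
peaks at position 120, so the leading edge holds 120 transcripts, and half
the seeds sit in the top 6.6% of the list — far tighter than the ~50%
expected without co-regulation, and no random label assignment matched it
(p = 1/1001). 83% of seeds correlate with more seed-universe genes than the
2.5% chance expectation, and the leading edge stays strongly enriched for
planted regulator-responsive transcripts even after removing the seeds
themselves.

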