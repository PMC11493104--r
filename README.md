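# haplotrace

Mitochondrial phylogeography of biological invasions, end to end: given an
alignment of mtDNA sequences (e.g. a ~2.2 kb COI/tRNA-Leu/COII fragment)
and per-specimen geographic metadata, `haplotrace` collapses specimens into
haplotypes, classifies each haplotype by its geographic distribution,
computes per-population diversity statistics, tests population structure
with AMOVA, and summarizes relationships with a minimum-spanning haplotype
network and a bootstrapped neighbor-joining tree. It is aimed at the
classic invasion-biology question: *which part of the native range did the
invasive populations come from?*

## The statistics at the core

* **Haplotype classification.** A haplotype found in two or more countries
  and carried by at least one specimen from an introduced population is
  *invasive* (labelled `Hap-A`, `Hap-B`, ... by global abundance); one
  found in two or more countries but never in an introduced population is
  *shared native*; anything confined to a single country is *private*.
* **Diversity.** Haplotype diversity
  `H = n/(n-1) * (1 - sum(p_i^2))`, nucleotide diversity
  `pi = mean pairwise differences / L`, and maximum pairwise divergence
  (%), per group.
* **AMOVA.** Single-level variance decomposition from pairwise
  substitution counts (`delta^2 = d`), variance components
  `sigma2_a`, `sigma2_w`, `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`, and
  a seeded permutation p-value with the add-one estimator.
* **Network.** The union of all minimum spanning trees over haplotypes
  (deterministic, no tie-breaking), with clusters defined by deleting
  edges of `>= cut` substitutions.
* **Tree.** Neighbor joining (via `ape`) with seeded column-resampling
  bootstrap and outgroup rooting.

A seeded synthetic-data generator (`sim_config()`, `simulate_dataset()`)
produces invasion-structured datasets — divergent native regional pools,
bottlenecked introduced populations dominated by one exported haplotype,
rare one-step singletons, a distant outgroup — together with a truth table,
so the entire pipeline is testable without field data.

## Worked example

```r
library(haplotrace)

cfg <- sim_config(seed = 101)                 # default study conditions
sim <- simulate_dataset(cfg, dir = "results/data")
res <- run_pipeline(sim$alignment, sim$meta, outdir = "results/pipeline",
                    seed = 101, n_perm = 1000, bootstrap = 200)

res$catalog
#> <haplotype_catalog> 26 haplotypes, 272 analysis specimens (1 excluded), L = 2181
#>   invasive: 4  shared_native: 0  private: 22

max(res$clusters)                             # network clusters at cut = 6
#> [1] 3

res$amova$NativeC$phi_st                      # structure across source-country locations
#> [1] 0.1741176
```

The catalog reports the four exported haplotypes as invasive and everything
region-restricted as private; the network separates the three native
regions as three clusters; the AMOVA finds significant structure among the
source country's locations (p ≈ 0.001 at 1000 permutations). The bundle in
`results/pipeline/` contains `haplotypes.fasta`, `summary_table.tsv`,
`classification.tsv`, `amova_<country>.tsv`, `network_edges.tsv`,
`network_nodes.tsv`, `tree.nwk`, and `run.json` (all parameters and seeds;
reruns are byte-identical).

The numbered scripts under `analysis/` run the full study: `01_simulate.R`
and `02_pipeline.R` as above, `03_survey_recomputation.R` (rebuilds the
published global survey's per-country count structure and recomputes its
summary statistics), `04_amova_calibration.R` (worked AMOVA instance and
permutation type-I error), `05_recovery_study.R` (replicate recovery of
classification, clusters and the bottleneck diversity signature).

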