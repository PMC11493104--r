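---
title: "Tracing invasive populations from mitochondrial haplotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing invasive populations from mitochondrial haplotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotrace)
```

## The problem

When an agricultural pest invades new regions, locating the geographic
source of the invasive populations is a prerequisite for biological control
and quarantine policy. Mitochondrial phylogeography is the classical tool:
because mtDNA is clonal and maternally inherited, field specimens can be
collapsed into haplotypes whose geographic distribution carries the
invasion's signature. A native range accumulates deep, regionally structured
variation; introduced populations pass through founder bottlenecks and
typically carry one or a few haplotypes exported from a single source
region. `haplotrace` implements the complete analysis chain for this
setting: haplotype collapsing and geographic classification, per-population
diversity statistics, analysis of molecular variance (AMOVA), a
minimum-spanning haplotype network, and a neighbor-joining (NJ) tree with
bootstrap support — plus a seeded generator of synthetic invasion datasets
so that every stage can be verified end to end without access to field
data.

## Haplotypes and their classification

Specimens with identical sequences over the trimmed, unambiguous alignment
window share a haplotype. Identity is exact string equality: because every
specimen with any ambiguous or unconfirmed site is removed up front
(`filter_and_trim()`, which treats IUPAC codes, `N`, and gaps alike), no
fuzzy matching is defined or needed. Interception specimens — flies seized
at ports of entry, with a country of record but no confirmed field
population — are catalogued but excluded from abundance ranking,
classification, diversity statistics and AMOVA; they re-enter only in the
network and tree, where their placement is informative.

Classification is a three-way partition by geographic distribution:

* **private** — found in exactly one group (country or location). A
  haplotype confined to a single *introduced* country is still private:
  it says nothing about origins.
* **invasive** — found in two or more groups *and* carried by at least one
  specimen from an introduced population.
* **shared_native** — found in two or more groups but never in an
  introduced population.

Invasive haplotypes are labelled `Hap-A`, `Hap-B`, ... in decreasing order
of global abundance (ties broken by first occurrence in input order, so
labelling is deterministic); all other haplotypes get zero-padded numeric
labels.

## Diversity statistics

For a group with haplotype counts $c_i$, $n = \sum_i c_i$:

* haplotype (gene) diversity, with small-sample correction:
  $H = \frac{n}{n-1}\bigl(1 - \sum_i \hat p_i^2\bigr)$, $\hat p_i = c_i/n$.
  The corrected form is used because it reproduces, exactly at print
  precision, the published per-country values that are fully determined by
  their printed count vectors (six independent cells: 0.4167, 0.2195,
  0.5385, 0.6765, 0.2279, 0.2222 — recomputed by
  `analysis/03_survey_recomputation.R` and the test suite); the uncorrected
  form does not.
* nucleotide diversity per site:
  $\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij} / L$, mean pairwise
  substitution count over all sequence pairs, no small-sample correction.
* maximum pairwise divergence: $\max_{i<j} d_{ij}/L \times 100$.

A group of a single specimen reports all three statistics as missing
values, not zeros: the estimators are undefined at $n = 1$, and an
undefined estimator must not masquerade as an observation of zero
diversity (a *monomorphic* group with $n \ge 2$, by contrast, genuinely has
$H = \pi = 0$). Report output is rounded to 4 decimals for $H$, 6 for
$\pi$, 3 for divergence percentages, 1 for percentages of specimens.

On the residual question of deletion strategy for ambiguous sites in
$\pi$: it is moot here, because the pipeline removes ambiguous specimens
entirely before any distance is computed.

## AMOVA

`amova_one_level()` partitions molecular variance among and within
populations from pairwise substitution counts, using the standard
convention for sequence data that the number of differences $d_{ij}$ *is*
the squared distance $\delta^2_{ij}$. With $N$ specimens in $P$
populations of sizes $n_p$:

$$SS_{total} = \tfrac1N \sum_{i<j}\delta^2_{ij}, \qquad
  SS_{within} = \sum_p \tfrac1{n_p} \sum_{i<j \in p}\delta^2_{ij},$$

$\sigma^2_w = SS_{within}/(N-P)$,
$\bar n = (N - \sum_p n_p^2/N)/(P-1)$,
$\sigma^2_a = (SS_{among}/(P-1) - \sigma^2_w)/\bar n$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. The test suite checks
the decomposition against an independent oracle that embeds each sequence
as a one-hot vector scaled so squared Euclidean distance equals the
substitution count, and computes sums of squared deviations from (group)
centroids directly.

The permutation null shuffles individuals across populations with group
sizes fixed; the p-value uses the add-one estimator
$p = (1 + \#\{\Phi^* \ge \Phi\})/(1 + n_{perm})$, which cannot return zero
and under exchangeability gives exactly
$\Pr(p \le \alpha) = \lfloor \alpha(n_{perm}+1)\rfloor/(n_{perm}+1)$. The
default is 1000 permutations with a mandatory seed. If all pairwise
distances are zero the decomposition is degenerate and $\Phi$ is reported
as 0 with an explicit flag (and no p-value) rather than NaN, to keep
downstream tabulation stable. One published within-country table prints a
within-population variance component that is inconsistent with its own
printed $SS_{within}/df$ (1.745 vs 157.066/87 = 1.805); the companion
table for the second country is exactly consistent with
$\sigma^2_w = SS_{within}/df$ (1387.408/46 = 30.161), so that estimator is
the implemented one and the discrepancy is documented rather than fitted.

Only single-level AMOVA is provided: with essentially no haplotype sharing
between native countries, a continent-wide hierarchical analysis is not
meaningful, and the pipeline runs one AMOVA per country sampled at two or
more locations.

## Minimum-spanning network

The haplotype network is the union of all minimum spanning trees of the
complete graph over haplotypes weighted by substitution count: an edge
$(u, v)$ of weight $w$ belongs to the network iff $u$ and $v$ cannot be
connected using only edges of weight $< w$. This formulation needs no
arbitrary tie-breaking — every tied alternative appears — and is therefore
deterministic and invariant to input order. A relaxation parameter
$\varepsilon$ (default 0, matching the plain minimum-spanning construction)
loosens the threshold to $< w - \varepsilon$ per Kruskal round for
exploratory use. The test suite verifies the union-of-MSTs identity by
exhaustively enumerating spanning trees on graphs of up to 7 nodes.

Clusters "separated by long mutational branches" are connected components
after deleting edges of weight $\ge$ `cluster_cut`. The cut is a
configuration value (default 6 substitutions), not an inferred quantity:
what counts as a long branch is a judgement the analyst must own.

## Neighbor-joining tree

Tree inference is delegated to `ape::nj()` (NJ is exact on additive
distance matrices, which the suite verifies on random additive trees of up
to 8 taxa); this package adds clamping of negative branch lengths to zero
(raw values retained as an attribute), a seeded column-resampling bootstrap
whose supports are counted as bipartition recovery percentages, rooting on
the midpoint of the outgroup's pendant edge, and newick serialization with
supports as internal node labels. Distances default to uncorrected
p-distances; at the divergences involved here (well under 1% within the
ingroup, 5–6% to the outgroup) model correction is immaterial, and a
Jukes–Cantor-style correction was deliberately left out rather than
implied. Maximum-likelihood inference is out of scope: on these data ML
and NJ topologies agree except for shallow within-population placements,
so NJ is the supported surface.

## The synthetic generator

`sim_config()` / `simulate_dataset()` generate datasets with the
statistical structure this analysis assumes, under an infinite-sites
approximation: every mutation hits a globally unique site, so Hamming
distance equals the number of mutation events and all truth distances are
exact — which is what makes the generator usable as an oracle.

* A random root sequence of `L = 2181` bp; each of 3 regional ancestors
  differs from it at `ceiling(12/2) = 6` unique sites, so regional pools
  are pairwise at least 12 substitutions apart (`between_region_steps`).
* Each region's pool is a star radiation: 5, 14, or 19 haplotypes
  (echoing observed per-country haplotype counts), each derived directly
  from the regional ancestor by 1–3 substitutions. Pool frequencies follow
  a geometric series (ratio 0.5): one common type plus progressively rarer
  ones, the skew real surveys show. A star rather than a nested tree keeps
  every within-region distance at most 6 while every between-region
  distance is at least 12, so cluster recovery at cut 6 is exact by
  construction rather than probabilistic.
* Native sample sizes default to one country of 9, one of 49 over three
  locations, and a source country of 93 over three locations — the
  sampling depths of the motivating survey. Non-hub locations draw from
  location-specific subsets of the pool (ancestor shared), producing real
  among-location structure for the AMOVA.
* The source country's first location is the export hub: its specimens are
  drawn like an introduced population (dominance 0.9 on the top exported
  haplotype), and all 4 exported haplotypes are guaranteed present there —
  they are, by construction, the types that were exported. This guarantee
  is what makes classification recovery exact: an exported haplotype
  sampled in any introduced country is then automatically in two or more
  countries with an introduced carrier.
* Introduced countries (default sizes 60, 31, 17, 13) draw the top
  exported haplotype with probability 0.9 (matching the ~90% dominance
  observed in introduced populations), the rest geometrically from the
  remaining exported types; with probability 0.03 a specimen instead
  carries a brand-new one-step derivative of its drawn haplotype — the
  rare private singletons introduced populations show.
* An outgroup record at 5.6% divergence (within the 5.4–5.8% range typical
  of the sister species) is written with status `outgroup` and excluded
  from population statistics automatically.

What the generator does *not* emulate: coalescent noise within haplotype
classes, recurrent or back mutation (excluded by infinite sites),
recombination (mtDNA is clonal), migration between native regions, and
selection. Passing recovery tests on these data therefore demonstrates
that the pipeline's logic is correct under the stated model — not that the
model captures every feature of real invasion data, where homoplasy and
incomplete sampling can blur cluster boundaries.

## Numerical and degenerate-case choices

* Coordinates are 0-based half-open everywhere in windowing code.
* Metadata joins are strict by default: a specimen present in exactly one
  of alignment/metadata is an error unless `allow_unmatched = TRUE`,
  because silent drops corrupt frequency tables.
* The trimming window is a user input: only the final trimmed length is a
  known quantity, not its coordinates within the raw amplicon.
* All stochastic stages (AMOVA permutations, bootstrap, simulation) take
  explicit seeds, restore the caller's RNG state, and are bit-reproducible;
  the pipeline records every seed in `run.json` and reruns are
  byte-identical.
* Statistics undefined at the observed sample size are `NA`, never 0.

## Problem sizes used in the checks

The bundled analyses and tests run at deliberately modest scale: the
default synthetic dataset has 273 specimens; the recovery study uses 30
replicates (100 in the test suite); AMOVA calibration uses 500
exchangeable datasets of 12 specimens at 99 permutations; the
union-of-MSTs identity is enumerated exhaustively up to 7 nodes; NJ
exactness uses 100 random additive matrices of up to 8 taxa. These sizes
make the full verification suite run in well under a minute per module
while leaving the statistical assertions sharp.

## Known limitations

* The invasive/private rule is sensitive to sampling: a genuinely exported
  haplotype sampled in only one country is (correctly, per the
  definition) called private. The classification describes the sample, not
  the unobservable truth.
* One published per-country "% invasive" cell (43.6 for the source
  country) disagrees with the ratio of its own printed counts
  (41/93 = 44.1%); this package computes from counts and reports 44.1.
* Single-level AMOVA only; no hierarchical region/population designs.
* Median-joining networks and likelihood-based trees are out of scope.
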