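Package: haplotrace
Title: Phylogeographic Tracing of Invasive Populations from Mitochondrial Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mitochondrial phylogeography of
    biological invasions: collapsing aligned mtDNA sequences into haplotypes,
    classifying them as private, shared-native, or invasive by their geographic
    distribution, per-population diversity statistics (haplotype diversity,
    nucleotide diversity, maximum pairwise divergence), single-level analysis
    of molecular variance (AMOVA) with permutation testing, minimum-spanning
    haplotype networks (union of all minimum spanning trees), and
    neighbor-joining trees with bootstrap support and outgroup rooting.
    Includes a seeded generator of synthetic invasion-genetics datasets with
    divergent native regional haplotype pools and bottlenecked introduced
    populations, so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph
Config/testthat/edition: 3
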