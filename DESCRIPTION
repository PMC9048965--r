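Package: iridograph
Title: Phylogeny-Aware Reconstruction of Iridoid Biosynthetic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing biosynthetic pathway hypotheses for
    oxidized iridoid scaffolds from sparse, genus-level metabolite reports.
    Scaffolds are encoded as per-carbon complex oxidation-state vectors, the
    full scaffold space is enumerated as a reaction-adjacency graph, and
    per-genus pathway hypotheses are obtained by extending reported scaffolds
    through the space and pruning candidate routes with phylogenetic weights
    (Brownian-motion tip correlations or Felsenstein root weights). A neutral
    pathway-evolution simulator generates synthetic benchmarks along a
    phylogeny; surrogate selection (network descriptors, UMAP embedding,
    Mahalanobis gating) and a Matthews-correlation-coefficient benchmark pick
    reconstruction parameters; ancestral pathways are estimated from root
    weights; and coexpressed enzyme candidates are ranked with a
    self-organizing map, Ward clustering and hypergeometric enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
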