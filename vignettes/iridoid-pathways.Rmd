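---
title: "Phylogeny-aware reconstruction of iridoid scaffold pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware reconstruction of iridoid scaffold pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

iridograph turns scattered genus-level reports of oxidized iridoid
scaffolds into testable biosynthetic pathway hypotheses.  This vignette is
the package's account of the underlying models: what is assumed, which
parameters matter, how the synthetic benchmark is built, and where the
design was genuinely open.

## The scaffold code and its grammar

An oxidized iridoid scaffold is described carbon by carbon over the ten
positions of the cyclopentanopyran core (C1, C3, C4, C5, C6, C7, C8, C9,
C10, C11).  Each carbon carries a complex value: the real part is the
ordinal oxidation state (0 saturated, 1 alcohol, 2 aldehyde, 3 carboxylic
acid, 4 decarboxylated; C11 skips the alcohol, so 1 is already the
aldehyde and 3 the decarboxylated state), and the imaginary part, written
in fourths, flags unsaturation: `1/4` for a double-bond carbon and `3/4`
for an epoxide carbon.  Flags only come in bonded pairs along the ring
skeleton, so a lone flagged carbon is invalid.

The default grammar fixes, per carbon, how far the ordinal scale runs:
C1, C6, C8 and C9 only hydroxylate (two states); C5 reaches the aldehyde;
C10 runs the full alcohol-aldehyde-acid-decarboxylation series; C4 and C7
carry longer series; C3, the enol-ether carbon, is only modified through
its double bond; C11 uses its shifted three-step scale.  Unsaturation
flags are restricted to unoxidized carbons, and epoxides may only sit on
the C7-C8 and C8-C9 bonds of the cyclopentane ring.  These constants were
calibrated so that the enumerated space reproduces the published size of
the oxidized iridoid scaffold space (6.24e4 scaffolds, 8.22e5 reactions);
they are all exposed through `iridoid_grammar()`, so a different valence
model can be dropped in and the space re-enumerated.

Two scaffolds are reaction-adjacent when their difference is a single
registered move: an oxidation step at one carbon, a desaturation, an
epoxidation of an existing double bond, a double-bond migration or
relocation, or a concerted pair of desaturations.  Literal complex
arithmetic gives a desaturation a distance of 0.5 (two carbons moving by
`1/4` each); the calibrated generalized distance therefore decomposes the
unsaturation difference into the minimal number of registered bond events
and counts each event as 1, so every registered move has distance exactly
one.  Equivalently, the adjacency connects all pairs whose literal
generalized Manhattan distance is at most 1.  The published reaction
count corresponds to counting each adjacency in both directions; the
undirected count is available through `count_reactions(space,
"undirected")`.

## Phylogenetic weights

Two weighting schemes turn the genus-by-scaffold report matrix into item
scores.  The *correlation* scheme uses the Brownian-motion tip
correlation of the genus tree (shared root-to-ancestor path length over
the geometric mean of tip depths, `ape::vcv` followed by
`stats::cov2cor`); the score of an item for a focal genus is its presence
row multiplied into the correlation column of that genus, so an item
reported in close relatives scores almost as highly as one reported in
the genus itself.  The *Felsenstein* scheme computes the posterior weight
of "present" at the root under a symmetric two-state Markov model by the
pruning recursion, with a flat root prior.  Unreported items are treated
as missing data (conditional likelihood one for both states), never as
absences - the literature records presences only.  The transition rate
defaults to 1 per unit branch length; it is exposed because reasonable
alternatives exist and the choice shifts all root weights smoothly.

## From reports to pathway hypotheses

The *naive prediction* takes every scaffold reported anywhere in the
family as a point in the chemical space, expands the set by `n_reactions`
breadth-first steps, and connects all unit-distance pairs.  The same
family-wide graph underlies every genus: scaffolds reported only in other
genera sit in it as candidate intermediates, which is what allows a genus
hypothesis to predict a metabolite never reported in that genus.

Pruning scores candidate *pathways* - routes through the naive graph -
with the focal genus's item scores and keeps those within `tolerance`
percent of the best score anywhere in the graph; the hypothesis is the
union of the retained routes together with every unit-distance reaction
among the retained scaffolds, plus the genus's own reported scaffolds
(kept isolated when their routes are discarded).  In small components
(at most `exact_cutoff` nodes, default 12) the candidate set is the
exhaustive collection of minimal connectors of the reported nodes; in
larger components it is a capped sample of near-shortest routes between
reported pairs, drawn with jittered edge weights, and optionally with
weights discounted between high-scoring metabolites so that routes deviate
through phylogenetically plausible intermediates.  The route sampler is
internally seeded from the component shape, so pruning the same naive
graph at several tolerances sees identical candidates and the
tolerance-monotonicity of the hypothesis is exact.  The published
algorithm's precise candidate set is not described at this level of
detail; the route-bundle contract here is the package's own documented
choice, selected because it reproduces the qualitative behaviour of the
published benchmark (recovery of unsampled metabolites through relatives,
precision falling as tolerance grows, whole low-affinity subnetworks
dropping out of a genus hypothesis).

The full protocol (`reconstruct_pathways`) runs the benchmark-selected
zero-extension model first and then rescues reported scaffolds left
without a connection by re-running the one-reaction extension under
Felsenstein weights at zero tolerance, merging the result.  The ancestral
pathway applies the root weight to every item across the per-genus
hypotheses and keeps items above a 0.9 cutoff.

## The evolution model and its calibration

The synthetic benchmark rests on a neutral model of pathway evolution
with three constraints: exploration draws reactions uniformly at random
from the whole space and fixes them only when one of their substrates is
already producible from the pathway source; each lineage maintains at
most `max_enzymes` enzymes, a random incumbent being lost when the cap is
exceeded; and the number of exploration rounds on a branch is
proportional to its length (a molecular clock).  Children inherit
independent copies of the parent state, and a genus pathway is the set of
metabolites reachable from the source through the lineage's enzymes.

Defaults: `ancestral_edges = 4`, `max_enzymes = 20`, `rounds_per_unit =
30000` on trees normalised to unit root depth.  The large round count is
a direct consequence of uniform exploration: a draw lands next to a
producible substrate only a fraction of a percent of the time, so tens of
thousands of draws per unit branch yield a handful of fixations.  These
values were chosen once, by matching the observable statistics of the
curated Lamiaceae report table at the natural sampling fraction (about
six reported scaffolds per genus, with each scaffold reported in a small
number of genera); the simulated report matrices come close to those
statistics but remain somewhat more shared and less diverse than the
curated data, a known limitation of the single-config generator.

## Surrogate selection and the benchmark

Each candidate surrogate is one simulated evolution sampled at one
fraction of the 10-60% ladder, summarised by its per-genus naive-model
graphs.  Sixteen classical topology descriptors (counts, density, degree
moments, component structure, diameter/radius, clustering, articulation
points, leaves, mean path length, assortativity, cycle rank and degree
entropy) are concatenated in fixed genus order - 336 columns for 21
genera - deduplicated, log-transformed (`sign(x) * log10(|x| + 1)`, so
zero and the signed assortativity survive) and column z-scaled.  A 2-D
UMAP is fitted to the surrogate rows (uwot, fixed neighbour count and
minimum distance); the natural naive model is projected repeatedly with
the stochastic transform, and surrogates whose squared Mahalanobis
distance to the projection cloud falls below the 0.99 quantile of a
chi-squared with 2 degrees of freedom are selected.  Because the gate can
be strict when the candidate pool is small, `select_surrogates` can be
asked to keep at least a minimum number of sets by falling back to the
nearest candidates by Mahalanobis rank; the result records whether that
fallback fired.

The benchmark regenerates sampled reports per surrogate, reconstructs at
every grid combination, and scores both metabolites (nodes) and enzymes
(edges) against the simulation ground truth.  True negatives are counted
over the union of the family-wide naive graph and every genus's true
pathway: against the full 62,000-scaffold space the false-positive rate
would be vacuously zero.  Medians and quartiles are pooled over
surrogates, resamples and genera, and the best combination per extension
level maximises the median metabolite MCC.  The test suite runs this at
a documented reduced scale: 48 candidate evolutions across six parameter
combinations, at least 20 selected surrogates, three resamples, and a
grid restricted to vertex weighting on reported presence with tolerances
0-20%.

## Coexpression candidate ranking

Expression matrices are transformed cell-wise by `log2(x + 1)` and
z-scored per transcript; constant transcripts are zeroed and flagged.
Transcripts are placed on a self-organizing map - a 20 x 20 hexagonal
grid embedded on a torus, batch-trained with a Gaussian neighbourhood
whose radius shrinks linearly - and the 400 codebook vectors are
clustered by Ward's criterion on Manhattan distances into ten clusters.
The SOM implementation is the package's own; its training schedule
(30 batch iterations, radius from half the grid diameter down to 0.5) is
fixed in code.  Bait enrichment per cluster uses the exact hypergeometric
upper tail, and candidates are the members of clusters below the
significance threshold, baits excluded.

## Numerical choices and degenerate inputs

Zero-variance descriptor or expression rows are set to zero rather than
dropped; undefined graph descriptors (assortativity of regular graphs,
path lengths of singletons) map to zero sentinels; an MCC with a zero
denominator is reported as 0 with an explicit flag; ties in candidate
scores are kept (union semantics), so results do not depend on candidate
order; the chi-squared gate covariance is ridged when the projection
cloud degenerates.  All stochastic steps take explicit seeds, and
`generate_fixture` reproduces byte-identical bundles from its seed.

## What the synthetic benchmark does and does not show

The generator emulates genus-level presence reports produced by uniform
undersampling of true pathways that diverged under a neutral clock.  It
does not emulate publication bias toward charismatic genera, correlated
sampling within clades, taxonomic misassignment, or decoration chemistry
(all inputs are pre-coded oxidized scaffolds).  Passing benchmarks on
these fixtures therefore demonstrates the machinery - encoding,
enumeration, weighting, pruning, selection and scoring - under controlled
conditions, not the field accuracy of any particular biological
prediction.  The curated literature table and the published genus
phylogeny are distributed separately; when placed under `inst/extdata/`
the data-dependent checks in the test suite run against them directly.
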