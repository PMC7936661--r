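---
title: "Short loop motifs, commonality and companion statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short loop motifs, commonality and companion statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortloop)
```

This vignette documents the statistical and algorithmic content of the
package: what each quantity means, which parameters matter and why the
defaults are what they are, what the synthetic-data generators do and
do not emulate, and the design decisions taken where more than one
reasonable reading existed.

## Networks and their invariants

A `ppi_network` is a simple undirected graph over protein accessions.
Three invariants are enforced at construction and therefore hold for
every object in the package: no self-loop, each unordered pair present
at most once, and every edge endpoint in the node set. Identifiers are
case-sensitive; only surrounding whitespace is trimmed. Interaction
direction and confidence scores in source files are deliberately
ignored — the model is an unweighted, undirected graph, and callers who
want confidence filtering should pre-filter their edge lists. When
several sources are merged (`merge_networks`), node and edge sets are
unioned and each edge accumulates the union of its source labels;
self-loops and duplicates cannot survive the merge by construction.

Proteins that appear only in dropped self-loop rows are themselves
dropped by default (`keep_isolated = FALSE`), because protein counts
"in the network" are interaction-based counts; the flag retains them
when a fixed node universe matters. Induced subnetworks
(`induce_subnetwork`) report mapping coverage — the percentage of the
query accessions found in the network, rounded to the nearest integer —
because disease mutation lists routinely contain proteins without
interaction data and the coverage is part of the result, not a
nuisance.

## Short loop enumeration

A length-3 short loop is a triangle; a length-4 loop is a simple
4-cycle counted once per node cycle. Triangles are enumerated by
sorted-adjacency neighbour intersection: with nodes indexed, each edge
(u, v) contributes one triangle per common neighbour with index above
both endpoints, so every triangle is emitted exactly once and the
output order is canonical (lexicographically sorted member triples).
The algorithm is a contract, not a contribution: the test suite checks
its output against an exhaustive scan over all node triples on several
hundred random graphs, and against an independent graph library's
triangle counter.

Two decisions for length-4 loops:

* **Chords are allowed by default.** A 4-cycle inside a 4-clique
  counts. Short loops are cycles, not induced cycles, and nothing in
  the loop definition excludes chords; `chordless = TRUE` provides the
  induced-cycle alternative. Counts under both conventions are
  oracle-tested.
* **Loops are counted as node cycles, once each** — K4 has three
  distinct Hamiltonian 4-cycles, not 24 vertex sequences.

No numeric reference values exist for length-4 profiles (length-4
analyses of the motivating networks showed no differences from
length 3), so k = 4 is validated purely by oracle equivalence, and all
downstream statistics (consensus, commonality) are defined on k = 3.

The **loop3 ratio** is loops / interactions. It is reported to two
decimals at the printing layer but carried at full precision
internally. A network with zero interactions has no defined ratio and
raises an error rather than returning 0/0 quietly.

## Functional consensus

A loop has consensus when the intersection of its members' term sets
is non-empty; the network-level consensus ratio is the percentage of
such loops. Two choices:

* **Unannotated members.** By default a loop containing an
  unannotated protein counts as non-consensual — a protein with no
  terms cannot share one. The `"exclude"` policy instead removes such
  loops from both numerator and denominator, for annotation tables
  with poor coverage where "no terms" means "not annotated" rather
  than "annotated with nothing".
* **Exact term matching only.** Consensus is measured independently of
  any ontology hierarchy; if ancestor closure is wanted, it must be
  pre-applied to the annotation table. This keeps the statistic a pure
  function of the supplied table and avoids shipping a DAG parser the
  analysis does not need.

The graded per-loop percentage, 100·|∩|/|∪| of the member term sets,
is exposed for ranking loops but plays no role in the consensus ratio.

## Short loop commonality

For protein X, a *partner pair* is an unordered pair {A, B} such that
{X, A, B} is a triangle. Two non-adjacent proteins X and Y are in
commonality when

1. they share at least `min_shared = 3` partner pairs, and
2. the shared pairs make up at least `min_frac = 0.95` of **each**
   protein's partner-pair set.

The 95% criterion is read symmetrically (both fractions must pass):
the defining picture has X and Y with identical loop sets, and the
symmetric rule is the strictest reading consistent with it. Because
the choice is genuinely open, `frac_mode = "either"` gives the
one-sided variant; raising either threshold can only remove pairs
(anti-monotonicity, property-tested). Proteins with no partner pairs
are never candidates — their fraction would be 0/0 — and adjacency is
always disqualifying, since commonality is specifically an *indirect*
relationship. Shared loops are counted as shared partner pairs, not
shared whole triangles: the pair {A, B} shared between X and Y
witnesses both triangles {X, A, B} and {Y, A, B}.

The commonality network takes the detected pairs as edges; its
summary reports the mean neighbour count 2·pairs/nodes and connected
component sizes, the statistics used to compare disease networks.

The *control set* construction re-derives commonality pairs in the
general (unfiltered) network under the same thresholds and keeps pairs
with exactly one member drawn from the disease pairs and the other
free of disease mutations, excluding the disease pairs themselves.
This yields the comparison set for the dependency screen below.

## Random-subnetwork null models

`sample_random_subnetworks` draws uniform random node subsets (without
replacement within a sample, independent across samples), induces each
subnetwork and evaluates the statistic (`loop3_ratio` or
`mean_neighbours_commonality`). Decisions:

* Sampling is uniform over nodes, not degree-matched; degree-preserving
  rewiring nulls are an explicit non-goal. The null asks "what does a
  random protein set of this size look like", not "what does a random
  graph with this degree sequence look like".
* A sample on which the statistic is undefined (no interactions; no
  commonality pairs) scores 0 and is counted in `n_degenerate`.
  Resampling instead would condition the null on having edges and bias
  it upward.
* The standard deviation uses the n−1 denominator (sample sd), and the
  standard error is sd/√n. Stored summaries are property-tested to
  match recomputation from the stored samples at 1e−12 relative
  tolerance.
* With `sd = 0` (e.g. complete-graph nulls, where every induced
  subgraph is complete and the ratio is constant) the z-score is
  returned as a signed infinity with a warning, or 0 when observed
  equals the mean — never NaN.

Reproducibility: every sampler takes a `seed` and restores the
caller's RNG state afterwards, so identical seeds give bit-identical
sample lists and library calls do not perturb user scripts.

## Mutation statistics

Mutation tables are filtered on reading: only amino-acid-changing
types are admitted (nonsense/missense substitutions, in-frame and
frameshift insertions and deletions, complex/compound, plus the rare
whole-gene-deletion and nonstop-extension classes), and proteins seen
in fewer than two distinct samples are removed entirely, so
single-case observations never reach the statistics. Positions are
1-based residue indices; insertions and deletions are represented by
their start position.

The normalized nsSNV frequency is variants / protein length, under
the assumption that mutability scales with protein size.

**Hotspots.** The hotspot rule is: a position carrying at least
`min_fraction = 0.05` of the protein's mutations, in at least
`min_samples = 2` distinct samples. The external definitions this
mirrors are stated loosely in the literature; 5%/2 was fixed once as
the default because it cleanly separates the regimes of interest —
a handful of dominant positions (which then jointly account for most
of the protein's mutations) versus a flat profile where no position
reaches a few percent — and both knobs are exposed.

**MHRD** is the fraction of the protein's mutations falling on its
hotspot positions. Significance is assessed against a uniform null:
`n_sims = 10000` placements of the protein's N records, each record
uniform over positions 1..L, measuring the mass on the **fixed**
observed hotspot set. Fixing the positions (rather than re-detecting
hotspots per simulation) is the simplest reading of a uniform null
and makes the null distribution exactly Binomial(N, |H|/L)/N, which
the tests exploit as a closed-form oracle: the simulation is kept as
the implementation precisely so that the binomial formula remains an
independent check. The empirical p-value is add-one smoothed,
(r+1)/(n_sims+1), so it is never exactly 0 and is valid under the
usual Monte-Carlo-test argument. When the hotspot set covers all
positions the null is degenerate (sd 0); this is flagged rather than
scored.

## Gene dependency calls

Dependence is score < −1, **strictly**: a score of exactly −1 is not
dependent. Contingency tables are built over the cell lines with
non-missing scores for both genes (pairwise-complete). Fisher's exact
test is delegated to `stats::fisher.test` — the canonical
implementation — and the test suite validates it against a full
hypergeometric enumeration written independently with binomial
coefficients; `side = "less"` corresponds to the mutual-exclusivity
direction and `"greater"` to co-occurrence.

Classification is **count-driven, not p-value-driven**, because
dependency profiles are sparse and essential genes are near-universal,
which distorts p-value rankings. The rules:

* *mutually exclusive*: zero co-dependent lines (configurable via
  `max_overlap`; zero is the strictest reading of "dependent on either
  X or Y"), at least 2 exclusively dependent lines per gene ("more
  than one"), and each gene dependent in strictly less than 50% of the
  lines (the essentiality cap eliminating housekeeping genes);
* *co-occurring*: at least 2 co-dependent lines, same cap;
* otherwise *neither*.

"<50%" and ">1" are strict, as printed in the criteria they encode.
The two classes are mutually exclusive by construction (a pair with
≥2 co-dependent lines cannot have 0). Classification is symmetric in
gene order (property-tested).

## What the generators emulate — and what they do not

Every generator is deterministic under a fixed seed and emits its
ground truth; at zero noise/background every detector recovers the
planted truth exactly, which the tests assert end to end through the
file formats the readers consume.

* `gen_er_network`: Erdős–Rényi G(n, p). Real PPINs are not ER — they
  are heavy-tailed, clustered and assortative — so ER backgrounds
  validate *algorithms* (counts, calibration), not biological effect
  sizes. Scale-free backgrounds are a documented extension point.
* `gen_planted_commonality`: the canonical fan motif — hub pair
  (X, Y), no X–Y edge, a chain C1…C(fan+1) with every chain protein
  tied to both hubs. Partner pairs are deliberately *chained*
  (AB, BC, CD share members) to reproduce the defining topology
  rather than a disjoint-pair simplification.
* `gen_annotations`: each triangle is independently consensual with
  probability q via a fresh term shared by exactly its three members;
  every other term (private and decoy) is unique to one protein, so a
  non-planted loop can never achieve consensus by accident. This
  makes the per-loop consensus events exactly independent
  Bernoulli(q), which is what turns the consensus-ratio test into a
  clean binomial-oracle check. Real annotation tables are of course
  correlated across related proteins; the generator validates the
  counting, not annotation realism.
* `gen_mutations`: exactly round(mass·N) records on the planted
  hotspots, the rest uniform over *non-hotspot* positions, so the
  achieved MHRD equals the requested mass exactly and recovery tests
  are deterministic.
* `gen_dependency`: planted mutually exclusive pairs get disjoint
  2-line dependent blocks, co-occurring pairs a shared 2-line block,
  decoy genes at most one dependent line (below every criterion), with
  dependent scores in (−2, −1.2) and others in (−0.3, 0.3) —
  comfortably either side of the −1 cutoff so that binarization is
  noise-free at zero noise rate.

## Problem sizes and numerical choices

The validation suite favours many small problems over few large ones:
triangle-oracle equivalence on 500 random graphs of up to 25 nodes,
Fisher-vs-enumeration on all 2×2 tables with N ≤ 30, commonality
oracle equivalence on graphs up to 30 nodes, ER triangle-count
calibration over 200 seeds, and p-value calibration over 200 uniform
replicates with 400 simulations each (N = 500 records over
L = 1000 positions, a 100-position reference set). These sizes give
binomial standard errors tight enough for 3-sigma bands while keeping
the whole suite well under a minute per file. Because the MHRD null
statistic is discrete, the calibration test compares the observed
rejection rate with the *exact* discrete-null rejection probability
computed from the binomial tail, rather than with a nominal 5%.

Ties and ordering are everywhere resolved lexicographically (radix
sort, locale-independent): canonical loop rows, commonality pair
order, edge order. This makes every output deterministic and
diffable.

## Known limitations

* Commonality is defined for length-3 loops only; a length-4 analogue
  would need its own partner-pair notion.
* Uniform node-sampling nulls do not control for degree; conclusions
  about *why* a subnetwork is loop-rich need degree-aware nulls.
* The uniform mutation null ignores sequence context and mutational
  signatures; it tests "more concentrated than uniform", nothing more.
* Hotspot positions are linear-sequence positions; 3D clustering of
  spatially adjacent hotspots is out of scope.
* The dependency calls treat cell lines as exchangeable; lineage
  structure or mutation status of the lines is not modelled.
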