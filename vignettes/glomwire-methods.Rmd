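---
title: "glomwire: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glomwire: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomwire)
```

## The system and the data model

The package analyses synapse-resolution wiring diagrams of glomerular
olfactory circuits, with the larval *Drosophila* antennal lobe as the
reference system: 21 glomeruli, each defined by a single identified
olfactory receptor neuron (ORN), one uniglomerular projection neuron (uPN)
per glomerulus, a parallel multiglomerular readout (mPNs), and a small set
of identified inhibitory local neurons — the panglomerular, axonless Broad
LNs (a Trio and a Duet subtype), the oligoglomerular Picky and Choosy LNs,
Keystone, and a Ventral LN.

Four tables carry a diagram:

* a **roster** (id, cell type, side, glomerulus, fragment flag),
* **skeletons** — rooted trees of 3-D nodes in micrometres, read and written
  as standard SWC with a separate tag table ("axon start", "axon initial
  segment", "soma"); the SWC radius field is ignored because the analyses
  are skeleton-based, not volumetric,
* a **synapse table** with one row per *postsynaptic site*: a polyadic
  connector contacting *n* targets contributes *n* rows sharing a connector
  id. All synapse counts in the package are postsynaptic-site counts, which
  makes counts additive and lets presynaptic-site counts remain a separate
  view,
* a **homolog pairing** mapping each neuron to its contralateral partner,
  with an explicit unpaired set for the ventral unpaired medial (VUM)
  neurons.

Unassigned arbor fragments are first-class: they enter the roster as
pseudo-neurons with a fragment flag, so `unassigned_fraction()` can report
how many postsynaptic sites downstream of a cell class, and how much cable,
remain unassigned. Percentages are computed on raw counts and rounded to one
decimal only for display. Cable totals include fragment cable in the
denominator; with one-decimal display the alternative (excluding it) is
indistinguishable at realistic fragment fractions, and including it keeps
the denominator equal to the total reconstructed cable.

## The bilateral-consistency filter

Identified neurons appear once per side, so stereotypy can be used as a
noise filter: a connection between cell *A* and cell *B* is accepted only if
it carries at least `min_synapses` synapses between the homologs on the
left side *and* at least `min_synapses` on the right side. The threshold is
a per-side minimum, not a summed one — "found in both" forces that reading —
and the default is 2 synapses, with 4 as a common display variant for
excitatory inputs in crowded figures. The filter output is symmetric under
swapping the sides and monotone in the threshold (raising it never adds
edges); both properties are tested.

For unpaired (VUM) targets with bilateral arbors, consistency is evaluated
on the left-source/right-source connections when the sources are paired
(`merge_bilateral_inputs()` sums inputs from the two homologs of a source
under its pair identity); a VUM neuron is its own instance on both sides of
the generator for the same reason.

Input-fraction tables always carry an explicit denominator specification —
whole-neuron postsynaptic totals or dendrite-only totals — because published
tables use both and the numbers are not comparable across the two. Two
display-rounding conventions are implemented in `render_table()`:
`floor_below_half` maps percentages in (0, 0.5) to 0, `ceil_to_one` maps
(0, 1) to 1; totals are always recomputed from the raw values, so they are
invariant to the convention. Which columns a rendering includes (e.g.
whether neuromodulatory and descending neurons appear) is left to the
caller; the stored matrices always carry everything.

A **glomerulus**, as a source group for input tables, is the ORN plus the
dendro-dendritic output of that ORN's uPN — uPN synapses whose presynaptic
node lies on the uPN dendrite; axonal uPN outputs are excluded. Glomeruli
lacking a uPN contribute the ORN alone and are flagged.

## Morphology

Compartments are defined by tags, not inferred: every node in the subtree
rooted at an "axon start" node is axon, "soma"-tagged nodes are soma,
everything else is dendrite. A skeleton with no axon-start tag is axonless
(zero axon nodes), matching the Broad LNs. No synapse-flow heuristic is
used — automatic axon/dendrite inference is out of scope.

Cable length is the sum of parent–child Euclidean edge lengths; under a
compartment restriction an edge is attributed to the compartment of its
child node, which makes lengths exactly additive across compartments.
Distances of postsynaptic sites to the axon initial segment are geodesic
(along the cable, via the lowest common ancestor), never straight-line.
`distance_profile()` summarises them per presynaptic partner by medians, so
proximity statements ("Choosy LN input is more proximal than Broad LN
input") are assertable as median comparisons rather than by eye; the package
deliberately exposes medians instead of asserting an effect size.

The axo-dendritic polarity of a connection with *d* sites on the target's
dendrite and *a* on its axon is *(d − a)/(d + a)*, the unique simple form
with range [−1, 1], sign equal to sign(*d − a*), and invariance to scaling
both counts. It is undefined (and excluded) at *d + a* = 0, antisymmetric
under relabelling the compartments, and `polarity_table()` reports a
connection only when a compartment reaches the consistency threshold
(default 2 sites).

## Circuit motifs

`input_motifs()` classifies, for each ORN and a given target, the route of
influence: *direct* (an edge onto the target), *lateral* (a length-2 path
through a relay interneuron class, by default the Picky LNs), and the
*incoherent feedforward loop* when both routes exist. The classes partition
the influencing ORNs. Lateral routes are paths of length exactly two; longer
disinhibition chains are the business of the hierarchy and reciprocal-core
views, not the triad census.

A "hierarchy" drawing is operationalized as: condense the subgraph into
strongly connected components (reciprocally connected neurons merge and are
reported as such), then rank components by longest path from the sources.
"Dominant" neurons are rank-0 nodes of maximal out-reach; rank and out-reach
are reported separately rather than collapsed into one dominance scalar,
since the two can disagree. Nodes with no path in either direction are
flagged as able to operate in parallel.

`reciprocal_cores()` reports pairs connected in both directions at a minimum
weight (the Broad-Trio/Keystone motif); group-level self-arrows use the
convention of `group_self_weight()`: the mean number of synapses one group
member receives from the other members. `inhibition_profile()` quantifies
pre- vs postsynaptic inhibition per glomerulus (sites on ORN axon terminals
vs on uPN dendrites) and summarises a source's heterogeneity across
glomeruli by the coefficient of variation — a panglomerular inhibitor has
CV near 0, a selective one that skips glomeruli a larger CV. Edge weights
for display can be linear or square-root scaled; the underlying counts are
untouched. No dynamics are simulated: putative operational states of the
inhibitory network are represented only as structural motif queries.

## ORN odor tuning

`orn_tuning()` fits the receptive-field pipeline:

1. **PCA** of the odorant × ORN response matrix, centering on, variable
   scaling off by default (responses share units; both flaggable).
2. **Scree choice** of the retained dimensionality: the named test is a
   visual elbow, operationalized here as the largest second difference of
   the explained-variance curve — the component after which the drop in
   explained variance falls off the most. Callers can override `k`.
3. **Affinity propagation** on the odorants in the retained component space,
   with similarity = negative squared Euclidean distance, preference = the
   median off-diagonal similarity, damping 0.9, convergence declared after
   50 iterations of a stable exemplar set. The algorithm does not take a
   cluster count. A multiplicative jitter of ~1e-14 relative magnitude
   breaks exact ties deterministically; inputs whose off-diagonal
   similarities are all equal (indistinguishable points) short-circuit to a
   single cluster. The implementation is the standard
   responsibility/availability message-passing scheme and is checked in the
   tests against values frozen from an independent reference implementation.
4. **Back-projection** of each cluster centroid into ORN space through the
   transpose of the loading map with the centering offset re-added; a
   singleton cluster back-projects to that odorant's rank-k reconstruction
   and the component-space origin back-projects to the mean response vector
   (both tested as identities).
5. **Otsu threshold** on the back-projected coordinates, pooled across all
   clusters after per-cluster min–max scaling to [0, 1]: one global
   threshold, consistent with reporting a single printed threshold, and the
   scaling makes clusters with different absolute response levels
   comparable. On continuous values the candidate cuts are the midpoints
   between consecutive sorted unique values (exact search, equal to the
   exhaustive oracle by construction); a binned variant exists for large
   inputs. ORNs strictly above the threshold form the cluster's encoding
   set.

`predict()` assigns new odorants to the cluster of the nearest exemplar in
component space. `crossvalidate_private_odorants()` checks encoding sets
against odorants known to activate a single ORN: agreement means the
activated ORN lies in the encoding set of the cluster matching the
odorant's chemical class; classes absent from the training clusters are
reported as unpredictable rather than scored. K-means in the 32-dimensional
odorant-descriptor space (`kmeans_descriptor_clusters()`) provides the
independent descriptor-side clustering; it is a seeded best-of-restarts
wrapper around the standard algorithm.

The response loader exposes a per-source scaling hook (and applies no
transformation by default) because merged screens may be recorded on
different scales; whether any rescaling is appropriate is a property of the
data sources, not of the method.

## The synthetic generator: what it emulates

`generate_wiring()` draws mirrored left/right diagrams from a type-level
ground-truth edge table: each eligible (source pair, target pair)
combination carries a real connection with probability *p*; real
connections are realized on both sides with independent zero-truncated
Poisson(λ) synapse counts; `mirror_noise` drops a realization on one random
side; spurious connections appear independently per side at rate ε — so the
bilateral filter has genuine discriminative work, exactly the rationale for
the two-sides rule. Skeletons are random rooted trees (exponential edge
lengths, configurable branching) with a tagged axon-start/axon-initial-
segment node; synapse sites land on the configured compartments, so
compartment-restricted counts, dendro-dendritic grouping and polarity
indices all have ground truth. A configurable fraction of ORN postsynaptic
sites (default 0.9%) is diverted to fragment pseudo-neurons.

The default configuration reproduces the identified-neuron roster of the
larval antennal lobe — per side: 21 ORN, 21 uPN, 13 mPN, 3 Broad Trio,
2 Broad Duet, 5 Picky, 2 Choosy, 1 Keystone, 1 Ventral LN, 6 SEZ neurons,
1 descending, 2 neuromodulatory = 78 bilateral pairs, plus 4 VUM neurons
(2 mPNs, 2 neuromodulatory), 160 neurons in total. The default edge table
encodes the qualitative circuit structure: glomerulus-matched ORN→uPN
convergence (λ = 55, the strongest connection class), panglomerular Broad
input to ORN axons (presynaptic inhibition) and uPN dendrites (postsynaptic
inhibition, Duet-dominated), uPN dendro-dendritic output onto the Broad
Trio, a reciprocal Broad-Trio/Keystone core, selective Keystone presynaptic
inhibition, and sparse Picky-LN input to mPNs and each other. The
probabilities and means are plausibility choices for a first-instar antennal
lobe, not fitted values.

What the generator does **not** emulate: realistic neuron morphology or
glomerular geometry, correlated synapse counts between sides beyond the
shared edge identity, activity, neurotransmitters, or gap junctions.
Passing tests therefore demonstrate the correctness of the bookkeeping,
filtering, motif and tuning machinery on data with the right structure and
noise model — not that the biological conclusions would survive a different
noise model.

`generate_responses()` plants `n_clusters` odorant classes (default 5 —
alcohols, aromatics, esters, pyrazines, and a mixed class), each with a
disjoint 4-ORN encoding set out of 21 ORNs and 35 odorants: responses are
Gaussian around 150 spikes/s (sd 15) at encoding ORNs and around 10 (sd 5)
elsewhere, and a matching 32-dimensional descriptor matrix shares the class
structure. The separation is deliberately strong: the end-to-end tests ask
whether the pipeline recovers a clean planted structure exactly, which is a
correctness property; robustness to overlapping tuning is a scientific
question outside the suite's scope.

## Numerical choices and test design

* **Truncated-Poisson sampling** uses the inverse-CDF on a uniform draw
  restricted above P(X = 0), so realized edges always have ≥ 1 synapse and
  the draw is a single RNG call (reproducible stream).
* **Recovery fixture size.** At λ = 10 a realized side carries a single
  synapse with probability 4.5 × 10⁻⁴, so a connection falls below the
  2-synapse threshold somewhere in a 20-seed suite with probability
  proportional to the number of edges. The exact-recovery suite therefore
  uses a compact diagram (2 glomeruli + 1 mPN, 4 real edges per seed),
  sized so the expected number of below-threshold events across the whole
  suite is under 0.1; the filter logic itself is exhaustively checked
  against a brute-force oracle on random matrices, independent of the
  generator.
* **Monte-Carlo survival.** Spurious edges survive the two-side filter at
  approximately the squared per-side survival rate; the suite compares
  observed survivors against the product of empirically measured per-side
  rates over 40 seeded diagrams (~5,000 candidate pairs), with a tolerance
  set by the binomial error of that event count.
* **Problem sizes.** All suites run on one CPU in a few minutes: diagrams of
  10–160 neurons, 20-seed recovery runs, 40-seed Monte-Carlo runs, 10-seed
  end-to-end tuning runs, oracle checks on trees of ≤ 40 nodes, graphs of
  ≤ 8 nodes and value vectors of ≤ 64 entries.
* **Ties and degenerate inputs.** Otsu errors on constant input; PCA errors
  on a constant matrix; affinity propagation returns the first index as
  exemplar for indistinguishable points; `max.col(..., ties.method =
  "first")` makes cluster assignment deterministic; compartment labelling
  errors on tags referencing missing nodes; `distance_to_tag()` requires
  exactly one tagged node and names the offending skeleton otherwise.
* **Half-way rounding.** In the display conventions, a value of exactly 0.5%
  renders as 1 under both styles (the "rounded down to 0" band is the open
  interval below one half); values ≥ 1 round half-even as in base R. Stored
  values are never rounded.

## The pipeline interface

`run_stage()` ties the stages together (simulate → validate → tables →
morphology → motifs → tuning) under a single `pipeline_config()` — YAML or
arguments — in which every threshold is explicit: the per-side filter
minimum, the rounding style and the fraction denominator are recorded in
each stage's manifest along with the seed and a hash of the configuration,
so any emitted table states its provenance. Rerunning a stage with an
unchanged configuration reproduces byte-identical artifacts. A thin
command-line wrapper (`inst/cli/glomwire`) exposes the same stages to shell
users; validation failures exit non-zero.

## Known limitations

* The bilateral filter is the threshold rule itself; no permutation test or
  p-value for stereotypy is provided, because none is defined for this
  setting.
* Compartment labels come only from tags; skeletons without an axon-start
  tag are treated as axonless, which is correct for Broad-type LNs but
  silently mislabels a tag-less projection neuron.
* The odor-tuning pipeline assumes responses share units after the optional
  per-source scaling hook; no concentration normalisation is built in.
* The affinity-propagation preference default (median similarity) follows
  common practice; strongly unbalanced cluster sizes may need a hand-set
  preference.
* Replicating a published threshold value requires the published response
  screens, which the package neither bundles nor fetches; the Otsu
  implementation is instead verified against an exhaustive-search oracle.
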