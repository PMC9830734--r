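---
title: "Identifying disease modules in weighted co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying disease modules in weighted co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A disease module is a subnetwork of a gene co-expression network (GCN)
whose members are densely interconnected, functionally coherent, and
collectively discriminative between disease and control samples. moganet
searches for such modules in four stages: (1) build a weighted GCN from
two-class expression data, (2) coarsen it, (3) search partitions with a
decomposition-based multi-objective genetic algorithm, (4) score the
selected core module against a ground-truth gene set.

## Network construction

Differentially expressed genes (DEGs) are selected by a per-gene Welch
two-sample t-test with Benjamini-Hochberg adjustment at `alpha = 0.05`.
This is a deliberate approximation: the classical workflow for microarray
data uses an empirical-Bayes moderated t-statistic, whose variance
shrinkage matters most at very small sample sizes. With the replicate
numbers this package targets (tens per class) the plain Welch test selects
nearly the same genes, and it keeps the selection rule self-contained.
Genes that are constant in both classes are assigned p = 1 rather than
erroring, so flat probes in real matrices pass through silently.

Edge weights are Gaussian copula mutual information (GCMI): each margin is
rank-transformed to normal quantiles of fractional ranks `r/(n+1)` (ties
averaged), and the MI of the Gaussianised pair is `-log(1 - rho^2)/2`
nats. The estimator is therefore invariant under monotone transforms of
either profile and needs no density estimation. Two numerical guards
matter: the correlation magnitude is capped at `1 - 1e-12` so identical
profiles give a large finite weight instead of infinity, and constant
profiles return 0 with a warning because their rank transform is
degenerate. Units default to nats; bits are available via `unit`.

Only gene pairs present in a protein-protein interaction network (PPIN)
keep their co-expression weight; everything else is set to zero, which
drops the edge. Identifier matching across expression, PPIN, ontology and
truth inputs is exact and case-sensitive — no alias resolution is
attempted, so inputs must share a namespace.

Functional similarity between genes uses the relevance score of a
shared-ancestor term pair: `max over common ancestors c of
2 log p(c) / (log p(c1) + log p(c2)) * (1 - p(c))`. The ontology arrives
pre-tabulated (term probabilities, reflexive ancestor closure, gene
annotations); no OBO parsing is done. Term-level scores are aggregated to
gene level by the best-match average, the de facto standard for semantic
similarity, with `max` and plain `avg` as options — the aggregation rule
is configurable precisely because the method's description leaves it
open. Genes without annotations get similarity 0 to everything (diagonal
1) and a warning; alternatively a precomputed similarity matrix can be
supplied and the ontology stage skipped entirely.

## Network reduction

`presimplify()` repeatedly draws a random unassigned node `a`, grows a
local module (LM) around it — the max-degree neighbour `a_k`, the
neighbour of `a_k` sharing the most common neighbours, their joint
neighbours, plus every outside node with more than half of its degree
wired into the module — and repeats until all nodes are assigned. Within
each LM, the triangle of maximal total edge weight (ties broken by lowest
vertex indices; the heuristic's description does not specify a choice) is
contracted into a supernode whose incident edge weights are summed. One
contraction pass only; no recursive coarsening.

`boundary_correction()` then re-examines LM membership on the *original*
graph. Each node's weight `vw` is the density times the order of the
highest k-core of its closed neighbourhood (unweighted degrees, matching
the unweighted density formula), and `va` is its summed edge weight to LM
co-members. A node stays in its module when `vw > 2` and `vw` is at least
the LM mean of `vw` — the mean is scoped to the LM because retention is
framed per module. Each LM seeds from its retained member of largest
`va`; if the retention rule empties an LM (common for path-like modules),
the seed is simply its max-`va` member, so the module reattaches rather
than dissolving into singletons. Unassigned nodes are absorbed
breadth-first from the growing seed modules, edge weights ignored during
absorption (no threshold is defined for it); whatever remains becomes
singleton modules, so the output always partitions the node set.

## Objectives and search

Two objectives are minimised over partitions:

* `f1`, a Davies-Bouldin index computed on the semantic similarity
  matrix. The module centre is the medoid (maximal mean similarity to
  co-members; ties to the lowest index), `S_i` the mean of `dist` to the
  medoid, and the index averages the worst `(S_i + S_j) / (dist(v_i,
  v_j) + eps)` ratio per module, with `eps = 1e-9` guarding the division.
  `dist` has two readings, both implemented. The literal one plugs the
  similarity itself into the formula; the `"distance"` reading uses
  `1 - sim`. The search defaults to `"distance"`: minimising the literal
  form *rewards* modules of functionally unrelated genes (a high
  within-module similarity inflates `S_i`), which empirically drives the
  archive away from planted structure — initial populations that score
  NMI near 1 against planted communities are dominated out within a few
  generations — whereas the distance reading recovers them reliably.
  The standalone `dbi()` keeps the literal default so the formula can be
  studied as written; `moga_config(dbi_mode=)` switches the search.
* `f2 = cc_sign * max_i CC'(C_i)`, where `CC'` sums, over module members,
  `2 * sum of within-neighbourhood edge weights / (|R| (|R|-1))` with the
  neighbour set `R` restricted to the module (that restriction is what
  makes `CC'` a per-module quantity). The default `cc_sign = -1` makes
  the minimiser maximise the densest module's aggregation, matching the
  objective's stated purpose; `+1` gives the literal minimisation.

A one-module partition has no between-module term, so `f1` substitutes a
penalty: inside `evolve()` it is calibrated to 10x the largest pairwise
ratio observed in the initial population — large enough to deter
degenerate solutions, finite so arithmetic stays clean. Standalone calls
use a fixed 1e6.

The search is MOEA/D over locus-based genotypes on the reduced network:
position `v` points at a neighbour of `v` (or itself) and modules are the
connected components of the pointer graph, so every genotype decodes to a
valid partition by construction. Weight vectors are uniform on the
two-objective simplex; each subproblem's neighbourhood holds the `nm`
closest weight vectors; the reference point tracks the componentwise
minimum. Initial pointers are uniform random and then refined toward the
pointer value most neighbours share (restricted to the node's own valid
options; majority ties to the smallest index), stopping when a full pass
changes nothing, with a hard cap of 2N unchanged positions against
oscillation on tie-heavy graphs. Variation is two-point crossover (valid
by construction, since options are per-position) followed by per-position
neighbour resampling at the mutation rate. Mates come from the
subproblem's neighbourhood by default (`mate_scope = "global"` for the
literal "another randomly selected individual"), and a child replaces
every neighbouring incumbent whose Tchebycheff value it improves
(`replace_scope = "one"` restricts to a single replacement). An unbounded
external archive keeps all non-dominated solutions, deduplicated.

Objectives are always evaluated on the partition *expanded* to the
original network — contracted supernodes move as atomic blocks — so the
semantic index sees gene-level similarities and `CC'` the original
weights. The alternative (scoring the reduced graph directly) would
conflate merged edge weights with module density.

Reference settings: population 50, 100 generations, neighbourhood 40,
mutation rate 0.1, DEG threshold 0.05. After the run, the archived
partition with the largest contrast criterion
`W' = sum_i O(C_i)/|C_i|^2 - B(C_i)/(|C_i| |C_i'|)` (internal weights
summed over ordered pairs, hence the squared size; boundary term zero for
a module spanning the whole graph) is selected, and its largest module is
reported as the disease-module candidate.

All randomness flows from one master seed through deterministically
derived per-phase streams, so identical configurations reproduce runs
bit for bit.

## Enrichment

The core module is scored against a ground-truth gene set with the
hypergeometric upper tail, accumulated in log space, plus BH adjustment
when several modules are tested. The default universe is the node set of
the constructed network — the module was drawn from the network, so the
draw model should be too — with the full assayed gene list available via
`universe = "all"` since the appropriate choice depends on how the
ground-truth list was compiled.

## Synthetic data, and what passing tests show

The generators plant known structure: `gen_planted_network()` draws
within/between-community edges at `p_in`/`p_out` with uniform weights
(defaults 64 nodes, 4 communities, `p_in = 0.9`, `p_out = 0.05`, weights
U(0.5, 1) inside and U(0.05, 0.2) across); isolated nodes are rewired to
a same-community partner, preserving the planted labels while keeping
every node reachable by the pointer encoding. `gen_expression()` gives
block genes a shared latent factor (loading 0.8 by default) plus unit
noise and a disease shift of 2 on affected blocks — with 20 + 20 samples
that effect corresponds to a comfortably detectable standardised
difference, chosen so that DEG recovery is expected but not trivial.
`gen_similarity()` draws clipped-normal within/between similarities
(0.8/0.2, sd 0.05). These fixtures validate the machinery: correct
masking, calibrated estimators, recoverable planted partitions
(64 nodes, population 20, 30 generations in the standing checks — sizes
chosen so the full suite runs in well under a minute). They do not mimic
microarray platform artifacts, probe-level noise, correlated background
genes, or the scale (about 20,000 genes) of real studies, so passing
them demonstrates correctness of the algorithmics, not end-to-end
performance on real cohorts.

## Known limitations

* The Welch-test DEG stage is an approximation to moderated statistics
  and will differ at very small replicate numbers.
* Gene identifiers are matched verbatim; mixed symbol/probe namespaces
  must be reconciled upstream.
* The evolutionary loop is single-threaded and in-memory; networks of a
  few thousand nodes are comfortable, genome-scale dense similarity
  matrices are not.
* With `cc_sign = -1`, `f2` favours large dense modules; it is the
  distance-mode `f1` and the final `W'` selection that counteract
  degenerate giant modules. Users switching both flags to their literal
  readings should expect qualitatively different fronts.
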