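---
title: "Methods: semantic descriptor similarity, penalty-weighted search and pathway grouping"
author: "kbmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic descriptor similarity, penalty-weighted search and pathway grouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbmine)
```

kbmine implements the mining layer of a semantically integrated disease
knowledge base as a standalone toolkit. This vignette describes the
models and procedures, the parameters that matter, the numerical
choices, and what the synthetic fixtures do and do not establish about
real data.

## 1. Concept graphs and ontological inference

Biomedical knowledge bases integrate many controlled vocabularies at
once — anatomy (FMA), substances (PubChem), clinical terminology
(MeSH, NCI Thesaurus, ICD, SNOMED) — connected internally by
subsumption and partonomy relations and across ontologies by mapping
tables (typically derived from metathesauri such as UMLS). kbmine
merges all of these into a single undirected *concept graph*
(`build_concept_graph()`): concepts are nodes keyed by CURIE
(`PREFIX:LOCALID`), and every relation — `is_a`, `part_of`, `xref`,
`mapped_to` — is one edge.

*Ontological inference* treats two concepts as "similar" when a short
relation chain connects them, with similarity decaying in the number of
steps (`concept_distance()`). Three choices deserve comment:

* **Uniform step cost.** Traversal is undirected and
  relation-class-agnostic: an `is_a` edge and a cross-ontology
  `mapped_to` edge both cost one step. Nothing in the inference rule
  distinguishes edge classes by cost, and assigning per-class weights
  would introduce parameters with no principled defaults; uniform cost
  keeps the distance interpretable as "number of inference steps". A
  user who considers cross-ontology mappings weaker can simply lower
  `max_steps`.
* **`max_steps = 3` by default.** Under the score function below, a
  3-step neighbour contributes 0.25; beyond that the contribution is
  small enough that inference mostly adds noise, and the cut keeps
  distance queries local.
* **CURIE normalization.** Source vocabularies print identifiers
  inconsistently (`NCI: C25378` vs `MESH:D010313`), so whitespace
  around the colon is stripped; prefixes match case-insensitively,
  local ids case-sensitively. Dangling relation endpoints become
  flagged stub concepts rather than errors, because partial ontology
  extracts are the common case.

## 2. Combinatorial semantic descriptors

Physiological and clinical quantities often have no single ontology
term: "partial arterial blood oxygen pressure" decomposes into a
pressure concept, a substance, and an anatomical compartment. A
*semantic descriptor* (`parse_descriptor()`) is therefore a **set** of
concepts — from one ontology where possible, from several orthogonal
ontologies where necessary — attached to one parameter identifier.
Descriptors may optionally carry internal edges among their elements;
the worked examples in the field list concepts only, so edges default
to empty and all edge scoring degrades gracefully. Element order is
preserved for reporting but carries no meaning in scoring, and labels
never participate in matching.

## 3. Descriptor similarity

`match_descriptors()` compares a query descriptor against a target
through the concept graph:

1. Every (query element, target element) pair gets a step count
   (`Inf` beyond `max_steps`, or for concepts absent from the graph;
   0 for identical CURIEs whether or not they are in the graph).
2. Steps map to scores: $s(0) = 1$ and $s(k) = 1/(1+k)$ for
   $k \ge 1$ (see below).
3. A **one-to-one assignment** of query elements to target elements
   maximizing the score sum is found exactly; each target element is
   used at most once. Ties are broken lexicographically by
   (query curie, target curie), so results are deterministic.
4. Query edges are scored after elements: an edge whose endpoints map
   to target elements joined by a target edge scores
   $1/(1 + k_a + k_b + m)$, where $k_a, k_b$ are the endpoint step
   counts and $m = 1$ on an edge-class mismatch ("alternative edge
   classes" count as one inference step); identical edges score 1.
5. Aggregation: with $S$ the score sum, $C$ the fraction of query
   elements and edges matched identically *or* similarly, and $N$ the
   query element + edge count,
   $$\text{total} = S \times C, \qquad
     \text{normalized} = \frac{S \times C}{N} \in [0, 1].$$

**Why $1/(1+k)$ and not $1/k$.** The field's stated rule — score 1 for
identical matches, otherwise 1 divided by the number of steps — makes a
1-step neighbour score $1/1 = 1$, indistinguishable from identity and
contradicting the accompanying requirement of *diminishing*
contribution. $s(k) = 1/(1+k)$ preserves both stated properties
(1 for identity, strictly diminishing with distance). The literal
variant remains available as `score_fn = "literal"` for comparability;
the two differ only at $k = 1$.

**Normalizer.** Reported similarity percentages in deployed systems
imply a normalization that is never specified. Dividing the total by
the query's element + edge count maps self-similarity to exactly 100%
and keeps the score in $[0,1]$; it is the only choice with both
properties that uses no extra parameters. Coverage counts edges in its
denominator whenever the query has edges — the inclusive reading.

**Directionality.** Scores are computed over the query's elements, so
`match_descriptors(q, t)` and `match_descriptors(t, q)` differ when the
descriptors differ in size. No symmetrization is imposed;
`rank_candidates()` ranks targets for a fixed query, which is the
operation actually used to map model parameters onto clinical ones.

The exact assignment is a depth-first search with an upper-bound prune
and is feasible because descriptors are small (a handful of concepts);
its results are verified against full enumeration in the test suite.
Reproducing any particular deployed similarity figure (e.g. a specific
98% match) is out of scope: such values depend on proprietary
cross-ontology mapping networks that are not published.

## 4. Penalty-weighted network search

Association networks mix evidence qualities: a co-immunoprecipitation
PPI is more trustworthy than a two-hybrid one. `penalized_search()`
lets the user encode this as a non-negative penalty per edge class
(e.g. co-IP = 1, two-hybrid = 3, `penalty_table()`) and finds paths
minimizing accumulated penalty — shorter *and* higher-quality routes
win. The search is the weighted generalization of breadth-first
expansion (uniform-cost search); with unit penalties it reduces exactly
to BFS hop distance, which the tests assert.

Retention follows two modes: `best` keeps the complete set of
minimum-penalty simple paths; `all_below` keeps every simple path with
penalty at or below a user threshold, enumerated depth-first with
pruning (admissible because penalties are non-negative, using the exact
remaining-penalty bound from a uniform-cost pass). Since the number of
sub-threshold simple paths can grow exponentially, enumeration truncates
at `max_paths` (default 1000) with an explicit `truncated` attribute —
never silently. Edges are undirected (the association classes in scope
— PPI, gene–disease, co-morbidity — are symmetric); parallel edges of
different classes between one node pair are searched separately. Path
ordering is deterministic: lexicographic by node sequence in `best`
mode, by (penalty, node sequence) in `all_below`. Penalty comparisons
use an absolute tolerance of $10^{-9}$ so that floating-point penalty
sums cannot drop a tied optimal path.

`rank_nodes()` then re-ranks the nodes on the returned paths by
external quality annotations (disease association counts, expression
variability, ...). How penalty and quality should combine is not
prescribed anywhere, so the rule here is an explicit design choice:
each quality column is min–max normalized over the result nodes,
weighted and summed, and the min–max-normalized best path penalty
through the node is subtracted with weight `weight_penalty` (default
1). Nodes missing from the quality table get neutral normalized
quality 0; an all-equal column normalizes to 0 with a warning instead
of dividing by zero. The weights expose the rule rather than hide it —
rankings should be read as "under these weights".

## 5. Pathway grouping at a permutation FDR

Pathway collections from different databases describe the same biology
redundantly. `group_pathways()` connects two pathways when the Jaccard
index of their member sets, $J = |A \cap B| / |A \cup B|$, reaches a
threshold, and reports connected components of size ≥ 2 as groups —
components, not cliques, because grouping is meant as a partition and
components are the minimal-assumption partition of a thresholded
similarity graph.

The threshold comes from a permutation null
(`permutation_threshold()`): each of `n_perm` (default 1000) null
collections redraws every pathway's members uniformly without
replacement from the collection's member universe, preserving set
sizes — the standard null for set-overlap significance; the universe is
the union of observed members, so the null respects the identifier
space actually in play. For candidate thresholds $t$ (the sorted
observed pairwise values), the estimated FDR is the mean null count of
pairs ≥ $t$ divided by the observed count ≥ $t$; the smallest
admissible $t$ is returned. FDR is estimated over *pairs* (the objects
the null actually generates). "0% FDR" therefore means: no null pair
in any permutation reached the threshold — a conservative cut. When no
threshold is admissible the result says so explicitly instead of
raising an error, since disjoint collections are a legitimate input.
A published clustering of this kind (13 groups over 421 of 1367
pathways) depends on specific database releases and an unpublished
text-mined pathway set, so it is a motivating illustration here, not a
reproduction target.

## 6. Synthetic fixtures and what they show

`make_ontology_fixture()` builds disjoint `is_a` trees with distinct
prefixes plus random cross-tree `mapped_to` edges, and emits descriptor
pairs planted at known element distances (0, 1, 2, unreachable). The
planted distances are guaranteed: pair concepts sit on one root-to-leaf
chain, and mapping edges avoid that chain, so no shortcut can undercut
the tree distance; the unreachable element uses a prefix absent from
the graph. Expected aggregates are computed arithmetically from the
planted distances — not by the matching code — and the test suite
re-verifies them with a fully independent brute-force oracle
(queue-based BFS plus exhaustive assignment enumeration).

`make_network_fixture()` produces a connected random multigraph: a
random spanning tree of the cheapest class guarantees connectivity,
then each class is sprinkled independently per node pair.
`make_pathway_fixture()` plants groups sharing disjoint cores: with
core size $c$ and $p$ private members per pathway, within-group Jaccard
is $c/(c + 2p)$, so $p = \lfloor c(1-w)/(2w) \rfloor$ enforces a
within-group floor $w$. Defaults — 4 groups × 10 pathways, universe
2000, core 40, $w = 0.5$ — put within-group overlap (≥ 0.5) far above
both the between-group chance overlap (≈ 0.015) and the permutation
null maximum (≈ 0.1 at these set sizes), which is the regime in which
database-redundant pathway entries actually live. All generators are
deterministic under a fixed seed, down to byte-identical
serializations.

What passing these tests shows: the algorithms implement their
contracts exactly — optimal assignment, exact minimum penalties,
correct null calibration — and recover planted structure reliably (the
acceptance suite requires exact recovery of the planted partition in at
least 95 of 100 seeded runs). What they do not show: real ontologies
are not random trees (their branching and depth are heterogeneous, and
mapping edges are dense and correlated), real pathway collections have
heavy-tailed set sizes and nested (not disjoint-core) overlap, and
real association networks are scale-free rather than Erdős–Rényi.
Performance on real inputs therefore still depends on choosing
`max_steps`, penalties and FDR targets with the data in view.

## 7. Problem sizes and numerical conventions

The shipped test and acceptance runs use: 200 random descriptor
fixtures (≤ 5 query / ≤ 6 target elements, graphs ≤ 50 concepts) for
the assignment-oracle equivalence; 200 random typed networks (≤ 10
nodes) with all node pairs checked against exhaustive path enumeration;
and 100 planted pathway fixtures at the defaults above with 1000
permutations each. Score ties are resolved lexicographically
everywhere; all TSV output uses `.` decimals and 6 significant digits;
output files are written atomically (temp file + rename). Assignment
and penalty comparisons use absolute tolerances of $10^{-12}$ and
$10^{-9}$ respectively, far below the coarsest score spacing the
rational score values can produce at descriptor scale.

## 8. Known limitations

* Exact assignment is exponential in the worst case; it is intended for
  descriptor-sized inputs (tens of elements at most), not for matching
  whole pathways element-by-element.
* `all_below` path enumeration is exponential by nature; `max_paths`
  bounds work, at the cost of completeness (always flagged).
* The OBO reader covers the `[Term]`/`id`/`name`/`is_a`/
  `relationship`/`xref` subset that concept-graph construction needs —
  not OWL semantics, obsolete-term handling or transitive-closure
  materialization.
* Directed association networks are out of scope; all edges are
  treated as symmetric.
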