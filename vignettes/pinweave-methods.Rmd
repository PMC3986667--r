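---
title: "Homology-based interaction network construction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based interaction network construction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinweave)
```

## The problem

Many economically or ecologically important species — aquatic crustaceans
are a prominent example — have no sequenced genome and no curated
interactome. What they increasingly do have is a de novo transcriptome: a
set of assembled transcript clusters ("unigenes"). `pinweave` builds a
protein–protein interaction network (PIN) for such a target organism by
*interolog mapping*: an interaction observed between two proteins in a
model organism is transferred to the target when both proteins are
homologous to target unigenes. Six model organisms contribute by default —
*D. melanogaster*, *C. elegans*, *H. sapiens*, *R. norvegicus*,
*M. musculus* and *S. cerevisiae* — each yielding one sub-network, and the
sub-networks are merged iteratively into a single integrated PIN.

All sequence comparison happens outside the package: BLAST tabular files
(unigene-vs-proteome, BLASTX-style; and proteome-vs-proteome,
BLASTP-style) are inputs, as are PINA-style interaction lists, an OBO
ontology and per-protein GO annotation tables.

## Homology: the first-hit rule

Throughout, a query sequence's homolog is the **first** hit in file order
with E-value strictly below `1e-5` — BLAST writes hits per query in its
own ranking, and the pipeline honours that file order rather than
re-sorting by E-value. `best_hits()` makes this deterministic on arbitrary
input by breaking ties on rank, then lower E-value, then higher bitscore,
then lexicographic subject id. The cutoff is strict (`< 1e-5`); a hit at
exactly `1e-5` does not pass.

When a query organism is matched against the *integrated* network, the
target spans several organisms. The package concatenates the query
organism's hit tables against each previously integrated organism, in
integration order, restricts subjects to current network nodes, and applies
the first-hit rule to the concatenation. This reproduces the behaviour of a
BLASTP search against the pooled target proteome in which earlier-integrated
(genetically closer) organisms are searched first, and it is the design
choice made where the procedure was genuinely open.

## Sub-network construction

For one model organism, an interaction is kept iff both partner proteins
carry at least one unigene match. Kept edges and their endpoints form the
model-organism-based sub-network (`build_subnetwork()`); proteins with a
unigene match but no kept interaction are excluded from the node set,
because the sub-network is defined by its interactions. Unigenes and
proteins are deliberately *not* one-to-one: `map_unigenes()` inverts the
best-hit map into a multimap, and a protein may carry several unigenes.

Interaction lists are normalized first: `uniprotkb:` prefixes stripped,
unordered duplicates collapsed (with a count), self-interactions retained
but flagged, and protein IDs replaced by protein names where a name is
known (`normalize_protein_names()`), so that one protein written two ways
collapses to one node.

## Iterative integration and the confidence score

Sub-networks are merged one at a time in genetic-relationship order. At
each *turn*, the accumulating network is the **target** and the incoming
sub-network the **query**. Query proteins homologous to target nodes merge
into them (target names win); query edges translate through that mapping:

* both endpoints mapped and the translated edge already exists — the edge
  is **matched**, per-turn edge score `R = 3`;
* a target edge not matched this turn keeps `R = 2`;
* any query edge translating to a new pair is **added** with `R = 1`,
  unmapped query proteins entering under their own names.

Node ("point-matching") scores per turn: a target node that absorbed a
homologous query protein scores `2` when the merged proteins share a
unigene and `1` otherwise; all other nodes score `0`. The confidence score
of an interaction between proteins A and B is

$$S = \sum_{i=1}^{N} (A_i + R_i + B_i)$$

summed over all `N` turns (`N = 5` with six organisms), where `A_i`,
`B_i` are the endpoints' node scores and `R_i` the edge score at turn
`i`. Because a target edge accrues `R = 2` in every turn it goes
unmatched, the score rewards both conservation across organisms and early
entry from genetically close organisms. The maximum per turn is
`2 + 3 + 2 = 7`, so the maximal total with five turns is `35`, attained
exactly when an edge is matched every turn with same-unigene merges at
both endpoints. This per-turn accrual (including scoring the initial
target's edges in turn 1) is the only reading under which that stated
maximum is attainable, and it is the one implemented. A consequence worth
noting: any edge surviving to the end has `S ≥ 1` (an edge added in the
final turn by an unmerged pair), and ledgers record `0` for turns before
an edge or node existed.

Two further integration choices were open and are resolved as follows:
query→target mappings may be many-to-one (two query proteins may collapse
into one target protein; "first matched protein" is defined per query and
imposes no injectivity), and an edge matched in an early turn may be
re-matched (`R = 3`) by a later organism's identical edge.

`filter_by_score()` extracts the high-confidence network (conventional
cutoff `S ≥ 30`), `score_distribution()` bins scores in widths of 5, and
`hubs()` lists nodes with degree strictly above a cutoff (default 33).

## Topology

`topology_report()` summarises a network by node and edge counts,
diameter and average path length (hop distances; the average runs over
connected unordered pairs, so it is well defined on fragmented graphs),
mean local clustering coefficient
$C_v = 2e_v / (k_v(k_v-1))$, average degree (self-loops counted twice)
and *index aggregation*, the fraction of all nodes in the largest weakly
connected component. Since the networks are undirected, strong and weak
connectivity coincide and only the weak form is implemented. Nodes with
fewer than two neighbours contribute $C_v = 0$ to the mean by default
(`include_low_degree = FALSE` excludes them instead); self-loops are
excluded from clustering neighbourhoods. Statistics are computed on the
largest component by default, where diameter and path length are always
defined. The graph machinery is igraph; the test suite checks every
statistic against independent brute-force oracles (Floyd–Warshall,
union-find, triple-loop neighbour counting).

## Signaling sub-network and evolutionary origins

`extract_go_subnetwork()` pulls out the proteins annotated with a GO term
— by default "signaling", GO:0023052 — together with the interactions
among them; seeds interacting with no other seed are reported as
isolated. Annotations should first be closed under `is_a` ancestors
(`propagate_annotations()`), so any descendant of the signaling term
qualifies; matching on the direct annotations only is available by
skipping propagation. With `expand_neighbors = TRUE` the sub-network also
includes every neighbour of a seed and all seed-incident edges.

Each protein and each interaction is assigned an evolutionary origin from
the organisms it occurs in (taken from the integration ledgers): **P**
(primitive) if present in any primitive organism, else **B** (bilaterian),
else **V** (vertebrate). An interaction's *evo-group* is the ordered
triple of its two protein origins and its own origin; its *complete
origin* is the latest of the three — the stage at which its last component
appeared. `pathway_origin_profile()` tallies complete origins over the
interactions internal to a pathway's member set, giving the stage profile
of each pathway.

## Function assignment

Unclassified proteins inherit GO biological-process terms from their
network neighbours by a modified majority rule (`assign_functions()`): a
term is assigned when the annotated neighbours carrying it exceed
**strictly more than 25%** of the annotated neighbours (the threshold
replaces a fixed top-three rule, so proteins with many annotations lose
nothing); a protein with exactly one annotated neighbour inherits all of
its terms. Rounds are synchronous — every assignment in a round is
computed from the previous round's state, so node iteration order cannot
change the result — and iterate until a round assigns nothing. Newly
assigned proteins count as classified, with their inferred term sets, in
later rounds.

Two readings of the rule's denominator are defensible ("total number of
neighbor proteins" could mean all neighbours or annotated neighbours);
the package defaults to annotated neighbours — consistent with the
counting step that precedes it — and exposes `denominator = "all"` for the
other reading. Counting on ancestor-closed annotations is available via
`propagate = TRUE`.

`go_depth()` places terms in the ontology (root depth 1, shortest `is_a`
path for multi-parent terms) and `depth_distribution()` profiles the
specificity of new assignments. `hide_annotations()` plus
`recovery_evaluation()` measure how well hidden labels are recovered; in
the perfect-homophily limit (every neighbour shares the label) recall is
1 by construction, which the tests verify.

## The synthetic universe

Because the real inputs require transcriptome assembly and database
downloads, validation runs on a generated universe
(`generate_universe()`) with known ground truth. It emulates:

* **ortholog families** shared across the six organisms, each organism
  retaining a family member with a stage-dependent probability (defaults
  0.75–0.9);
* **family-level interactions** (density 0.08 over family pairs) realized
  per organism with conservation probability 0.7 — values chosen to give
  sub-networks of a few dozen proteins whose integrated network shows the
  full range of per-turn score histories;
* **homology hit tables** with true hits log-uniform in E-value on
  [1e-50, 1e-6] and decoys on [1e-4, 1], so the 1e-5 first-hit rule
  recovers planted orthologs with zero errors (a property the tests
  assert rather than assume);
* a **rooted GO DAG** (30 terms, depth ≤ 6) grown by attaching each term
  to 1–2 existing parents — acyclic by construction — containing a
  "signaling" term with guaranteed descendants;
* **planted labels**: ~70% of families annotated (gated per family, so
  the unannotated minority of network nodes is realistic rather than
  vanishing under the union over merged proteins), and a **planted
  pathway** of 8 families chained together and labelled with signaling
  descendants; pathway families are always present in the first organism
  so the pathway is connected there when conservation is 1.

Everything is a deterministic function of the seed, and
`write_fixture()`/`read_fixture()` round-trip the universe through the
same plain-text formats (MITAB-lite, BLAST outfmt-6, OBO) used for real
data — numeric fields are written with 17 significant digits so the round
trip is exact.

What the generator does *not* emulate: realistic degree distributions
(hubs, scale-free tails), correlated annotation error, paralog confusion
(decoy E-values never cross the cutoff), or sequence-level effects.
Passing tests therefore demonstrate correctness of the algorithms under
clean homology signal, not robustness to noisy real-world BLAST output.

## Problem sizes and defaults

The bundled analyses and tests run universes of 30–60 families with six
organisms — integrated networks of ~40–60 proteins and ~100 interactions —
sizes at which every brute-force oracle (all-pairs shortest paths,
union-find, event replay) is exact and fast. Tunables with their defaults:
E-value cutoff `1e-5` (strict), score bin width `5`, high-confidence
cutoff `S ≥ 30`, hub cutoff degree `> 33`, signaling term `GO:0023052`,
assignment threshold `0.25`. All are surfaced in `pipeline_config()`, so
running on real data is a configuration change, not a code change.

## Known limitations

* The per-turn accrual makes `S` depend on integration order; the order
  encodes genetic relationship and is an input, not inferred.
* Name-collision between an unmapped query protein and an existing node
  merges them silently by name; identifiers are assumed globally
  consistent after name normalization.
* `read_obo` parses the `id`/`name`/`namespace`/`is_a` subset of OBO
  only; relationship types other than `is_a` are ignored.
* The assignment rule propagates annotation errors transitively across
  rounds; provenance (supporting fraction, round) is recorded for audit.
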