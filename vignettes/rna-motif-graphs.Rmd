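---
title: "Graph-based RNA motif extraction, similarity and evolution modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based RNA motif extraction, similarity and evolution modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamotifs)
```

## The representation

An RNA 3D structure is reduced to a nucleotide-level attributed graph: one
node per residue, ordered along the concatenated chains, and edges carrying a
three-component indicator over (covalent, Watson–Crick, non-Watson–Crick)
interaction types. A residue pair annotated with several interaction types
yields a single multi-hot edge, e.g. `(0, 1, 1)` for a pair that is both WC
and non-WC annotated. Two views of each graph are kept throughout: the full
view with non-WC edges, which carries the conformational detail, and the
WC-only view (`without_nonwc()`), on which all motif searching runs — non-WC
edges would otherwise multiply the pattern space without changing the
WC-defined motif classes.

Residues are identified by `(chain, author number, insertion code)` keys;
motif membership and sizes are computed on keys only, never on coordinates.
Structure ingestion normalizes the input the way large-scale PDB processing
requires: only the first model of multi-model (NMR) entries is kept,
two-letter chain identifiers are remapped deterministically to the first
unused symbol of `A–Z a–z 0–9` in encounter order (an error is raised beyond
62 chains), and atom-serial overflow records are accepted and re-sequenced
from 1. Hetero/modified residues inside RNA chains are kept as nodes with
base `OTHER`; dropping them would silently break backbone adjacency.

Base-pair annotations enter through a one-pair-per-line text dialect
(`"A1-A8 : WC"`); any production annotation tool can be adapted to it by a
one-line converter. For self-contained fixtures, `naive_annotate()` calls
pairs geometrically: complementary bases (A–U, G–C, G–U) whose C1'–C1'
distance lies in [8.5, 12] Å, matched greedily by distance with at most one
WC partner per residue. The window brackets the ~10.4 Å C1'–C1' separation
of paired ribonucleotides; the annotator is fixture-grade by design (no base
planes, no edge/face geometry) and never emits non-WC calls.

## Compression and motif search

Motifs are defined by their closing WC pairs: hairpin loops, internal loops,
bulges and 3- to 8-way junctions. Searching for them naively requires one
explicit subgraph pattern per loop-size combination, and subgraph
isomorphism cost grows steeply with pattern size. Instead, every maximal run
of consecutive unpaired nucleotides lying *between* two retained nodes of
one chain is collapsed into a single super-edge whose weight is the run
length and whose labels store the collapsed residues in order
(`compress_graph()`). One ranged pattern per motif class then covers all
sizes: a pattern strand with range `[lo, hi]` matches a super-edge of weight
`w` iff `lo <= w <= hi`, and an empty strand (`lo = 0`, as in coaxially
stacked junction arms) matches a plain covalent edge between two paired
nodes. Matching is a small backtracking embedding search over the compressed
graph; matches are decompressed into full member sets and deduplicated by
(class, member-set). `decompress_graph()` is an exact inverse, which the
tests check by label-preserving graph equality rather than isomorphism.

Two deliberate boundary choices: chain-terminal unpaired runs (dangling
ends) are never compressed — they lack a paired flank on one side — and
consequently can never appear inside a motif; and helices are not trimmed,
so a motif's closing pair is the nearest flanking WC pair on each strand.
Hairpin loops are bounded at 1–20 unpaired nucleotides (larger loops are
thermodynamically unstable); internal/bulge/junction strands default to at
most 20 each, junction strand minima to 0. In pseudoknotted regions the
WC-pair graph is not a tree, and the same cycle-of-pairs patterns then
legitimately match crossing geometries (a kissing hairpin contains a
junction-shaped cycle); the synthetic generator's expected inventories
include these occurrences, enumerated once with the independent
uncompressed brute-force matcher used by the tests.

Motif size is the number of unpaired nucleotides, so the minimal internal
loop (1–1) has size 2; the closing-pair nucleotides are members but are not
counted in the size. Because published counts sometimes quote the 1–1 loop
as "6 nucleotides", the member count is exposed separately (`n_members` in
the store).

`custom_search()` serves user-defined queries: exact attribute-constrained
subgraph monomorphism at full node resolution, non-WC edges included, with
a 30-node capacity guard, deduplicated by member set.

## Pseudoknots

Pseudoknots have no single closed pattern, so they are detected from
extended dot-bracket text instead. The WC view is converted with first-fit
interval coloring ordered by left endpoint over four bracket pages
(`() [] {} <>`); four pages cover every structure the generator can emit,
and exceeding them raises a capacity error naming the offending pair rather
than silently mislabeling. Detection scans for square-bracket (page ≥ 1)
families, seeds a span from first opening to last closing bracket, extends
the span while any inside bracket has its partner outside, and merges
overlapping spans.

Classification into the six topological types is a deterministic cascade,
most specific first: HHH → HLIN → HLOUT → LL → H → LR. For each crossing
family the two endpoint groups (5' and 3' partners) are assigned a context:
inside a pure hairpin loop, inside a hairpin loop decorated with inserted
simple hairpin elements, inside a non-hairpin loop, or single-stranded.
Kissing hairpins (HHH) need two distinct hairpin-loop contexts; HLIN is the
decorated-hairpin-to-single-strand geometry; HLOUT is the plain H geometry
with an extra hairpin in the connecting single strand; LL covers any
endpoint group in a non-hairpin (internal/bulge/junction) loop; H is the
undecorated hairpin-loop-to-single-strand case; LR is strictly the
fallback, and additionally absorbs spans containing a third crossing family
or mixed endpoint contexts — the type naturally described as "long range
and complex". The cascade order prevents H from swallowing its decorated
variants. Classification sees pairing topology only: it is invariant to
sequence content and to padding with external unpaired nucleotides.

One known ambiguity is inherent to topology-only rules: a crossing group
sitting in an internal loop whose inner helix ends in a hairpin is
indistinguishable from a hairpin loop with one inserted hairpin; the
cascade resolves it by the far group's context (single-stranded → HLIN,
loop → LL).

## The catalog

Motif occurrences are stored with the columns the CSV contract exposes
(`ID`, `motif type`, `PDB ID`, `nucleotide number`) plus member keys, both
graph-view JSON payloads and the motif coordinates as PDB text. The store is
a single-file, schema-versioned JSON document with in-memory query
semantics; occurrences are stored per structure and never deduplicated
across entries, since the library statistics count occurrences. ZIP export
writes one `<motif_id>.pdb` entry per row with an uncompressed (STORE)
archive writer implemented in the package.

Conformation classification partitions fetched motifs by exact graph
topology including edge attributes, on the with-non-WC view by default —
non-WC decoration is precisely what distinguishes conformations of one
WC-defined motif. The canonical key is computed by iterative neighborhood
refinement on (degree, sorted incident attribute vectors) followed by the
lexicographically minimal adjacency serialization over refinement-compatible
orderings (capped at 5000 orderings, beyond which the refinement signature
alone is used); key collisions are always confirmed by an explicit
attribute-preserving isomorphism test, so the partition is exact even where
the key is only a filter. Frequencies sum to the fetch count and the
partition is independent of insertion order.

## Motif-based RNA similarity

Motif-motif similarity uses a Weisfeiler–Lehman subtree kernel made
edge-attribute-aware: the initial node label is the sorted multiset of
incident edge-attribute vectors, neighbor messages carry the connecting
edge attribute, and three refinement rounds (the default) are enough to
separate loop-sized graphs while staying robust to size differences. Scores
are cosine-normalized feature-count inner products, hence in [0, 1],
symmetric and relabel-invariant.

RNA-RNA similarity aggregates matched motif pairs:

    RS(i, j) = 2 * sum_m [ (W_m + W_sigma(m))/2 * S_{m, sigma(m)} ]
               / (sum W_i + sum W_j)

with weights `W = L * (1 + NC)` (L member nucleotides, NC non-WC edges) and
`sigma` the optimal one-to-one matching minimizing total cost `1 - S`
(Hungarian algorithm, rectangular via zero-cost padding; unmatched motifs
contribute only through the denominator). The matched-pair weight is taken
as the mean `(W_m + W_sigma(m))/2`, the unique symmetric choice for which
identical inventories score exactly 1 under this normalization. RS is
symmetric and bounded in [0, 1].

Clustering runs Leiden community detection (modularity objective,
resolution exposed, default 1.0) on the dense weighted similarity graph; no
similarity threshold is applied, so weak edges are retained and weighted
down naturally. The meta-graph keeps clusters with more than 10 members and
weights meta-edges by mean inter-cluster similarity. Intra- versus
inter-family score distributions are compared with the two-sided
Mann-Whitney U test.

## Modelling similarity evolution

The density `f(s, t)` of pairwise similarity scores is modelled with a
drift–diffusion (Fokker–Planck) equation: drift `A(s)` for systematic
change (motif swapping between related structures), diffusion `D` for
random change (mutation). The stationary solution is
`f(s) ∝ exp((1/D) ∫ A ds)`; the reference drift `A(s) = -D/(2s)` yields the
power law `f ∝ s^{-1/2}`.

Numerical choices: the domain is truncated to `[s_min, 1]`, default
`s_min = 0.01`, with reflecting boundaries — the power-law density is
integrable at 0 but the drift diverges there, so an untruncated walk is
ill-posed. The default grid is logarithmic (400 points) to match power-law
geometry; the drift integral is evaluated per grid interval with 7-point
Gauss–Legendre quadrature, so closed-form checks hold to ~1e-6 even near
`s_min`, and densities are normalized with trapezoidal weights on their own
grid. Drift inversion `A = D f'/f` uses nonuniform central differences
(one-sided at the ends); power-law fits exclude the lowest and highest 5%
of support to avoid boundary-layer bias, and sample inputs are trimmed at
their 5%/95% quantiles and binned into 40 log-spaced bins. Simulation is
Euler–Maruyama with reflection, run in compiled code for the built-in
drifts and driven by R's RNG so seeds propagate; a step-size guard rejects
`|A| dt` comparable to the domain width. The simulation experiment in the
acceptance suite uses 1e5 walkers, 1e4 steps and `dt = 2e-4`: large enough
steps to mix several relaxation times, small enough that the boundary-layer
discretization bias stays well inside the ±0.05 exponent check.

## The synthetic generator

Every quantitative claim in the tests is exercised on generated structures
with known ground truth: planted hairpins (loops 1–20), internal loops,
bulges, junctions (3–8 ways, strands 0–4 in the random suite), six
pseudoknot scaffolds, optional non-WC decorations between loop residues,
complementary sequences on planted pairs, and a schematic ladder layout
placing paired C1' atoms at 10.4 Å, ladder rows 6.5 Å apart and unpaired
residues far away — chosen so the geometric annotator recovers exactly the
planted pairs and nothing else. Suites are seeded and bit-reproducible,
with a deterministic coverage block (all classes, all hairpin sizes, all
junction ways, all six pseudoknot classes, decorated and undecorated)
before the random tail.

What the generator does not emulate — and hence what green tests do not
show about real data: real base-pair geometry (the annotator is distance
based), non-canonical pair families and their edge/face subtypes, modified
residues beyond the `OTHER` base class, crystallographic artifacts
(alternate locations, missing residues mid-chain), and realistic sequence
or length distributions. Tests demonstrate algorithmic correctness of the
pipeline, not annotation accuracy on experimental structures, for which an
external annotation tool should feed the dialect adapter.

## Problem sizes used by the checks

The property suites run at: 500 structures for compression round-trips, 300
(filtered to ≤ 25 nt) for matcher-versus-brute-force equivalence, 200 for
planted-inventory recovery, 300 for pseudoknot detection versus the
crossing-pair check, 1000 motif-inventory fixtures for similarity
bounds/symmetry/self-similarity, 100 random rectangular cost matrices up to
6×6 for assignment optimality, 20 random smooth drifts for the
drift-density consistency loop, and one 1e5-walker simulation for the
stationary exponent. These sizes make every distributional check stable
under reseeding while keeping the full suite comfortably within a
coffee-break run on one core.

## Known limitations

* Base-pair annotation quality is delegated: the built-in annotator is
  deliberately schematic.
* Leontis–Westhof edge/face subtypes of non-WC pairs are out of scope; all
  non-WC interactions share one attribute channel.
* The pseudoknot cascade is a topological operationalization of pictorially
  defined classes; borderline decorated geometries (HLIN vs LL) are resolved
  by rule order as described above.
* The dot-bracket converter supports at most four crossing families.
* `ways` reported for junction-shaped matches in pseudoknotted (non-tree)
  regions depends on which cycle pattern found the member set first; the
  (class, size, member-set) identity is canonical.
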