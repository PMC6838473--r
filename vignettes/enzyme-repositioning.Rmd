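---
title: "Enzyme re-positioning by reaction similarity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme re-positioning by reaction similarity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzrepo)
```

## The problem

Many valuable secondary metabolites are made only by plants, and the genes
behind those biosynthetic steps rarely have bacterial homologs that sequence
search can find — the pathways are taxon-specific, and some steps are known
only as *orphan* enzymatic reactions with no assigned gene at all. Enzyme
re-positioning inverts the search axis: instead of asking "which bacterial
gene looks like this plant gene?", it asks "which bacterial **reaction**
performs the same chemical change?", and then reports the genes behind that
reaction as candidates to substitute for the plant enzyme. Because the
query is a substrate/product compound pair, the approach works even when
the target enzyme is an orphan.

`enzrepo` implements this screen end to end: a reaction-database model, an
RDM-based reaction-similarity engine, taxon-specificity filtering, the
all-pairs screen with thresholding and ranking, per-organism phylogenetic
profiling, a sequence-independence check by local protein alignment, and a
seeded synthetic-data generator that makes the whole pipeline testable
without any external database.

## Reaction similarity through RDM patterns

Two reactions are considered similar when the *chemical changes* they
perform are similar, not when their substrates are globally similar. The
engine works in three stages.

**Atom mapping.** For a substrate/product pair the maximum common
connected-subgraph mapping is computed over the heavy-atom graphs. Mapped
atoms must share an element, and bond *existence* must agree in both
directions inside the mapped set, but bond *orders* are deliberately not a
compatibility constraint — an order change (C–O to C=O) is exactly the kind
of event the method must detect, and an order-strict mapping would exclude
the reaction center itself. Exact search is a backtracking enumeration over
connected extensions with a reachability bound (compiled code); above a
configurable cap of 30 heavy atoms per graph a documented greedy extension
heuristic is used instead and the mapping is labeled with its mode. Among
equal-size maximum mappings the lexicographically smallest sequence of
(substrate index, product index) pairs is returned, which makes every
downstream number bit-reproducible.

**Atom types and reaction centers.** Every atom carries a deterministic
code `ELEMENT.hyb.ring.het`: hybridization class (`sp3`, `sp2`, `ar`, `sp`)
derived from incident bond orders, ring membership (`rg`/`ac`, an atom is
in a ring iff it lies on a cycle, the flag equivalent of
smallest-set-of-smallest-rings membership), and the number of non-carbon
heavy neighbors bucketed as `h0`/`h1`/`h2`. This vocabulary captures the
granularity class of the classic KEGG atom types while being fully
specified in this package; patterns embed a vocabulary version string and
scores are never compared across versions. Aromaticity is taken from input
bond annotation only (bond type 4) — no perception is attempted, for
determinism. Hydrogens are implicit: explicit H atoms are stripped at parse
time (their counts are retained per heavy atom) because the reaction-center
descriptors concern heavy-atom changes. Stereochemistry, charges and
isotopes are out of scope.

A mapped atom is a **reaction center** iff its type code changes across the
mapping, or it is adjacent to an unmapped atom on either side, or an
incident bond inside the mapped set changes order. Each center yields one
RDM triple:

* **R** — the (before, after) type codes of the center itself;
* **D** — the multiset of type codes of unmapped atoms adjacent to the
  center (the difference region, gained or lost);
* **M** — the multiset of (before, after) type pairs of mapped atoms
  adjacent to the center (the matched region).

**Scoring.** Triple similarity is
`w_R [R equal] + w_D J(D_a, D_b) + w_M J(M_a, M_b)` with multiset Jaccard
`J` and default weights (0.5, 0.25, 0.25) — the reaction-center change
dominates, mirroring its primacy in the RDM idea. `J(∅, ∅)` is defined as
1: two pure bond-order-change centers with no difference region can and
should score 1. Pattern similarity is the maximum-weight bipartite matching
between the two triple multisets (solved exactly via igraph), normalized by
the larger pattern size; two empty patterns score 1, exactly one empty
scores 0. The score is symmetric, bounded in [0, 1], and equals 1 exactly
when the triple multisets are equal. The upstream web service this design
echoes never published its scoring formula, so the formula here is the
package's own documented definition, and its absolute values are not
comparable with that service's; whether that service weights R/D/M equally
is unknown and not guessed here.

```{r example}
ethanol <- compound_graph("eth", c("C", "C", "O"),
                          data.frame(a = c(0, 1), b = c(1, 2),
                                     order = c("1", "1")))
acetaldehyde <- compound_graph("ald", c("C", "C", "O"),
                               data.frame(a = c(0, 1), b = c(1, 2),
                                          order = c("1", "2")))
pair <- reactant_pair(ethanol, acetaldehyde)
extract_rdm(pair, map_atoms(pair))
```

## Taxon specificity and orphans

"Occurs only in taxon X" is operationalized in its strictest natural
reading: a reaction is **specific** to a group iff it has at least one
annotated gene and *every* annotated gene belongs to an organism of that
group; any outside gene makes it **shared**. The strict rule avoids
false-specific calls; a relaxed majority rule was considered and rejected
as a default because a single misassigned ortholog member would otherwise
silently flip screens' query sets (the classification function is pure, so
callers can implement relaxations on top of the evidence lists it
returns). Orphan reactions — no gene at all — are never assigned a taxon
from absence of data: they are **orphan-specific** only when explicit
pathway evidence (`pathway_taxa`) names exactly the query group, and
**unassigned** otherwise. The pathway-evidence mechanism is a declared
extension point: the reaction TSV dialect carries it as an optional sixth
column.

## The screen

`run_screen(db, "plant", "bacteria", threshold = 0.4)` takes every
plant-specific reaction (orphan-specific included by default) as a query
and every reaction with at least one bacterial gene as a target, scores all
pairs on their main reactant pairs, and keeps hits at or above the
threshold together with the hit reaction's genes restricted to bacterial
organisms. The 0.4 default threshold follows the screening convention the
method was introduced with; the tier summary (0.4 to 0.9 in steps of 0.1)
reproduces the usual nested reporting — candidate sets at a higher
threshold are always subsets of those at a lower one. Scoring is all-pairs
with an RDM cache (each reaction's pattern is computed once); an optional
coarse pre-filter on shared reaction-center elements exists as a config
flag, default off, because its conservativeness is empirical, not
analytic. Ranking ties are broken by hit reaction id; the run seed is
recorded in the result for provenance symmetry with the generator even
though the screen is deterministic. Multi-substrate reactions are reduced
to a single main pair (first pair in the record; first compound on each
side in the flat-file dialect) — the convention is recorded in the result
metadata, since upstream databases do not state how such reductions were
done historically.

Candidates aggregate per organism into a binary organism-by-query matrix
(reactions are counted, not genes), roll up clades over a Newick tree, and
export as an iTOL-style `DATASET_HEATMAP` plain-text annotation; rendering
is left to tree viewers, and raw marginal counts are exported alongside the
binary matrix.

## Sequence independence

The point of the method is to find candidates sequence search would miss,
so reports include a local-alignment check: Smith–Waterman with BLOSUM62
and BLAST-default-style affine gaps (open 11, extend 1; a gap of length k
costs 11 + k), identity computed over aligned columns (the BLAST
convention) and coverage as the aligned query span over query length. The
traceback is fully deterministic (start cell with maximal score, smallest
query then target index; diagonal preferred over gap-in-target over
gap-in-query at ties), so identity and coverage are reproducible, which is
also why the aligner is implemented in the package rather than delegated
to an external library with unspecified tie-breaking. A pair with no
positive-scoring local alignment is reported as `N.A.` — a deterministic,
tool-free analog of a no-hit result. E-values are not computed
(Karlin–Altschul statistics are out of scope), and exact reproduction of
any published BLAST numbers is explicitly not attempted since program
versions and parameters for those are unstated.

## The synthetic generator

The generator emulates the statistical shape of a real screen — specific,
shared and orphan reactions with cross-taxon analogs — while staying small
enough for the exact mapping path. Scaffolds are random connected graphs
(trees plus up to two ring-closing edges, 4–12 heavy atoms, elements
C/N/O/S) and every reaction is a single-center transformation applied to a
pendant site `attach–Ca–Cb–Cc[–X]` grafted onto the scaffold at a carbon.
The site is acyclic and all-single-bond, so every atom type entering the
RDM triples (the center `Cc` or `Cb`, the terminal `X`, their neighbors) is
independent of the scaffold by construction. A planted bacterial analog
applies the *same* site transformation to a *different* scaffold and
therefore scores exactly 1.0 against its plant query at perturbation 0 —
this is the generator's central invariant and the basis of the
planted-recovery tests.

Site signatures combine the terminal element (O/N/S), the operation
(bond-order raise to 2 or 3 on `Cc–X`, atom addition or removal at `Cc`,
order raise on `Cb–Cc`) and an optional methyl branch on `Cc`: 30 distinct
signatures. Planted signatures are unique within a database, and
non-planted bacterial and shared reactions use a nitrogen spacer at `Cb`
(orphan plant reactions an oxygen spacer), so no background reaction can
tie a planted analog at 1.0 and the analog wins rank 1 under the
deterministic tie-break.

The perturbation ladder degrades analogs cumulatively at their
RDM-relevant atoms: level 1 mutates the `Cb` spacer to nitrogen, level 2
adds a pendant oxygen on `Cc`, level 3 shifts the terminal element. Each
level was chosen to break a component that still matched at the previous
level, so the mean planted-pair score decreases strictly along the ladder
(about 1.00, 0.42, 0.41, 0.18 under the defaults).

Default counts — 20 plant queries with 20 planted analogs, 10 background
bacterial reactions, 5 shared, 3 orphan, over 5 plant / 8 bacterial / 2
other organisms — are the package's study conditions, sized so a complete
screen takes a couple of seconds and the full test suite a couple of
minutes on one core. One master seed feeds a labeled substream per
component (each reaction, each sequence), so changing one count never
perturbs another component's draws and a config is reproducible
byte-for-byte. Protein fixtures are random length-300 sequences with
mutated copies at configured substitution rates; at rate r the local
alignment identity of a (candidate, source) pair lands within a few points
of 100(1 − r).

What the generator does *not* emulate: chemically realistic molecules or
thermodynamically plausible transformations, reaction balancing,
stereochemistry, and the scale and redundancy of real ortholog databases.
Passing tests therefore demonstrate the correctness of the machinery —
mapping optimality, scoring axioms, recovery and ranking logic, format
round-trips — not the biological hit rate on real data, which depends on
licensed database content this package neither bundles nor fetches.

## Numerical and degenerate-input choices

* Mapping tie-break: lexicographic smallest pair sequence; empty mapping
  when no element-compatible atom pair exists.
* `J(∅, ∅) = 1`; two empty patterns score 1; one empty pattern scores 0.
* Bipartite matching solved with igraph's exact weighted matching
  (epsilon 1e-10); weights are small rationals, far above that resolution.
* Screens with an empty query set or target pool return an empty result
  with a warning status, not an error.
* Thresholds and tiers validated to [0, 1]; tiers must ascend strictly.
* Zero-length or illegal-character protein sequences error with the
  offending position; `X` is allowed and scored per the matrix.
* Tables are written with fixed column orders, LF line endings and
  C-locale sorting, so write–read–write cycles are byte-identical.

## Known limitations

* Exact mapping is exponential in the worst case; the 30-atom cap with the
  greedy fallback is a pragmatic bound, and greedy mappings carry no
  optimality guarantee (they are labeled, so results can be filtered).
* The similarity formula is this package's own; absolute score values are
  not comparable with other reaction-similarity tools, although the 0.4
  screening convention transfers as a rank-based heuristic.
* One score is produced per (query, hit reaction) and all the hit's
  target-taxon genes are attached; per-ortholog-group scoring would need
  per-group reactant pairs, which the data model does not carry.
* The tree annotation export is dataset-style plain text; no tree
  rendering is attempted.
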