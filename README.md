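# enzrepo — enzyme re-positioning by reaction similarity

Plant secondary metabolites (flavorings, pharmaceuticals, flavones) are
often made by enzymes that exist **only** in plants, so searching bacteria
for sequence homologs of those enzymes usually finds nothing. `enzrepo`
screens for bacterial substitute enzymes the other way around: by the
similarity of the **reactions** they perform, not of their gene sequences.
A query is a substrate/product compound pair; the screen returns bacterial
ortholog-cluster genes whose native reactions perform a similar chemical
change — and it works even when the plant enzyme is an *orphan* (reaction
known, gene unknown).

## Method in brief

For each reaction the package computes an atom mapping between substrate
and product (maximum common connected subgraph; elements must match, bond
orders may change) and extracts the **RDM pattern**: one triple per
reaction-center atom, recording the type change at the **R**eaction center,
the types gained/lost in the adjacent **D**ifference region, and the type
pairs of the conserved adjacent **M**atched region. Atom types are
deterministic codes `ELEMENT.hyb.ring.het` (e.g. `C.sp3.ac.h1`).

Two reactions are compared by a maximum-weight bipartite matching between
their triple multisets, with per-triple similarity

    s(a, b) = 0.5 [R_a = R_b] + 0.25 J(D_a, D_b) + 0.25 J(M_a, M_b)

(`J` = multiset Jaccard, `J(∅,∅) = 1`), normalized by the larger pattern
size. The score lives in [0, 1], is symmetric, and equals 1 exactly for
identical patterns. A screen takes every *taxon-specific* query reaction
(every annotated gene in the query group; orphans admitted on pathway
evidence), scores it against all reactions with genes in the target group,
keeps hits with score ≥ 0.4 (configurable), and reports the hit reactions'
target-taxon genes with tiered summary counts, per-strain phylogenetic
profiles, and a Smith–Waterman (BLOSUM62, gap 11/1) sequence-independence
report.

## Worked example

```r
library(enzrepo)

cfg <- generator_config(seed = 1)     # 20 plant queries, 20 planted analogs,
gen <- generate_database(cfg)         # background bacterial/shared/orphan reactions
gen$db
#> <reaction_db: 116 compounds, 58 reactions, 84 clusters, 15 organisms> [enzrepo synthetic (seed 1)]

res <- run_screen(gen$db, "plant", "bacteria", threshold = 0.4)
res
#> <screen_result [ok]: 23 queries (plant) x 35 targets (bacteria), threshold 0.40, 166 candidate hit(s)>
#>   queries with a candidate at score >= tier:
#>     0.4: 23
#>     ...
#>     0.9: 20

res$candidates[1:3, c("query_reaction_id", "hit_reaction_id", "score")]
#>   query_reaction_id hit_reaction_id     score
#> 1             R1001           R2001 1.0000000
#> 2             R1001           R2016 0.9583333
#> 3             R1001           R2002 0.6666667
```

Query `R1001` is a plant-specific reaction; its top hit `R2001` is the
planted bacterial analog performing the identical chemical change (score
1.0 — equal RDM patterns), followed by bacterial reactions with
progressively less similar transformations. The tier counts say how many
of the 23 queries (20 gene-annotated + 3 orphan) keep at least one
candidate as the threshold rises — 20 still have a candidate at 0.9.

What the change itself looks like:

```r
pair <- reactant_pair_of(gen$db, "R1001")
extract_rdm(pair, map_atoms(pair))
#> <rdm_pattern R1001.s>R1001.p: 2 reaction-center triple(s)>
#>   R C.sp3.ac.h1 -> C.sp2.ac.h1 | D {} | M {C.sp3.ac.h0>C.sp3.ac.h0, O.sp3.ac.h0>O.sp2.ac.h0}
#>   R O.sp3.ac.h0 -> O.sp2.ac.h0 | D {} | M {C.sp3.ac.h1>C.sp2.ac.h1}
```

— an alcohol-to-carbonyl style bond-order change: both atoms of the C–O
bond are reaction centers, nothing is gained or lost (`D` empty), and the
matched neighborhoods record the conserved context.

Profiling and the sequence-independence check:

```r
prof <- aggregate_by_organism(res, gen$db)
head(sort(prof$marginals, decreasing = TRUE), 3)
#> bac08 bac01 bac02
#>    23    22    22          # reactions each strain is predicted to substitute
export_itol_heatmap(prof, gen$tree, "itol_heatmap.txt")

fa <- generate_fasta(cfg)
head(sequence_independence_report(fa$candidates, fa$known), 4)
#>    query  target  score coverage identity
#> 1 CAND01 KNOWN01 1768.0    100.0    100.0
#> 2 CAND01 KNOWN02   41.0      4.7     42.9
#> 3 CAND01 KNOWN03   31.0      5.3     31.2
#> 4 CAND02 KNOWN01   40.0      3.3     60.0
```

A command-line wrapper with subcommands `synth`, `filter-specific`,
`search`, `profile` and `seqcheck` is installed at
`inst/cli/reposition.R` (run `Rscript <path> search --db DIR
--query-taxon plant --target-taxon bacteria --threshold 0.4 --out DIR`).

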