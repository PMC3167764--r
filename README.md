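# rxnunify

Reconciliation of heterogeneous biochemical reaction databases into a
non-redundant, cross-referenced set of unique reactions.

## The problem

Genome-scale metabolic reconstruction needs *all* known biochemical
reactions, but no single source database is complete: BRENDA, KEGG and
MetaCyc (and any databases shaped like them) each publish overlapping
reaction sets under their own compound identifiers, compound names,
reaction IDs and equation writing conventions. Finding the identical
reactions across sources is the hard part:

* one compound appears under different names ("Orthophosphate" /
  "phosphate"), different spellings ("alpha, alpha-Trehalose" /
  "alpha,alpha-trehalose" / "α,α-trehalose"), different protonation states
  (acetic acid vs. acetate), and with or without defined stereochemistry
  (β-D-glucose vs. glucose with an undefined anomeric centre);
* generic compounds ("an aldehyde") have no structure at all;
* equations differ in direction arrows, participant order, explicit
  `H2O`/`H+` participants, glycan vs. compound identifier spaces, and
  ambiguous cofactor placeholders (`NAD(P)H`);
* the same reaction sometimes occurs twice within one database.

`rxnunify` implements a two-step entity-resolution strategy for compounds —
**structure first, names second** — followed by reaction canonicalization,
a stoichiometric element-balance QC, and merging:

1. **Reduced InChI keys.** Each compound's InChI is decomposed into layers
   and the ionisation-dependent layers (`/q`, `/p`) and the isotope layer
   (`/i`) are dropped, keeping formula, connectivity (`/c`), hydrogen
   (`/h`) and stereo (`/b`, `/t`, `/m`, `/s`) layers. Protonation variants
   of one parent compound reduce to one key. Compounds with equal keys are
   merged (union-find).
2. **Normalized names.** Names are lower-cased, Greek glyphs transliterated,
   and every character outside `[a-z0-9+']` deleted ('+' for charged
   cofactors and the apostrophe for primes are kept). Name matching only
   merges pairs where at least one side has *no* structure — identical
   synonyms can name different compounds, so names never override structure
   evidence. A shipped table expands implicit stereo descriptors
   ("alanine" → "L-alanine").
3. **Stereo-relaxed tier (optional, on by default).** A compound whose key
   has no stereo layers may merge with a fully-defined form sharing the
   same stereo-stripped key; the representative of each class is the member
   with the most defined stereo descriptors (complete stereochemistry is
   favored).
4. **Reaction canonicalization.** Glycan alias IDs are substituted by their
   canonical compound IDs; `NAD(P)+/NAD(P)H` placeholder reactions are split
   into an NADP form (original ID) and an NAD form (ID + `_WOP`, "WithOut
   Phosphate"); element balance is checked (see below) *before* `H2O` and
   `H+` participants are removed from both sides; each reaction then gets a
   direction-agnostic key: both sides as sorted multisets of
   (compound class, coefficient), side order canonical, so `A = B` and
   `B <=> A` collide.
5. **Balance QC.** Per-element totals (from the neutral-parent InChI formula
   layers) are compared across sides: `balanced`; `balanced_tolerated` when
   the difference is only whole protons and/or waters missing from one side
   (a·H + b·H2O); `incomplete` otherwise, with the atom deficits reported in
   the *Missing Substrate* / *Missing Product* columns; `undetermined` when
   a participant has no formula or a symbolic coefficient `n`.
6. **Merge & export.** Reactions sharing a key become one unique reaction
   with per-source member IDs, the union of EC numbers (complete,
   incomplete, or `SPONTANEOUS`), pass-through pathway annotations and the
   worst-case balance status; overlap (Venn) statistics and a three-table
   CSV export (`Reactions.csv`, `Compounds.csv`, `Links.csv`) summarize the
   result.

A seeded synthetic fixture generator (`generate_fixture()`) produces
multi-source dumps exercising every one of these obstacles with known
ground truth, and `score_recovery()` computes pairwise precision/recall of
the recovered compound and reaction classes plus a balance-status confusion
matrix.

## Worked example

The package ships a synthetic three-source worked example
(`inst/extdata/worked_example/`, see its README): twelve reaction records
that write three biochemical reactions in different forms — tautomer names
and a within-source duplicate, an explicit `H+` in one source only, a
glycan alias plus defined/undefined glucose stereochemistry.

```r
library(rxnunify)
dir <- system.file("extdata", "worked_example", package = "rxnunify")
dumps <- lapply(list.files(dir, pattern = "[.]json$", full.names = TRUE),
                read_dump)
res <- reconcile(dumps)
res$stats
for (m in res$merged) print(m)
subset(res$balance, status != "balanced")
```

prints

```
unique reactions: 3
EC/reaction combinations: 3
  BRENDA&KEGG&MetaCyc            3
<UR00001 [BRENDA,KEGG,MetaCyc] 3-hydroxy-1H-quinolin-4-one + O2 <=> CO + N-formylanthranilate | 4 member(s), balanced>
<UR00002 [BRENDA,KEGG,MetaCyc] diphosphate <=> 2 phosphate | 3 member(s), balanced>
<UR00003 [BRENDA,KEGG,MetaCyc] alpha, alpha-trehalose <=> 2 beta-Dglucose | 5 member(s), balanced>
    source           reaction_id             status missing_substrate missing_product
11 MetaCyc INORGPYROPHOSPHAT-RXN balanced_tolerated                 H
```

The twelve records collapse to 3 unique reactions, each present in all
three sources. `UR00001` has four members because KEGG lists the reaction
twice under tautomer names; `UR00003` has five, reachable only after the
glycan alias G00293 → C01083 and the stereo-relaxed glucose merge (its
rendered equation uses the β form — the stereo-preferred representative).
The MetaCyc diphosphatase writes an explicit `H+` product: its balance is
`balanced_tolerated` with a single `H` missing on the substrate side, not
`incomplete`, and after water/proton stripping it still merges with the
other two writings. `write_output_tables(res$merged, res$classes, "out/")`
exports the three-table CSV cross-reference.

The same pipeline is scriptable: `exec/rxnunify
{merge|match-compounds|balance|simulate|score}` writes outputs plus a
`manifest.json` with count reconciliation.

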