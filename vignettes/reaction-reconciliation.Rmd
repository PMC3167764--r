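---
title: "Reconciling biochemical reaction databases: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling biochemical reaction databases: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnunify)
```

## The reconciliation model

Given two or more source dumps — each a compound table (IDs, names,
synonyms, optional InChI/Molfile) and a reaction table (participants with
coefficients, direction, EC numbers, pathways) — the pipeline produces a
partition of all compounds into cross-source equivalence classes and a
partition of all reactions into unique reactions, with QC annotations.

The central modelling assumption is an evidence hierarchy for compound
identity:

1. **Structure beats names.** Two compounds are the same if their
   ionisation-invariant reduced InChI keys are equal. The reduced key keeps
   the formula, connectivity (`/c`), hydrogen (`/h`) and stereo (`/b`,
   `/t`, `/m`, `/s`) layers and drops charge (`/q`), protonation (`/p`) and
   isotope (`/i`) layers, so an acid and its conjugate base compare equal.
   Dropping `/i` is our choice: isotopic labelling never distinguishes
   database reactions in practice, and the kept-layer set is an argument
   (`kept_layers`) for users who disagree.
2. **Names only where structure is absent.** Exact equality of normalized
   names (case-folded, Greek glyphs transliterated, all characters outside
   `[a-z0-9+']` deleted) merges a pair only when at least one member has no
   structure. A name edge that would bridge two classes carrying *different*
   structure keys is refused and logged: shared trivial names across
   distinct chemicals are common, and letting them override structures
   would corrupt the partition. This guard is why the structure pass runs
   first — the union-find consults each class's accumulated key at edge
   time.
3. **Stereo-relaxed tier (default on, flagged).** Databases disagree on
   whether ambiguous centres (the anomeric C1 of glucose, say) are written
   as defined or undefined. A compound whose key carries *no* stereo layers
   may merge with a defined form sharing the same stereo-stripped key
   (formula + `/c` + `/h`). The merge is annotated `stereo_relaxed` in the
   class audit column so downstream users can filter it out, and the class
   representative is always the member with the most defined stereo
   descriptors (`?`-marked descriptors do not count). Ties break on
   lexicographic (source, compound ID) so all outputs are deterministic.

A known limitation of the tier-3 rule: a record with *partial* stereo
(e.g. a real glucose InChI with `/t2-,3-,4+,5-,6?` — four defined centres,
one undefined) carries stereo layers and therefore does not qualify as the
"undefined" endpoint. Relaxing the rule to descriptor-subset matching would
cover that case but also invites chains through partially-defined isomers;
we kept the conservative form. The implicit-stereo synonym table
("alanine" → "L-alanine", 19 chiral standard amino acids by default,
extendable via the `stereo_table` argument) covers the other common source
of stereo mismatch at the name level.

## Reaction canonicalization and the balance check

Preprocessing order matters and is fixed:

1. **Alias substitution** (glycan → compound IDs), with transitive chains
   resolved and cycles rejected; absorbed alias records donate their names
   to the canonical record's synonyms.
2. **Cofactor placeholder splitting.** A reaction written with
   `NAD(P)+`/`NAD(P)H` (or the `NADP/H_OR_NO_P` dialect) becomes two: the
   NADP form under the original ID and the NAD form under ID + `_WOP`.
   Substitution targets are resolved by normalized name within the source
   and created as structure-less records if missing. A placeholder without
   its redox partner is malformed; it passes through unsplit with a
   warning rather than failing the run.
3. **Balance check, then stripping.** Element totals are compared *before*
   water/proton removal — otherwise the tolerance below could never see the
   discrepancy it is meant to tolerate. Formulas come from the
   neutral-parent InChI formula layer (what a standard InChI prints before
   any `/p` layer), so protonation differences surface as H-count
   differences and land in the tolerance rule; explicit charge balance is
   deliberately not checked. A structure-less member of a class inherits
   the class representative's formula; `H+` and `H2O` are recognized by
   name when no structure is given, so structure-free dumps still balance.
   The tolerance accepts a deficit of a·H + b·H2O (a, b ≥ 0 integers) on
   *exactly one* side (`balanced_tolerated`); mixed-side H/O discrepancies
   are `incomplete` — the stricter reading of "only a proton or water is
   missing". `incomplete` deficits are reported per side as Hill-order
   formulas (Missing Substrate / Missing Product). Symbolic coefficients
   (`n`) and missing formulas give `undetermined`.
4. **Water/proton stripping** from both sides; a reaction whose side empties
   (`H2O = H+ + OH-`) is excluded from matching and logged.
5. **Direction-agnostic keys.** Each side becomes a sorted multiset of
   (class ID, coefficient); the lexicographically smaller rendering is
   placed first. Reversed writings therefore collide — the sources disagree
   too often on arrow semantics (`<=>` vs `=` vs `→`) for direction to be
   identity-bearing; original directions are preserved per member for the
   output table. Coefficients are part of the key (`A = 2 B` ≠ `A = 3 B`),
   and `n` matches only `n`.

Merged reactions take the union of member EC sets (no conflict resolution —
one source's single reaction ID legitimately maps to several EC numbers),
the union of pathway annotations, and a conservative balance status: any
`incomplete` member makes the merged reaction `incomplete`; otherwise the
best-documented status wins (`balanced` > `balanced_tolerated` >
`undetermined`). EC/reaction combination counts treat an empty EC set and
the `SPONTANEOUS` label as one combination each, which keeps the count
conserved and ≥ the unique-reaction count.

`unified_id`s are zero-padded ordinals over lexicographically sorted keys,
so identical inputs give byte-identical outputs across runs.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds a pool of base compounds with surrogate
structures: syntactically valid standard-InChI strings over small CHNO
formulas whose connectivity payload embeds a global serial, so every base
compound has a unique reduced key without requiring a structure converter.
Base reactions are element-balanced by construction (product formulas
partition the substrate atom totals). Each source then receives a perturbed
copy of everything, with one ground-truth label per entity:

* name-level noise invisible to normalization (case flips, hyphen/comma/
  space insertion), synonym renaming, Greek variants;
* `/p`-layer protonation variants and stereo-undefined variants;
* spurious `H2O`/`H+` participants (one side per reaction, labelled
  `balanced_tolerated`), reversed writing, within-source duplicates
  (labelled with swapped deficit columns), glycan aliases;
* placeholder collapse: the first source writes one `NAD(P)` reaction where
  the others write explicit NADP and NAD forms — the truth labels the split
  pair separately;
* structure dropping at the *compound* level (every copy loses its InChI,
  so the class is name-matched and its reactions `undetermined`);
* balance corruption: one product is replaced by a variant missing one
  CH2O unit, giving a known `incomplete` deficit; a corrupted copy is a
  genuinely different reaction and is labelled as its own class. Balance
  edits are mutually exclusive per copy so each label is derivable from a
  single edit; placeholder reactions are exempt from corruption.

Default rates (e.g. 50% case/hyphen noise, 25% protonation variants, 10%
duplicates/aliases/corruption) are fixed once to represent a heterogeneous
but internally consistent trio of sources. Default problem sizes — 24 pool
compounds, 12 reactions, 3 sources for unit tests; 80/200/3 for the balance
study; 20 seeds for the recovery study — keep the whole suite under a
minute while exercising every perturbation multiple times per run.

What the generator does **not** emulate: outright errors in source data
(wrong structures under a shared name beyond the opt-in collision mode,
malformed InChIs), partial stereo definitions, tautomer-distinct InChIs for
one compound, macromolecules/polymer formulas, and realistic network
topology. Perfect recovery on these fixtures therefore demonstrates that
the machinery implements its own rules exactly — not that real database
integration achieves precision/recall 1.0; on real corpora the curated
synonym tables and structure quality dominate.

## Numerical and degenerate-input choices

* Union-find with path compression; classes and IDs are independent of
  input order (asserted by permutation tests).
* The standard proton InChI `InChI=1S/p+1` has an empty formula layer; it
  parses (the error is reserved for truly formula-less strings like
  `InChI=1S/`), reduces to an empty key, and an empty key is treated as "no
  structure evidence" rather than allowing all such records to merge.
* Multi-component InChIs (salts) are reduced per component with `.`/`;`
  splitting and multiplier expansion, then component-sorted, so component
  order cannot affect the key.
* Unparsable formulas (repeating units, `*`) set `has_unknown` and route
  the reaction to `undetermined` rather than guessing counts.
* Equation parsing requires exactly one arrow token with flanking spaces
  and splits participants on `" + "`, which keeps `NAD+` and `H+` intact;
  a missing coefficient is 1.
* Dangling compound references exclude only the affected reaction, with a
  warning and an entry in the dump's `excluded` report.

## Command-line interface

`exec/rxnunify` wires the subcommands (`merge`, `match-compounds`,
`balance`, `simulate`, `score`) over the exported functions, writes outputs
atomically into `--out`, and emits a `manifest.json` whose counts reconcile
with the output files. Exit codes: 0 success, 1 input error, 2 internal
invariant violation (e.g. a Venn cell sum that does not match the unique
count — which is also asserted inside `overlap_stats()` on every run).
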