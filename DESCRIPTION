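Package: rxnunify
Title: Reconciliation of Heterogeneous Biochemical Reaction Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates two or more biochemical reaction databases into a
    non-redundant set of unique reactions with cross-references. Compounds
    are resolved across sources by a two-step comparison: first on
    ionisation-invariant reduced InChI structure keys, then on normalized
    names and synonyms, with an optional stereo-relaxed tier for compounds
    whose stereochemistry is undefined in one source. Reactions are
    canonicalized (glycan alias substitution, NAD(P)/H placeholder
    splitting, water/proton stripping, direction-agnostic keys), checked
    for element balance with a proton/water tolerance, merged into unique
    reactions with union EC sets and pathway annotations, and exported as
    a three-table CSV cross-reference. Includes a synthetic multi-source
    fixture generator with known ground truth for validating recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
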