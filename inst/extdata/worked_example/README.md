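# Synthetic three-source worked example

Three small JSON source dumps (KEGG-, MetaCyc- and BRENDA-styled, hence the
`_synthetic` suffix: they are hand-built reconstructions, not database
exports) containing twelve reaction records that write the same three
biochemical reactions in different forms:

1. quinoline-3,4-diol / 3-hydroxy-1H-quinolin-4-one dioxygenation — tautomer
   naming, a within-KEGG duplicate pair (R04915/R05719), participant order
   differences;
2. inorganic diphosphatase — an explicit `H+` product in one source only
   (balance tolerated, proton missing on the substrate side), water present
   everywhere;
3. trehalase — a glycan alias (G00293 -> C01083), undefined vs. defined
   anomeric stereochemistry of glucose, case/hyphen name variants, and a
   `β`/`beta` glyph difference.

Reconciling the three dumps must yield exactly 3 unique reactions.
InChI strings are internally consistent across the dumps; the small
molecules carry their real standard InChIs, the larger ones syntactically
valid surrogates.
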