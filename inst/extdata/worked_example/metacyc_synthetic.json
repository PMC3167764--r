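{
  "label": "MetaCyc",
  "compounds": [
    {"compound_id": "3-HYDROXY-QUINOLINONE", "name": "3-hydroxy-1H-quinolin-4-one",
     "synonyms": [],
     "inchi": "InChI=1S/C9H7NO2/c11-8-5-10-7-4-2-1-3-6(7)9(8)12/h1-5,11H"},
    {"compound_id": "OXYGEN-MOLECULE", "name": "oxygen", "synonyms": ["O2"],
     "inchi": "InChI=1S/O2/c1-2"},
    {"compound_id": "CARBON-MONOXIDE", "name": "carbon monoxide", "synonyms": ["CO"],
     "inchi": "InChI=1S/CO/c1-2"},
    {"compound_id": "N-FORMYLANTHRANILATE", "name": "N-formylanthranilate",
     "synonyms": [],
     "inchi": "InChI=1S/C8H7NO3/c10-5-9-7-4-2-1-3-6(7)8(11)12/h1-5H,(H,9,10)(H,11,12)"},
    {"compound_id": "WATER", "name": "H2O", "synonyms": ["water"],
     "inchi": "InChI=1S/H2O/h1H2"},
    {"compound_id": "PROTON", "name": "H+", "synonyms": ["proton"]},
    {"compound_id": "PPI", "name": "diphosphate", "synonyms": ["pyrophosphate"],
     "inchi": "InChI=1S/H4O7P2/c1-8(2,3)7-9(4,5)6/h(H2,1,2,3)(H2,4,5,6)"},
    {"compound_id": "Pi", "name": "phosphate", "synonyms": ["orthophosphate"],
     "inchi": "InChI=1S/H3O4P/c1-5(2,3)4/h(H3,1,2,3,4)"},
    {"compound_id": "TREHALOSE", "name": "trehalose",
     "synonyms": ["alpha,alpha-trehalose"],
     "inchi": "InChI=1S/C12H22O11/c13-1-3-5(15)7(17)9(19)11(21-3)23-12-10(20)8(18)6(16)4(2-14)22-12/h3-20H,1-2H2/t3-,4-,5-,6-,7+,8+,9-,10-,11-,12+/m1/s1"},
    {"compound_id": "GLC", "name": "β-D-glucose", "synonyms": ["beta-D-glucose"],
     "inchi": "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2/t2-,3-,4+,5-,6-/m1/s1"}
  ],
  "reactions": [
    {"reaction_id": "1.13.11.47-RXN", "ec_numbers": ["1.13.11.47"],
     "equation": "3-hydroxy-1H-quinolin-4-one + oxygen = carbon monoxide + N-formylanthranilate",
     "pathways": ["MetaCyc:quinoline-2-carboxylate degradation"]},
    {"reaction_id": "INORGPYROPHOSPHAT-RXN", "ec_numbers": ["3.6.1.1"],
     "equation": "diphosphate + H2O = 2 phosphate + H+",
     "pathways": ["MetaCyc:pyrophosphate hydrolysis"]},
    {"reaction_id": "TREHALA-RXN", "ec_numbers": ["3.2.1.28"],
     "equation": "trehalose + H2O → 2 β-D-glucose",
     "pathways": ["MetaCyc:trehalose degradation"]}
  ],
  "aliases": {}
}
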