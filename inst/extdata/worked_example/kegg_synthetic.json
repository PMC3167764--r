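{
  "label": "KEGG",
  "compounds": [
    {"compound_id": "C06340", "name": "Quinoline-3,4-diol",
     "synonyms": ["quinoline-3,4-diol"],
     "inchi": "InChI=1S/C9H7NO2/c11-8-5-10-7-4-2-1-3-6(7)9(8)12/h1-5,11H"},
    {"compound_id": "C06341", "name": "3-Hydroxy-1H-quinolin-4-one",
     "synonyms": ["3-hydroxy-4-quinolone"],
     "inchi": "InChI=1S/C9H7NO2/c11-8-5-10-7-4-2-1-3-6(7)9(8)12/h1-5,11H"},
    {"compound_id": "C00007", "name": "Oxygen", "synonyms": ["O2"],
     "inchi": "InChI=1S/O2/c1-2"},
    {"compound_id": "C00237", "name": "CO", "synonyms": ["Carbon monoxide"],
     "inchi": "InChI=1S/CO/c1-2"},
    {"compound_id": "C05830", "name": "Formylanthranilate",
     "synonyms": ["N-Formylanthranilate"],
     "inchi": "InChI=1S/C8H7NO3/c10-5-9-7-4-2-1-3-6(7)8(11)12/h1-5H,(H,9,10)(H,11,12)"},
    {"compound_id": "C00001", "name": "H2O", "synonyms": ["Water"],
     "inchi": "InChI=1S/H2O/h1H2"},
    {"compound_id": "C00013", "name": "Diphosphate",
     "synonyms": ["Pyrophosphate", "PPi"],
     "inchi": "InChI=1S/H4O7P2/c1-8(2,3)7-9(4,5)6/h(H2,1,2,3)(H2,4,5,6)"},
    {"compound_id": "C00009", "name": "Orthophosphate",
     "synonyms": ["Phosphate", "Pi"],
     "inchi": "InChI=1S/H3O4P/c1-5(2,3)4/h(H3,1,2,3,4)"},
    {"compound_id": "C01407", "name": "alpha, alpha-Trehalose",
     "synonyms": ["Trehalose"],
     "inchi": "InChI=1S/C12H22O11/c13-1-3-5(15)7(17)9(19)11(21-3)23-12-10(20)8(18)6(16)4(2-14)22-12/h3-20H,1-2H2/t3-,4-,5-,6-,7+,8+,9-,10-,11-,12+/m1/s1"},
    {"compound_id": "C01083", "name": "D-Glucose", "synonyms": ["Glucose"],
     "inchi": "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2"},
    {"compound_id": "G00293", "name": "D-Glucose", "synonyms": []}
  ],
  "reactions": [
    {"reaction_id": "R04915", "ec_numbers": ["1.13.11.47"],
     "equation": "Quinoline-3,4-diol + Oxygen <=> Formylanthranilate + CO",
     "pathways": ["KEGG:Tryptophan metabolism"]},
    {"reaction_id": "R05719", "ec_numbers": ["1.13.11.47"],
     "equation": "3-Hydroxy-1H-quinolin-4-one + Oxygen <=> Formylanthranilate + CO",
     "pathways": []},
    {"reaction_id": "R00004", "ec_numbers": ["3.6.1.1"],
     "equation": "Diphosphate + H2O <=> 2 Orthophosphate",
     "pathways": ["KEGG:Oxidative phosphorylation"]},
    {"reaction_id": "R00010", "ec_numbers": ["3.2.1.28"],
     "equation": "alpha, alpha-Trehalose + H2O <=> 2 D-Glucose",
     "pathways": ["KEGG:Starch and sucrose metabolism"]},
    {"reaction_id": "R06103", "ec_numbers": ["3.2.1.28"],
     "left": [{"coefficient": "1", "compound_id": "C01407"},
              {"coefficient": "1", "compound_id": "C00001"}],
     "right": [{"coefficient": "2", "compound_id": "G00293"}],
     "direction": "<=>",
     "pathways": []}
  ],
  "aliases": {"G00293": "C01083"}
}
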