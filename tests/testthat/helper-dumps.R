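# shared fixtures built in code

# a minimal two-source pair: acetic acid vs acetate (InChIs generated once
# with the official IUPAC InChI library and frozen here)
ACETIC_INCHI <- "InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)"
ACETATE_INCHI <- "InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)/p-1"
BETA_GLUCOSE_INCHI <-
  "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2/t2-,3-,4+,5-,6-/m1/s1"
UNDEF_ANOMER_GLUCOSE_INCHI <-
  "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2/t2-,3-,4+,5-,6?/m1/s1"

acetic_pair_dumps <- function() {
  a <- source_dump("A",
    compound_record("A", "a1", "acetic acid", inchi = ACETIC_INCHI))
  b <- source_dump("B",
    compound_record("B", "b1", "acetate", inchi = ACETATE_INCHI))
  list(a, b)
}

worked_example_dumps <- function() {
  dir <- system.file("extdata", "worked_example", package = "rxnunify")
  lapply(c("kegg_synthetic.json", "metacyc_synthetic.json",
           "brenda_synthetic.json"),
         function(f) read_dump(file.path(dir, f)))
}

# simple structured dump builder used across tests
simple_dump <- function(label, compounds, reactions = list(),
                        aliases = character(0)) {
  source_dump(label, do.call(rbind, compounds), reactions, aliases)
}
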