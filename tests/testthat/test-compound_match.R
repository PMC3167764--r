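test_that("structure tier merges ionisation variants across sources", {
  classes <- match_compounds(acetic_pair_dumps())
  expect_length(classes, 1)
  expect_length(classes[[1]]$members, 2)
  expect_true(all(classes[[1]]$tiers == "structure"))
})

test_that("a complete InChI outranks a conflicting stereo-less name", {
  # same full-stereo structure published under a stereo-less name in one
  # source: one class via the structure tier, the name never consulted
  a <- source_dump("A", compound_record(
    "A", "f1", "beta-D-Fructose 1,6-bisphosphate", inchi = BETA_GLUCOSE_INCHI))
  b <- source_dump("B", compound_record(
    "B", "f2", "D-fructose-1,6-bisphosphate", inchi = BETA_GLUCOSE_INCHI))
  classes <- match_compounds(list(a, b))
  expect_length(classes, 1)
})

test_that("name tier merges generic compounds, exact names only", {
  a <- source_dump("A", rbind(
    compound_record("A", "g1", "an aldehyde", is_generic = TRUE),
    compound_record("A", "g2", "an alcohol", is_generic = TRUE)))
  b <- source_dump("B", rbind(
    compound_record("B", "g3", "an aldehyde", is_generic = TRUE)))
  classes <- match_compounds(list(a, b))
  expect_length(classes, 2)
  sizes <- sort(vapply(classes, function(cl) length(cl$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))
})

test_that("the name-match guard refuses bridging two different structures", {
  # two structured compounds share a synonym; a structure-less third carries
  # the same name. The structureless one may join one class, but the two
  # structures must never merge.
  a <- source_dump("A", rbind(
    compound_record("A", "s1", "compound one", synonyms = "trivial name",
                    inchi = ACETIC_INCHI),
    compound_record("A", "s2", "compound two", synonyms = "trivial name",
                    inchi = "InChI=1S/CO/c1-2")))
  b <- source_dump("B", compound_record("B", "s3", "trivial name"))
  classes <- match_compounds(list(a, b))
  keys <- vapply(classes, function(cl)
    if (is.na(cl$representative_key)) "" else cl$representative_key,
    character(1))
  # the two distinct structures remain in distinct classes
  expect_length(classes, 2)
  expect_setequal(unique(keys[nzchar(keys)]),
                  c(reduce_inchi(ACETIC_INCHI), reduce_inchi("InChI=1S/CO/c1-2")))
  expect_true(length(attr(classes, "conflicts")) >= 1)
})

test_that("stereo-relaxed tier merges undefined with defined stereo", {
  undef <- "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2"
  a <- source_dump("A", compound_record("A", "d1", "D-glucose", inchi = undef))
  b <- source_dump("B", compound_record("B", "b1", "beta-D-glucose",
                                        inchi = BETA_GLUCOSE_INCHI))
  classes <- match_compounds(list(a, b), stereo_relaxed = TRUE)
  expect_length(classes, 1)
  # the fully-defined beta form is the representative
  expect_equal(classes[[1]]$representative$compound_id, "b1")
  expect_true("stereo_relaxed" %in% classes[[1]]$tiers)
  # with the tier off they stay apart
  expect_length(match_compounds(list(a, b), stereo_relaxed = FALSE), 2)
})

test_that("match output is a partition, order-invariant, key-consistent", {
  fx <- generate_fixture(fixture_spec(seed = 11))
  dumps <- lapply(fx$dumps, apply_aliases)
  dumps <- lapply(dumps, split_placeholders_in_dump)
  classes <- match_compounds(dumps)
  refs <- unlist(lapply(classes, function(cl)
    vapply(cl$members, function(m)
      paste(m$source, m$compound_id, sep = "\r"), character(1))))
  # partition: every compound exactly once
  expect_false(anyDuplicated(refs) > 0)
  uni <- compound_universe(dumps)
  expect_setequal(refs, paste(uni$source, uni$compound_id, sep = "\r"))
  # tier-1 completeness: no two classes share a reduced key
  rep_keys <- vapply(classes, function(cl) {
    ks <- unique(stats::na.omit(vapply(cl$members, function(m) {
      i <- which(uni$source == m$source & uni$compound_id == m$compound_id)
      uni$key[i]
    }, character(1))))
    paste(sort(ks), collapse = "|")
  }, character(1))
  all_keys <- unlist(strsplit(rep_keys[nzchar(rep_keys)], "|", fixed = TRUE))
  expect_false(anyDuplicated(all_keys) > 0)
  # order invariance: permuted dumps give identical membership sets
  classes2 <- match_compounds(rev(dumps))
  canon <- function(cls) sort(vapply(cls, function(cl)
    paste(sort(vapply(cl$members, function(m)
      paste(m$source, m$compound_id, sep = "\r"), character(1))),
      collapse = ";"), character(1)))
  expect_identical(canon(classes), canon(classes2))
})

test_that("with stereo_relaxed off no class holds two distinct keys", {
  fx <- generate_fixture(fixture_spec(seed = 5, stereo_undefined_variant = 0))
  dumps <- lapply(fx$dumps, apply_aliases)
  dumps <- lapply(dumps, split_placeholders_in_dump)
  classes <- match_compounds(dumps, stereo_relaxed = FALSE)
  uni <- compound_universe(dumps)
  ref_key <- stats::setNames(uni$key, paste(uni$source, uni$compound_id,
                                            sep = "\r"))
  for (cl in classes) {
    ks <- stats::na.omit(ref_key[vapply(cl$members, function(m)
      paste(m$source, m$compound_id, sep = "\r"), character(1))])
    expect_lte(length(unique(ks)), 1)
  }
})

test_that("representatives prefer complete stereochemistry, ties lexicographic", {
  members <- data.frame(
    source = c("B", "A"), compound_id = c("x", "y"),
    key = c(reduce_inchi(BETA_GLUCOSE_INCHI),
            reduce_inchi(UNDEF_ANOMER_GLUCOSE_INCHI)),
    stringsAsFactors = FALSE)
  expect_equal(select_representative(members)$compound_id, "x")
  # singleton
  expect_equal(select_representative(members[1, ])$compound_id, "x")
  # identical keys: lexicographically first (source, id)
  members$key <- members$key[1]
  expect_equal(select_representative(members)$source, "A")
})

test_that("apply_aliases rewrites refs transitively and absorbs records", {
  comps <- list(compound_record("K", "C01083", "D-Glucose"),
                compound_record("K", "G00293", "D-Glucose"),
                compound_record("K", "G9", "glc-alias"),
                compound_record("K", "T1", "trehalose"))
  r <- reaction_record("K", "R06103",
                       left = data.frame(coefficient = "1", compound_id = "T1"),
                       right = data.frame(coefficient = "2", compound_id = "G9"))
  d <- simple_dump("K", comps, list(r),
                   aliases = c(G00293 = "C01083", G9 = "G00293"))
  d2 <- apply_aliases(d)
  expect_equal(d2$reactions[[1]]$right$compound_id, "C01083")
  expect_false(any(c("G00293", "G9") %in% d2$compounds$compound_id))
  # alias names absorbed as synonyms of the canonical record
  syn <- d2$compounds$synonyms[[which(d2$compounds$compound_id == "C01083")]]
  expect_true("glc-alias" %in% syn)
  # identity on empty alias maps
  d3 <- simple_dump("K", comps[c(1, 4)], list())
  expect_identical(apply_aliases(d3), d3)
  # cycles error
  d4 <- simple_dump("K", comps, list(), aliases = c(G9 = "G00293", G00293 = "G9"))
  expect_error(apply_aliases(d4), "cycle")
})
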