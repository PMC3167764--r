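test_that("parse_equation handles the arrow dialects and coefficients", {
  eq <- parse_equation("Diphosphate + H2O <=> 2 Orthophosphate")
  expect_equal(eq$left$name, c("Diphosphate", "H2O"))
  expect_equal(eq$left$coefficient, c("1", "1"))
  expect_equal(eq$right$coefficient, "2")
  expect_equal(eq$direction, "reversible")

  eq <- parse_equation("trehalose + H2O → 2 β-D-glucose")
  expect_equal(eq$direction, "left_to_right")
  expect_equal(eq$right$coefficient, "2")
  expect_equal(eq$right$name, "β-D-glucose")

  eq <- parse_equation("n polymer = n monomer")
  expect_equal(eq$left$coefficient, "n")

  # participant names containing '+' survive (split needs flanking spaces)
  eq <- parse_equation("alcohol + NAD+ = aldehyde + NADH + H+")
  expect_equal(eq$right$name, c("aldehyde", "NADH", "H+"))

  expect_error(parse_equation("A = B = C"), "more than one arrow")
  expect_error(parse_equation("A B C"), "no arrow")
})

test_that("NAD(P) placeholder reactions split into NADP and _WOP forms", {
  comps <- list(
    compound_record("S", "alc", "an alcohol"),
    compound_record("S", "ald", "an aldehyde"),
    compound_record("S", "ph_ox", "NAD(P)+"),
    compound_record("S", "ph_red", "NAD(P)H"),
    compound_record("S", "nadp", "NADP+"),
    compound_record("S", "nadph", "NADPH"),
    compound_record("S", "nad", "NAD+"),
    compound_record("S", "nadh", "NADH"),
    compound_record("S", "h", "H+"))
  r <- reaction_record("S", "BRX1",
    left = data.frame(coefficient = c("1", "1"),
                      compound_id = c("alc", "ph_ox")),
    right = data.frame(coefficient = c("1", "1", "1"),
                       compound_id = c("ald", "ph_red", "h")))
  d <- simple_dump("S", comps, list(r))
  res <- split_nadp_placeholder(r, d)
  expect_length(res$reactions, 2)
  ids <- vapply(res$reactions, `[[`, character(1), "reaction_id")
  expect_equal(ids, c("BRX1", "BRX1_WOP"))
  expect_true("nadp" %in% res$reactions[[1]]$left$compound_id)
  expect_true("nadph" %in% res$reactions[[1]]$right$compound_id)
  expect_true("nad" %in% res$reactions[[2]]$left$compound_id)
  expect_true("nadh" %in% res$reactions[[2]]$right$compound_id)
  # sides and coefficients preserved
  expect_equal(nrow(res$reactions[[2]]$right), 3)

  # no placeholder: identity
  r2 <- reaction_record("S", "R2",
    left = data.frame(coefficient = "1", compound_id = "alc"),
    right = data.frame(coefficient = "1", compound_id = "ald"))
  expect_length(split_nadp_placeholder(r2, d)$reactions, 1)

  # placeholder without redox partner: warned, passed through unsplit
  r3 <- reaction_record("S", "R3",
    left = data.frame(coefficient = "1", compound_id = "ph_ox"),
    right = data.frame(coefficient = "1", compound_id = "ald"))
  expect_warning(res3 <- split_nadp_placeholder(r3, d), "redox partner")
  expect_length(res3$reactions, 1)
})

test_that("split conservation: one or two outputs per input reaction", {
  fx <- generate_fixture(fixture_spec(seed = 9, nadp_placeholder_collapse = 0.5))
  for (d in fx$dumps) {
    n_ph <- sum(vapply(d$reactions, function(r) {
      nms <- d$compounds$name[match(c(r$left$compound_id,
                                      r$right$compound_id),
                                    d$compounds$compound_id)]
      any(tolower(nms) %in% c("nad(p)+", "nad(p)h"))
    }, logical(1)))
    d2 <- split_placeholders_in_dump(d)
    expect_equal(length(d2$reactions), length(d$reactions) + n_ph)
  }
})

test_that("check_balance classifies the documented cases", {
  formulas <- list(pp = formula_to_counts("H4O7P2"),
                   w = formula_to_counts("H2O"),
                   p = formula_to_counts("H3O4P"),
                   h = formula_to_counts("H"),
                   glcA = formula_to_counts("C6H12O6"),
                   rib = formula_to_counts("C5H10O5"))
  side <- function(...) {
    x <- list(...)
    data.frame(coefficient = vapply(x, `[[`, character(1), 1),
               compound_id = vapply(x, `[[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
  # diphosphate + H2O = 2 phosphate: balanced (hand tally H6P2O8 each side)
  r <- reaction_record("S", "r", side(c("1", "pp"), c("1", "w")),
                       side(c("2", "p")))
  expect_equal(check_balance(r, formulas)$status, "balanced")

  # with an explicit proton product: tolerated, proton missing on the left
  r <- reaction_record("S", "r", side(c("1", "pp"), c("1", "w")),
                       side(c("2", "p"), c("1", "h")))
  b <- check_balance(r, formulas)
  expect_equal(b$status, "balanced_tolerated")
  expect_equal(b$tolerated_species, "proton")
  expect_equal(counts_to_formula(b$deficit_left), "H")

  # a missing water: tolerated as water
  r <- reaction_record("S", "r", side(c("1", "glcA")),
                       side(c("1", "glcA"), c("1", "w")))
  b <- check_balance(r, formulas)
  expect_equal(b$status, "balanced_tolerated")
  expect_equal(b$tolerated_species, "water")

  # C6H12O6 = C5H10O5: incomplete, CH2O missing from the product side
  r <- reaction_record("S", "r", side(c("1", "glcA")), side(c("1", "rib")))
  b <- check_balance(r, formulas)
  expect_equal(b$status, "incomplete")
  expect_equal(counts_to_formula(b$deficit_right), "CH2O")
  expect_equal(counts_to_formula(b$deficit_left), "")

  # lone O deficit is NOT expressible as aH + bH2O: incomplete
  formulas$glcO <- formula_to_counts("C6H12O7")
  r <- reaction_record("S", "r", side(c("1", "glcO")), side(c("1", "glcA")))
  expect_equal(check_balance(r, formulas)$status, "incomplete")

  # mixed-side H/O discrepancies are incomplete (tolerance is one-sided)
  formulas$glcH <- formula_to_counts("C6H14O6")
  r <- reaction_record("S", "r", side(c("1", "glcO")), side(c("1", "glcH")))
  expect_equal(check_balance(r, formulas)$status, "incomplete")

  # missing formula or symbolic coefficient: undetermined
  r <- reaction_record("S", "r", side(c("1", "nostruct")), side(c("1", "glcA")))
  expect_equal(check_balance(r, formulas)$status, "undetermined")
  r <- reaction_record("S", "r", side(c("n", "glcA")), side(c("n", "glcA")))
  expect_equal(check_balance(r, formulas)$status, "undetermined")
})

test_that("balance agrees with a brute-force element tally on random reactions", {
  set.seed(202)
  els <- c("C", "H", "N", "O", "P", "S")
  for (i in 1:40) {
    n_l <- sample(1:3, 1); n_r <- sample(1:3, 1)
    ids <- paste0("c", seq_len(n_l + n_r))
    formulas <- lapply(ids, function(id) {
      cnt <- stats::setNames(sample(0:6, length(els), replace = TRUE), els)
      cnt["C"] <- cnt["C"] + 1L
      structure(list(counts = cnt[cnt > 0], has_unknown = FALSE),
                class = "element_counts")
    })
    names(formulas) <- ids
    coefs <- sample(1:3, n_l + n_r, replace = TRUE)
    r <- reaction_record("S", "r",
      data.frame(coefficient = as.character(coefs[1:n_l]),
                 compound_id = ids[1:n_l]),
      data.frame(coefficient = as.character(coefs[(n_l + 1):(n_l + n_r)]),
                 compound_id = ids[(n_l + 1):(n_l + n_r)]))
    got <- check_balance(r, formulas)
    # oracle: independent element tally
    tally <- stats::setNames(rep(0L, length(els)), els)
    for (k in seq_len(n_l)) {
      tally <- tally + coefs[k] *
        vapply(els, function(e) {
          cc <- formulas[[ids[k]]]$counts
          if (e %in% names(cc)) cc[[e]] else 0L
        }, integer(1))
    }
    for (k in seq_len(n_r)) {
      tally <- tally - coefs[n_l + k] *
        vapply(els, function(e) {
          cc <- formulas[[ids[n_l + k]]]$counts
          if (e %in% names(cc)) cc[[e]] else 0L
        }, integer(1))
    }
    if (all(tally == 0L)) {
      expect_equal(got$status, "balanced")
    } else {
      expect_true(got$status %in% c("balanced_tolerated", "incomplete"))
      # the deficits must reproduce the tally exactly
      dl <- got$deficit_left; dr <- got$deficit_right
      for (e in els) {
        d <- (if (e %in% names(dr)) dr[[e]] else 0L) -
             (if (e %in% names(dl)) dl[[e]] else 0L)
        expect_equal(d, unname(tally[e]))
      }
    }
  }
})

test_that("water/proton stripping removes small species, excludes degenerates", {
  comps <- list(compound_record("S", "pp", "diphosphate"),
                compound_record("S", "p", "phosphate"),
                compound_record("S", "w", "H2O",
                                inchi = "InChI=1S/H2O/h1H2"),
                compound_record("S", "h", "H+"))
  d <- simple_dump("S", comps)
  small <- sub("^S\r", "", small_species_refs(list(d)))
  expect_setequal(small, c("w", "h"))
  r <- reaction_record("S", "r",
    data.frame(coefficient = c("1", "1"), compound_id = c("pp", "w")),
    data.frame(coefficient = c("2", "1"), compound_id = c("p", "h")))
  s <- strip_water_protons(r, small)
  expect_equal(s$left$compound_id, "pp")
  expect_equal(s$right$compound_id, "p")
  # untouched when absent
  r2 <- reaction_record("S", "r2",
    data.frame(coefficient = "1", compound_id = "pp"),
    data.frame(coefficient = "2", compound_id = "p"))
  expect_equal(strip_water_protons(r2, small), r2)
  # degenerate: side empties -> excluded with a warning
  r3 <- reaction_record("S", "r3",
    data.frame(coefficient = "1", compound_id = "w"),
    data.frame(coefficient = c("1", "1"), compound_id = c("h", "p")))
  expect_warning(s3 <- strip_water_protons(r3, small), "empty")
  expect_null(s3)
})

test_that("reaction keys are direction-agnostic and coefficient-sensitive", {
  class_of <- c("S\ra" = 1L, "S\rb" = 2L, "S\rc" = 3L)
  mk <- function(lc, lid, rc, rid) reaction_record("S", "r",
    data.frame(coefficient = lc, compound_id = lid),
    data.frame(coefficient = rc, compound_id = rid))
  k1 <- reaction_key(mk("1", "a", c("2", "1"), c("b", "c")), class_of)
  k2 <- reaction_key(mk(c("2", "1"), c("b", "c"), "1", "a"), class_of)
  expect_equal(k1$key, k2$key)
  expect_equal(reaction_key(swap_sides(mk("1", "a", "2", "b")), class_of)$key,
               reaction_key(mk("1", "a", "2", "b"), class_of)$key)
  # coefficients are part of the key
  expect_false(reaction_key(mk("1", "a", "2", "b"), class_of)$key ==
               reaction_key(mk("1", "a", "3", "b"), class_of)$key)
  # unresolved participants: no key
  expect_null(reaction_key(mk("1", "a", "1", "zzz"),
                           class_of))
})

test_that("water/proton additions never change the key and only move the
           balance between balanced and tolerated", {
  fx <- generate_fixture(fixture_spec(seed = 13, add_water = 0, add_proton = 0,
                                      corrupt_balance = 0, drop_structure = 0,
                                      nadp_placeholder_collapse = 0))
  base <- reconcile(fx$dumps)
  # re-generate with spurious small species everywhere
  fx2 <- generate_fixture(fixture_spec(seed = 13, add_water = 1, add_proton = 1,
                                       corrupt_balance = 0, drop_structure = 0,
                                       nadp_placeholder_collapse = 0))
  res2 <- reconcile(fx2$dumps)
  expect_equal(res2$stats$unique_reaction_count,
               base$stats$unique_reaction_count)
  expect_true(all(res2$balance$status %in%
                    c("balanced", "balanced_tolerated")))
})
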