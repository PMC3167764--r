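test_that("generation is deterministic in the seed", {
  f1 <- generate_fixture(fixture_spec(seed = 21))
  f2 <- generate_fixture(fixture_spec(seed = 21))
  t1 <- tempfile(); t2 <- tempfile()
  write_dump(f1$dumps[[1]], t1)
  write_dump(f2$dumps[[1]], t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_fixture(fixture_spec(seed = 22))
  expect_false(identical(f1$truth$reaction_class, f3$truth$reaction_class))
})

test_that("with all perturbation rates zero the sources are copies", {
  sp <- fixture_spec(seed = 2, synonym_rename = 0, case_hyphen_noise = 0,
                     protonation_variant = 0, stereo_undefined_variant = 0,
                     add_water = 0, add_proton = 0, reverse_direction = 0,
                     within_source_duplicate = 0, glycan_alias = 0,
                     nadp_placeholder_collapse = 0, drop_structure = 0,
                     corrupt_balance = 0)
  fx <- generate_fixture(sp)
  expect_length(fx$dumps, 3)
  # identical content modulo the source label
  c1 <- fx$dumps[[1]]$compounds; c2 <- fx$dumps[[2]]$compounds
  expect_equal(c1[setdiff(names(c1), "source")],
               c2[setdiff(names(c2), "source")])
  # expected classes: one per base entity; every reaction balanced
  res <- reconcile(fx$dumps)
  expect_equal(length(res$classes),
               length(unique(fx$truth$compound_class)))
  expect_true(all(res$balance$status == "balanced"))
})

test_that("corrupt_balance records its own edit as the expected deficit", {
  fx <- generate_fixture(fixture_spec(seed = 4, corrupt_balance = 1,
                                      add_water = 0, add_proton = 0,
                                      drop_structure = 0,
                                      nadp_placeholder_collapse = 0))
  tb <- fx$truth$balance
  inc <- tb[tb$status == "incomplete", ]
  expect_gt(nrow(inc), 0)
  expect_true(all(inc$missing_substrate == "CH2O" |
                  inc$missing_product == "CH2O"))
  res <- reconcile(fx$dumps)
  sc <- score_recovery(res, fx$truth)
  expect_equal(sc$balance_agreement, 1)
})

test_that("score_recovery matches a brute-force pair-enumeration oracle", {
  fx <- generate_fixture(fixture_spec(seed = 7))
  res <- suppressWarnings(reconcile(fx$dumps))
  sc <- score_recovery(res, fx$truth)
  # oracle: enumerate all pairs explicitly
  pred <- res$class_of
  truth <- fx$truth$compound_class[names(pred)]
  n <- length(pred)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- pred[i] == pred[j]
      t <- truth[i] == truth[j]
      if (p && t) tp <- tp + 1
      if (p && !t) fp <- fp + 1
      if (!p && t) fn <- fn + 1
    }
  }
  expect_equal(unname(sc$compound["precision"]), tp / (tp + fp))
  expect_equal(unname(sc$compound["recall"]), tp / (tp + fn))
})

test_that("predicting all singletons yields recall 0 on merge pairs", {
  fx <- generate_fixture(fixture_spec(seed = 8))
  res <- suppressWarnings(reconcile(fx$dumps))
  res$class_of[] <- seq_along(res$class_of)      # degrade to singletons
  res$merged <- lapply(seq_along(res$merged), function(i) {
    m <- res$merged[[i]]
    m$members <- m$members[1]
    m
  })
  # rebuild a members list covering the universe as singletons
  all_refs <- names(fx$truth$reaction_class)
  res$merged <- lapply(seq_along(all_refs), function(i) {
    parts <- strsplit(all_refs[i], "\r", fixed = TRUE)[[1]]
    structure(list(unified_id = paste0("U", i),
                   members = list(list(source = parts[1],
                                       reaction_id = parts[2]))),
              class = "merged_reaction")
  })
  res$stripped_out <- list()
  sc <- score_recovery(res, fx$truth)
  expect_equal(unname(sc$compound["recall"]), 0)
  expect_equal(unname(sc$reaction["recall"]), 0)
  expect_equal(unname(sc$compound["precision"]), 1)  # no predicted pairs
})

test_that("universe mismatches are refused", {
  fx <- generate_fixture(fixture_spec(seed = 6))
  res <- suppressWarnings(reconcile(fx$dumps))
  truth <- fx$truth
  truth$compound_class <- truth$compound_class[-1]
  expect_error(score_recovery(res, truth), "universe mismatch")
})

test_that("name fallback carries recovery when structures are missing", {
  # everything unstructured + renamed: name tier must still recover classes
  sp <- fixture_spec(seed = 15, drop_structure = 1, synonym_rename = 0.8,
                     nadp_placeholder_collapse = 0, glycan_alias = 0)
  fx <- generate_fixture(sp)
  dumps <- lapply(fx$dumps, split_placeholders_in_dump)
  with_names <- match_compounds(dumps, name_matching = TRUE)
  without <- match_compounds(dumps, name_matching = FALSE)
  pred_of <- function(classes) {
    out <- integer(0)
    for (cl in classes) for (m in cl$members) {
      out[paste(m$source, m$compound_id, sep = "\r")] <- cl$class_id
    }
    out
  }
  p1 <- pred_of(with_names); p0 <- pred_of(without)
  truth <- fx$truth$compound_class
  rec <- function(pred) {
    pred <- pred[names(truth)]
    tab <- table(pred, truth)
    ch2 <- function(n) n * (n - 1) / 2
    sum(ch2(tab)) / sum(ch2(colSums(tab)))
  }
  expect_gt(rec(p1), rec(p0))   # disabling name matching strictly hurts
  expect_equal(rec(p1), 1)
})

test_that("full recovery across seeds with every perturbation active", {
  for (s in 1:20) {
    fx <- generate_fixture(fixture_spec(seed = s))
    res <- suppressWarnings(reconcile(fx$dumps))
    sc <- score_recovery(res, fx$truth)
    expect_equal(unname(sc$compound["precision"]), 1, info = paste("seed", s))
    expect_equal(unname(sc$compound["recall"]), 1, info = paste("seed", s))
    expect_equal(unname(sc$reaction["precision"]), 1, info = paste("seed", s))
    expect_equal(unname(sc$reaction["recall"]), 1, info = paste("seed", s))
    expect_equal(sc$balance_agreement, 1, info = paste("seed", s))
  }
})
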