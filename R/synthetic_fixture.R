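#' Specification for a synthetic multi-source fixture
#'
#' The generator emulates the obstacles real reaction databases present to
#' integration: spelling and case variants of one compound name, synonym
#' use, protonation-state differences in the InChIs, undefined
#' stereochemistry in some sources, spurious water/proton participants,
#' reversed writing direction, within-source duplicate reactions, glycan
#' alias IDs, collapsed NAD(P)/H cofactor placeholders, missing structures
#' (generic compounds) and genuinely imbalanced reactions with a known atom
#' deficit. Every perturbation records its ground-truth label, so recovery
#' can be scored exactly.
#'
#' @param n_base_compounds Size of the shared substrate pool.
#' @param n_base_reactions Number of base reactions (each element-balanced
#'   by construction before perturbation).
#' @param n_sources Number of source dumps.
#' @param seed Integer seed; fully determines the output.
#' @param synonym_rename,case_hyphen_noise,protonation_variant,stereo_undefined_variant
#'   Per-copy compound perturbation rates in `[0, 1]`.
#' @param add_water,add_proton,reverse_direction,within_source_duplicate,glycan_alias
#'   Per-copy reaction perturbation rates.
#' @param nadp_placeholder_collapse Per-base-reaction rate of carrying an
#'   NAD(P)/NAD(P)H cofactor pair that the first source writes as a
#'   placeholder (such reactions are exempt from `corrupt_balance`).
#' @param drop_structure Per-pool-compound rate of having no structure in
#'   any source (matchable only by name; balance undetermined).
#' @param corrupt_balance Per-copy rate of replacing one product with a
#'   variant missing one CH2O unit (known `incomplete` deficit).
#' @param name_collision Rate of injecting one shared synonym across two
#'   structurally different compounds (off by default; exercises the
#'   name-match guard).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_base_compounds = 24, n_base_reactions = 12,
                         n_sources = 3, seed = 1,
                         synonym_rename = 0.3, case_hyphen_noise = 0.5,
                         protonation_variant = 0.25,
                         stereo_undefined_variant = 0.5,
                         add_water = 0.2, add_proton = 0.15,
                         reverse_direction = 0.3,
                         within_source_duplicate = 0.1,
                         glycan_alias = 0.1,
                         nadp_placeholder_collapse = 0.15,
                         drop_structure = 0.1, corrupt_balance = 0.1,
                         name_collision = 0) {
  rates <- c(synonym_rename = synonym_rename,
             case_hyphen_noise = case_hyphen_noise,
             protonation_variant = protonation_variant,
             stereo_undefined_variant = stereo_undefined_variant,
             add_water = add_water, add_proton = add_proton,
             reverse_direction = reverse_direction,
             within_source_duplicate = within_source_duplicate,
             glycan_alias = glycan_alias,
             nadp_placeholder_collapse = nadp_placeholder_collapse,
             drop_structure = drop_structure,
             corrupt_balance = corrupt_balance,
             name_collision = name_collision)
  stopifnot(all(rates >= 0 & rates <= 1),
            n_base_compounds >= 4, n_base_reactions >= 1, n_sources >= 1)
  structure(c(list(n_base_compounds = n_base_compounds,
                   n_base_reactions = n_base_reactions,
                   n_sources = n_sources, seed = seed), as.list(rates)),
            class = "fixture_spec")
}

# name syllable pools for pseudo-biochemical compound names
.SYL1 <- c("gluc", "fruct", "mal", "cit", "succ", "lact", "pyr", "oxal",
           "fum", "aden", "guan", "thre", "ser", "xyl", "rib", "arab",
           "galact", "mann", "sorb", "erythr")
.SYL2 <- c("ose", "ate", "itol", "amine", "yl phosphate", "onate",
           "aldehyde", "one", "ol", "ic acid")
.GREEKS <- c("alpha", "beta", "gamma", "delta")

# deterministic unique-name builder; index keeps names collision-free
.mk_name <- function(i) {
  g <- .GREEKS[(i %% length(.GREEKS)) + 1L]
  s1 <- .SYL1[(i %% length(.SYL1)) + 1L]
  s2 <- .SYL2[(i %/% length(.SYL1)) %% length(.SYL2) + 1L]
  sprintf("%s-D-%s%s %d", g, s1, s2, i)
}

# apply case/hyphen/comma noise that is invisible to normalize_name()
.noise_name <- function(name) {
  chars <- strsplit(name, "")[[1]]
  flip <- stats::runif(length(chars)) < 0.3
  chars[flip] <- toupper(chars[flip])
  out <- paste(chars, collapse = "")
  # insert punctuation at an interior position
  if (nchar(out) > 4) {
    pos <- 2L + sample.int(nchar(out) - 3L, 1L)
    sep <- sample(c("-", ", ", " ", "()"), 1L)
    out <- paste0(substr(out, 1, pos), sep, substr(out, pos + 1, nchar(out)))
  }
  out
}

# assemble a syntactically valid standard-InChI surrogate
.mk_inchi <- function(formula, cindex, n_stereo = 0L, protonated = FALSE,
                      drop_stereo = FALSE) {
  cnt <- formula_to_counts(formula)$counts
  h <- if ("H" %in% names(cnt)) cnt[["H"]] else 0L
  stereo <- ""
  if (n_stereo > 0L && !drop_stereo) {
    marks <- paste0(seq_len(n_stereo) + 1L,
                    rep_len(c("-", "+"), n_stereo), collapse = ",")
    stereo <- paste0("/t", marks, "/m0/s1")
  }
  paste0("InChI=1S/", formula,
         "/c1-", cindex + 1L,
         "/h1H", max(h, 1L),
         if (protonated) "/p-1",
         stereo)
}

.counts_to_hill <- function(cnt) {
  counts_to_formula(cnt)
}

#' Generate synthetic source dumps with known ground truth
#'
#' See [fixture_spec()] for what is emulated. The generator first builds a
#' pool of base compounds (unique surrogate structures over small CHNO
#' formulas, unique name + synonym pools), then element-balanced base
#' reactions whose products partition the substrate atoms, then writes one
#' perturbed copy of everything per source. The RNG state is saved and
#' restored; the seed in `spec` fully determines the output.
#'
#' @param spec A `fixture_spec`.
#' @return List with `dumps` (list of `source_dump`) and `truth`, a list
#'   with `compound_class` (named vector `source\rcompound_id -> label`),
#'   `reaction_class` (named vector `source\rreaction_id -> label`,
#'   including `_WOP` and duplicate ids) and `balance` (data.frame:
#'   `source`, `reaction_id`, `status`, `missing_substrate`,
#'   `missing_product`).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  sources <- paste0("SRC", seq_len(spec$n_sources))
  cindex <- 0L           # global connectivity-layer serial: unique keys
  pool <- list()         # base compound descriptors
  nxt_c <- function() { cindex <<- cindex + 1L; cindex }

  mk_compound <- function(id, name, formula, n_stereo = 0L,
                          synonyms = character(0), has_structure = TRUE) {
    list(id = id, name = name, formula = formula, n_stereo = n_stereo,
         cindex = nxt_c(), synonyms = synonyms,
         has_structure = has_structure)
  }

  # --- substrate pool
  combos <- expand.grid(C = 2:7, H = seq(4, 14, 2), N = 0:2, O = 1:5)
  combos <- combos[sample.int(nrow(combos), spec$n_base_compounds), ]
  for (i in seq_len(spec$n_base_compounds)) {
    f <- paste0("C", combos$C[i], "H", combos$H[i],
                if (combos$N[i] > 0) paste0("N", if (combos$N[i] > 1) combos$N[i]),
                "O", combos$O[i])
    nm <- .mk_name(i)
    syn <- c(paste0("syn-", gsub(" ", "-", tolower(nm))),
             paste0(toupper(substr(nm, 1, 3)), i, "x"))
    n_st <- if (stats::runif(1) < 0.6) sample.int(3L, 1L) else 0L
    pool[[i]] <- mk_compound(sprintf("C%04d", i), nm, f, n_st, syn,
                             has_structure = stats::runif(1) >= spec$drop_structure)
  }
  # optional forced synonym collision between two structured compounds
  if (spec$name_collision > 0 && stats::runif(1) < spec$name_collision &&
      spec$n_base_compounds >= 2) {
    pool[[1]]$synonyms <- c(pool[[1]]$synonyms, "shared trivial name")
    pool[[2]]$synonyms <- c(pool[[2]]$synonyms, "shared trivial name")
  }

  # --- fixed special compounds
  water <- mk_compound("CWAT", "H2O", "H2O", synonyms = c("water"))
  proton <- list(id = "CPRO", name = "H+", formula = "H", n_stereo = 0L,
                 cindex = NA, synonyms = c("proton"), has_structure = FALSE)
  cofactors <- list(
    nadp_ox = mk_compound("CNDP", "NADP+", "C21H28N7O17P3"),
    nadp_red = mk_compound("CNPH", "NADPH", "C21H29N7O17P3"),
    nad_ox = mk_compound("CNAD", "NAD+", "C21H27N7O14P2"),
    nad_red = mk_compound("CNDH", "NADH", "C21H28N7O14P2"))
  ph_ox <- list(id = "CPHO", name = "NAD(P)+", formula = NA, n_stereo = 0L,
                cindex = NA, synonyms = character(0), has_structure = FALSE)
  ph_red <- list(id = "CPHR", name = "NAD(P)H", formula = NA, n_stereo = 0L,
                 cindex = NA, synonyms = character(0), has_structure = FALSE)

  extra <- list()        # per-reaction product compounds
  add_extra <- function(cmp) extra[[length(extra) + 1L]] <<- cmp

  # --- base reactions: products partition the substrate atom totals
  reactions <- list()
  for (j in seq_len(spec$n_base_reactions)) {
    repeat {
      subs <- sample.int(spec$n_base_compounds, sample(1:2, 1))
      coefs <- sample(1:2, length(subs), replace = TRUE)
      total <- integer(0)
      for (k in seq_along(subs)) {
        cnt <- formula_to_counts(pool[[subs[k]]]$formula)$counts
        for (el in names(cnt)) {
          total[el] <- (if (el %in% names(total)) total[[el]] else 0L) +
            coefs[k] * cnt[[el]]
        }
      }
      placeholder <- stats::runif(1) < spec$nadp_placeholder_collapse
      if (placeholder) {
        if (total[["H"]] < 3L) next   # reserve one H for the cofactor
        total[["H"]] <- total[["H"]] - 1L
      }
      n_prod <- min(sample(1:2, 1), total[["C"]])
      # partition every element over the products; each product gets >=1 C
      prods <- vector("list", n_prod)
      alloc <- stats::setNames(
        lapply(names(total), function(el) {
          v <- integer(n_prod)
          if (el == "C") v <- v + 1L
          rem <- total[[el]] - sum(v)
          if (rem > 0L) {
            pick <- sample.int(n_prod, rem, replace = TRUE)
            for (p in pick) v[p] <- v[p] + 1L
          }
          v
        }), names(total))
      ok <- TRUE
      for (p in seq_len(n_prod)) {
        cnt <- vapply(alloc, `[`, integer(1), p)
        cnt <- cnt[cnt > 0L]
        if (!("C" %in% names(cnt))) { ok <- FALSE; break }
        prods[[p]] <- cnt
      }
      if (!ok) next
      prod_cmps <- lapply(seq_len(n_prod), function(p) {
        id <- sprintf("P%04d%s", j, letters[p])
        mk_compound(id, paste0("product ", j, letters[p], " ",
                               .mk_name(1000L + 10L * j + p)),
                    .counts_to_hill(prods[[p]]),
                    n_stereo = sample(0:2, 1))
      })
      for (pc in prod_cmps) add_extra(pc)
      reactions[[j]] <- list(
        j = j, subs = subs, coefs = coefs,
        prods = vapply(prod_cmps, `[[`, character(1), "id"),
        prod_counts = prods,
        placeholder = placeholder,
        ec = sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                     sample(1:9, 1), sample(1:99, 1)))
      break
    }
  }

  any_placeholder <- any(vapply(reactions, `[[`, logical(1), "placeholder"))
  specials <- c(list(water, proton),
                if (any_placeholder) cofactors)

  # --- per-source rendering
  by_id <- list()
  for (cmp in c(pool, extra, specials)) by_id[[cmp$id]] <- cmp

  truth_compound <- character(0)
  truth_reaction <- character(0)
  balance_rows <- list()
  dumps <- vector("list", spec$n_sources)

  for (si in seq_along(sources)) {
    src <- sources[si]
    comp_rows <- list()
    aliases <- character(0)
    alias_of <- character(0)   # compound id -> alias id used in this source

    render_compound <- function(cmp) {
      name <- cmp$name
      if (stats::runif(1) < spec$synonym_rename && length(cmp$synonyms)) {
        name <- sample(cmp$synonyms, 1L)
      }
      if (stats::runif(1) < spec$case_hyphen_noise) name <- .noise_name(name)
      inchi <- NA_character_
      if (isTRUE(cmp$has_structure) && !is.na(cmp$cindex)) {
        prot <- stats::runif(1) < spec$protonation_variant
        dropst <- cmp$n_stereo > 0L &&
          stats::runif(1) < spec$stereo_undefined_variant
        inchi <- .mk_inchi(cmp$formula, cmp$cindex, cmp$n_stereo, prot, dropst)
      }
      compound_record(src, cmp$id, name,
                      synonyms = c(cmp$name, cmp$synonyms), inchi = inchi)
    }
    for (cmp in c(pool, extra, specials)) {
      comp_rows[[length(comp_rows) + 1L]] <- render_compound(cmp)
    }
    if (si == 1L && any_placeholder) {
      # placeholder records are consumed by the split and absorbed, so they
      # carry no ground-truth label of their own
      comp_rows[[length(comp_rows) + 1L]] <-
        compound_record(src, ph_ox$id, ph_ox$name)
      comp_rows[[length(comp_rows) + 1L]] <-
        compound_record(src, ph_red$id, ph_red$name)
    }
    for (cmp in c(pool, extra, specials)) {
      truth_compound[paste(src, cmp$id, sep = "\r")] <- cmp$id
    }

    rxn_list <- list()
    emit <- function(rid, left, right, ec, truth_label, expected) {
      rxn_list[[length(rxn_list) + 1L]] <<-
        reaction_record(src, rid, left, right, ec_numbers = ec,
                        direction = sample(c("reversible", "left_to_right",
                                             "unspecified"), 1L),
                        pathways = sprintf("SYN:pathway-%s", truth_label))
      truth_reaction[paste(src, rid, sep = "\r")] <<- truth_label
      balance_rows[[length(balance_rows) + 1L]] <<- data.frame(
        source = src, reaction_id = rid, status = expected$status,
        missing_substrate = expected$ms, missing_product = expected$mp,
        stringsAsFactors = FALSE)
    }

    for (rx in reactions) {
      rid <- sprintf("R%04d", rx$j)
      left <- data.frame(coefficient = as.character(rx$coefs),
                         compound_id = vapply(rx$subs, function(i)
                           pool[[i]]$id, character(1)),
                         stringsAsFactors = FALSE)
      right <- data.frame(coefficient = rep("1", length(rx$prods)),
                          compound_id = rx$prods, stringsAsFactors = FALSE)

      # glycan alias: reference one substrate through an alias id
      if (stats::runif(1) < spec$glycan_alias) {
        tgt <- left$compound_id[1]
        if (!(tgt %in% names(alias_of))) {
          gid <- paste0("G", substring(tgt, 2))
          alias_of[tgt] <- gid
          aliases[gid] <- tgt
          comp_rows[[length(comp_rows) + 1L]] <-
            compound_record(src, gid, by_id[[tgt]]$name)
        }
        left$compound_id[1] <- alias_of[tgt]
      }

      corrupt <- !rx$placeholder && stats::runif(1) < spec$corrupt_balance
      truth_label <- sprintf("RX%04d", rx$j)
      deficit_on_right <- FALSE
      if (corrupt) {
        # replace an eligible product with a variant missing one CH2O
        eligible <- which(vapply(rx$prod_counts, function(cnt) {
          get0 <- function(el) if (el %in% names(cnt)) cnt[[el]] else 0L
          get0("C") >= 2L && get0("H") >= 3L && get0("O") >= 2L
        }, logical(1)))
        if (length(eligible)) {
          p <- eligible[1]
          cnt <- rx$prod_counts[[p]]
          cnt[["C"]] <- cnt[["C"]] - 1L
          cnt[["H"]] <- cnt[["H"]] - 2L
          cnt[["O"]] <- cnt[["O"]] - 1L
          cid <- sprintf("X%04d%s", rx$j, src)
          cmp <- mk_compound(cid, paste0("defect ", cid), .counts_to_hill(cnt))
          comp_rows[[length(comp_rows) + 1L]] <- local({
            compound_record(src, cmp$id, cmp$name,
                            inchi = .mk_inchi(cmp$formula, cmp$cindex))
          })
          truth_compound[paste(src, cid, sep = "\r")] <- paste0(cid, "@", src)
          right$compound_id[p] <- cid
          truth_label <- paste0(truth_label, "corr", src)
          deficit_on_right <- TRUE
        } else {
          corrupt <- FALSE
        }
      }

      placeholder_here <- rx$placeholder
      if (placeholder_here) {
        if (si == 1L) {
          left <- rbind(left, data.frame(coefficient = "1",
                                         compound_id = ph_ox$id))
          right <- rbind(right, data.frame(coefficient = "1",
                                           compound_id = ph_red$id))
        } else {
          left <- rbind(left, data.frame(coefficient = "1",
                                         compound_id = cofactors$nadp_ox$id))
          right <- rbind(right, data.frame(coefficient = "1",
                                           compound_id = cofactors$nadp_red$id))
        }
      }

      reversed <- stats::runif(1) < spec$reverse_direction
      if (reversed) {
        tmp <- left; left <- right; right <- tmp
        deficit_on_right <- corrupt && !deficit_on_right
      }

      # spurious small species on one side; never combined with a corrupted
      # copy so each copy carries exactly one known balance edit
      small_side <- sample(c("left", "right"), 1L)
      added_water <- !corrupt && stats::runif(1) < spec$add_water
      added_proton <- !corrupt && stats::runif(1) < spec$add_proton
      extra_small <- c(if (added_water) water$id,
                       if (added_proton) proton$id)
      if (length(extra_small)) {
        addition <- data.frame(coefficient = rep("1", length(extra_small)),
                               compound_id = extra_small,
                               stringsAsFactors = FALSE)
        if (small_side == "left") left <- rbind(left, addition)
        else right <- rbind(right, addition)
      }

      # expected balance label; placeholder participants do not count as
      # structure-less because the split rewrites them to real cofactors
      # before the balance check runs
      undet <- undet_nonplaceholder(left, right, aliases, by_id, water,
                                    proton, ph_ox, ph_red)
      expected <- if (undet) {
        list(status = "undetermined", ms = "", mp = "")
      } else if (corrupt) {
        list(status = "incomplete",
             ms = if (deficit_on_right) "" else "CH2O",
             mp = if (deficit_on_right) "CH2O" else "")
      } else if (added_water || added_proton) {
        d <- counts_to_formula(c(H = 2L * added_water + 1L * added_proton,
                                 O = 1L * added_water))
        list(status = "balanced_tolerated",
             ms = if (small_side == "left") "" else d,
             mp = if (small_side == "left") d else "")
      } else {
        list(status = "balanced", ms = "", mp = "")
      }

      if (si == 1L && placeholder_here) {
        rids <- c(rid, paste0(rid, "_WOP"))
        labels <- c(paste0(truth_label, "_P"), paste0(truth_label, "_N"))
        rxn_list[[length(rxn_list) + 1L]] <-
          reaction_record(src, rid, left, right, ec_numbers = rx$ec,
                          direction = "reversible",
                          pathways = sprintf("SYN:pathway-%s", truth_label))
        for (k in 1:2) {
          truth_reaction[paste(src, rids[k], sep = "\r")] <- labels[k]
          balance_rows[[length(balance_rows) + 1L]] <- data.frame(
            source = src, reaction_id = rids[k], status = expected$status,
            missing_substrate = expected$ms, missing_product = expected$mp,
            stringsAsFactors = FALSE)
        }
      } else if (placeholder_here) {
        # explicit phosphate form, plus the explicit NAD form
        emit(rid, left, right, rx$ec, paste0(truth_label, "_P"), expected)
        swapN <- function(side) {
          side$compound_id[side$compound_id == cofactors$nadp_ox$id] <-
            cofactors$nad_ox$id
          side$compound_id[side$compound_id == cofactors$nadp_red$id] <-
            cofactors$nad_red$id
          side
        }
        emit(paste0(rid, "N"), swapN(left), swapN(right), rx$ec,
             paste0(truth_label, "_N"), expected)
      } else {
        emit(rid, left, right, rx$ec, truth_label, expected)
        if (stats::runif(1) < spec$within_source_duplicate) {
          # duplicate written with swapped sides: deficit columns swap too
          expected_sw <- list(status = expected$status,
                              ms = expected$mp, mp = expected$ms)
          emit(paste0(rid, "D"), right, left, rx$ec, truth_label, expected_sw)
        }
      }
    }

    comps <- do.call(rbind, comp_rows)
    dumps[[si]] <- source_dump(src, comps, rxn_list, aliases)
  }

  list(dumps = dumps,
       truth = list(compound_class = truth_compound,
                    reaction_class = truth_reaction,
                    balance = do.call(rbind, balance_rows)))
}

# helper used when labelling placeholder copies: structure-less pool
# participants still force an undetermined label
undet_nonplaceholder <- function(left, right, aliases, by_id, water, proton,
                                 ph_ox, ph_red) {
  any(vapply(c(left$compound_id, right$compound_id), function(id) {
    if (id %in% c(ph_ox$id, ph_red$id, water$id, proton$id)) return(FALSE)
    id <- if (id %in% names(aliases)) aliases[[id]] else id
    cmp <- by_id[[id]]
    !is.null(cmp) && !isTRUE(cmp$has_structure)
  }, logical(1)))
}

# ---------------------------------------------------------------------------

# pairwise co-membership precision/recall from two label vectors
.pairwise_prf <- function(pred, truth) {
  stopifnot(setequal(names(pred), names(truth)))
  truth <- truth[names(pred)]
  tab <- table(pred, truth)
  ch2 <- function(n) n * (n - 1) / 2
  tp <- sum(ch2(tab))
  pp <- sum(ch2(rowSums(tab)))
  tpairs <- sum(ch2(colSums(tab)))
  precision <- if (pp == 0) 1 else tp / pp
  recall <- if (tpairs == 0) 1 else tp / tpairs
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Score recovery of the known fixture structure
#'
#' Compares the pipeline's compound classes and merged reactions against
#' the generator's ground truth: pairwise co-membership precision, recall
#' and F1 for both entity kinds, plus a balance-status confusion matrix and
#' the agreement rate of the full QC row (status and Missing
#' Substrate/Product formulas).
#'
#' @param result Output of [reconcile()] on the generated dumps.
#' @param truth The `truth` element of [generate_fixture()]'s output.
#' @return List with `compound` and `reaction` (named numeric vectors:
#'   precision/recall/f1), `balance_confusion` (table expected x computed),
#'   `balance_agreement` (fraction of reactions whose status and deficit
#'   formulas all match).
#' @export
score_recovery <- function(result, truth) {
  pred_comp <- result$class_of
  if (!setequal(names(pred_comp), names(truth$compound_class))) {
    extra <- setdiff(names(pred_comp), names(truth$compound_class))
    miss <- setdiff(names(truth$compound_class), names(pred_comp))
    stop("compound universe mismatch: ",
         length(extra), " unexpected, ", length(miss), " missing")
  }
  comp <- .pairwise_prf(pred_comp, truth$compound_class)

  pred_rxn <- character(0)
  for (m in result$merged) {
    for (mem in m$members) {
      pred_rxn[paste(mem$source, mem$reaction_id, sep = "\r")] <- m$unified_id
    }
  }
  # reactions excluded (degenerate after stripping) are absent from merged;
  # treat as their own singleton predictions if the truth knows them
  for (s in result$stripped_out) {
    ref <- paste(s$source, s$reaction_id, sep = "\r")
    pred_rxn[ref] <- paste0("excluded:", ref)
  }
  if (!setequal(names(pred_rxn), names(truth$reaction_class))) {
    extra <- setdiff(names(pred_rxn), names(truth$reaction_class))
    miss <- setdiff(names(truth$reaction_class), names(pred_rxn))
    stop("reaction universe mismatch: ",
         length(extra), " unexpected, ", length(miss), " missing")
  }
  rxn <- .pairwise_prf(pred_rxn, truth$reaction_class)

  bal <- merge(truth$balance, result$balance,
               by = c("source", "reaction_id"),
               suffixes = c("_expected", "_computed"))
  confusion <- table(expected = bal$status_expected,
                     computed = bal$status_computed)
  agree <- mean(bal$status_expected == bal$status_computed &
                  bal$missing_substrate_expected == bal$missing_substrate_computed &
                  bal$missing_product_expected == bal$missing_product_computed)
  list(compound = comp, reaction = rxn,
       balance_confusion = confusion,
       balance_agreement = agree,
       n_balance = nrow(bal))
}
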