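# Equation arrow dialects accepted across source databases.
.ARROWS <- c("<=>", "=>", "->", "→", "=")

#' Parse a reaction equation string
#'
#' Splits an equation on its (single) arrow token (`<=>`, `=>`, `->`,
#' `→`, `=`), then each side on `" + "` (the spaces keep compound
#' names like `"NAD+"` and `"H+"` intact). A leading integer on a
#' participant is its coefficient (default 1); a leading `"n"` stays
#' symbolic.
#'
#' @param text Equation string, e.g.
#'   `"Diphosphate + H2O <=> 2 Orthophosphate"`.
#' @return List with `left`, `right` (data.frames with `coefficient`,
#'   `name`) and `direction` (`"reversible"`, `"left_to_right"`,
#'   `"unspecified"`).
#' @export
parse_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  hit <- NULL
  for (a in .ARROWS) {
    pat <- paste0(" ", a, " ")
    cnt <- lengths(gregexpr(pat, text, fixed = TRUE))
    cnt[gregexpr(pat, text, fixed = TRUE)[[1]][1] == -1L] <- 0L
    if (cnt > 1L) stop("equation has more than one arrow: ", text)
    if (cnt == 1L) { hit <- a; break }
  }
  if (is.null(hit)) stop("equation has no arrow token: ", text)
  sides <- strsplit(text, paste0(" ", hit, " "), fixed = TRUE)[[1]]
  if (length(sides) != 2L || !nzchar(trimws(sides[1])) ||
      !nzchar(trimws(sides[2]))) {
    stop("equation must have participants on both sides: ", text)
  }
  parse_side <- function(s) {
    toks <- strsplit(s, " + ", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    coef <- rep("1", length(toks))
    name <- toks
    m <- regmatches(toks, regexec("^([0-9]+|n) (.+)$", toks))
    for (i in seq_along(toks)) {
      if (length(m[[i]]) == 3) {
        coef[i] <- m[[i]][2]
        name[i] <- m[[i]][3]
      }
    }
    data.frame(coefficient = coef, name = name, stringsAsFactors = FALSE)
  }
  list(left = parse_side(sides[1]), right = parse_side(sides[2]),
       direction = .arrow_to_direction(hit))
}

# ---------------------------------------------------------------------------
# NAD(P)/H placeholder splitting

# placeholder token -> redox state; matched case-insensitively against the
# participant compound's preferred name and synonyms
.default_placeholders <- function() {
  c("NAD(P)+" = "oxidized", "NAD(P)H" = "reduced",
    "NAD(P)" = "oxidized",
    "NADP-OR-NOP" = "oxidized", "NAD-P-OR-NOP" = "oxidized",
    "NADPH_OR_NO_P" = "reduced", "NADPH-OR-NOPH" = "reduced")
}

#' Split a NAD(P)/H placeholder reaction into explicit forms
#'
#' Source databases write some redox reactions with the ambiguous cofactor
#' placeholder NAD(P)+/NAD(P)H (or NADP/H_OR_NO_P). Such a reaction is
#' split into two: the phosphate form (NADP+/NADPH substituted, keeping the
#' original reaction ID) and the non-phosphate form (NAD+/NADH substituted,
#' ID suffixed `_WOP`, "WithOut Phosphate"). Reactions without a
#' placeholder pass through unchanged. A placeholder without its redox
#' partner anywhere in the reaction is flagged malformed and passed through
#' with a warning.
#'
#' @param r A `reaction_record`.
#' @param dump The `source_dump` the reaction belongs to (placeholder
#'   detection consults compound names; substitution targets NADP+/NADPH/
#'   NAD+/NADH are resolved by normalized name, and created as
#'   structure-less compound records when the dump lacks them).
#' @param placeholders Named character vector `token -> redox state`.
#' @return List with `reactions` (list of 1 or 2 `reaction_record`) and
#'   `dump` (possibly extended with substitution-target compounds).
#' @export
split_nadp_placeholder <- function(r, dump,
                                   placeholders = .default_placeholders()) {
  comps <- dump$compounds
  ph_norm <- stats::setNames(unname(placeholders), tolower(names(placeholders)))
  # compound_id -> redox state, for compounds whose name is a placeholder
  state_of <- function(cid) {
    i <- which(comps$compound_id == cid)
    if (!length(i)) return(NA_character_)
    nms <- tolower(c(comps$name[i], comps$synonyms[[i]]))
    hit <- nms[nms %in% names(ph_norm)]
    if (!length(hit)) NA_character_ else ph_norm[[hit[1]]]
  }
  all_ids <- c(r$left$compound_id, r$right$compound_id)
  states <- vapply(all_ids, state_of, character(1))
  if (all(is.na(states))) {
    return(list(reactions = list(r), dump = dump))
  }
  if (!all(c("oxidized", "reduced") %in% states)) {
    warning("reaction ", r$source, ":", r$reaction_id,
            ": NAD(P) placeholder without redox partner; kept unsplit",
            call. = FALSE)
    return(list(reactions = list(r), dump = dump))
  }
  # resolve or create the four explicit cofactor compounds; placeholder
  # records themselves are never substitution targets ("NAD(P)+" and
  # "NADP+" normalize identically)
  is_ph_row <- vapply(seq_len(nrow(comps)), function(i)
    any(tolower(c(comps$name[i], comps$synonyms[[i]])) %in% names(ph_norm)),
    logical(1))
  find_or_create <- function(nm) {
    key <- normalize_name(nm)
    i <- which(normalize_name(comps$name) == key & !is_ph_row)
    if (!length(i)) {
      i <- which(vapply(comps$synonyms, function(s)
        key %in% normalize_name(s), logical(1)) & !is_ph_row)
    }
    if (length(i)) return(list(id = comps$compound_id[i[1]], comps = comps))
    newid <- paste0("AUTO_", gsub("[^A-Za-z0-9]", "", nm))
    comps <<- rbind(comps, compound_record(dump$label, newid, nm))
    list(id = newid, comps = comps)
  }
  targets <- list(
    phosphate = c(oxidized = find_or_create("NADP+")$id,
                  reduced = find_or_create("NADPH")$id),
    wop = c(oxidized = find_or_create("NAD+")$id,
            reduced = find_or_create("NADH")$id))
  substitute_side <- function(side, which_form) {
    st <- vapply(side$compound_id, state_of, character(1))
    hit <- !is.na(st)
    side$compound_id[hit] <- unname(targets[[which_form]][st[hit]])
    side
  }
  mk <- function(which_form, rid) {
    reaction_record(source = r$source, reaction_id = rid,
                    left = substitute_side(r$left, which_form),
                    right = substitute_side(r$right, which_form),
                    ec_numbers = r$ec_numbers, direction = r$direction,
                    pathways = r$pathways)
  }
  out_dump <- source_dump(dump$label, comps, dump$reactions, dump$aliases)
  list(reactions = list(mk("phosphate", r$reaction_id),
                        mk("wop", paste0(r$reaction_id, "_WOP"))),
       dump = out_dump)
}

#' Apply the placeholder split to every reaction of a dump
#' @param dump A `source_dump`.
#' @param placeholders See [split_nadp_placeholder()].
#' @return The `source_dump` with placeholder reactions split.
#' @export
split_placeholders_in_dump <- function(dump,
                                       placeholders = .default_placeholders()) {
  out <- list()
  for (r in dump$reactions) {
    res <- split_nadp_placeholder(r, dump, placeholders)
    dump <- res$dump
    out <- c(out, res$reactions)
  }
  # absorb placeholder compound records that no reaction references anymore
  comps <- dump$compounds
  tokens <- tolower(names(placeholders))
  is_ph <- vapply(seq_len(nrow(comps)), function(i)
    any(tolower(c(comps$name[i], comps$synonyms[[i]])) %in% tokens),
    logical(1))
  still_used <- unique(unlist(lapply(out, function(r)
    c(r$left$compound_id, r$right$compound_id))))
  drop <- is_ph & !(comps$compound_id %in% still_used)
  source_dump(dump$label, comps[!drop, , drop = FALSE], out, dump$aliases)
}

# ---------------------------------------------------------------------------
# Stoichiometric balance

#' Check the element balance of a reaction
#'
#' Sums element counts (from the neutral-parent InChI formula layers) over
#' each side, weighted by coefficients, and compares. Statuses:
#' \describe{
#'   \item{balanced}{element totals equal;}
#'   \item{balanced_tolerated}{totals differ only by whole protons and/or
#'     waters missing from exactly one side (`a`·H + `b`·H2O, `a,b >= 0`)
#'     — such reactions are not flagged incomplete;}
#'   \item{incomplete}{any other deficit; the atoms missing from the
#'     substrate side populate `deficit_left` (the "Missing Substrate"
#'     column), those missing from the product side `deficit_right`
#'     ("Missing Product");}
#'   \item{undetermined}{some participant has no formula (generic or
#'     structure-less compound) or a symbolic coefficient.}
#' }
#' The check is intended to run \emph{before} water/proton stripping, so
#' tolerated discrepancies remain visible.
#'
#' @param r A `reaction_record`.
#' @param formulas Named list/vector: `compound_id -> element_counts` (or
#'   formula string), as produced by [formula_map()].
#' @return An object of class `balance_report`: list with `status`,
#'   `deficit_left`, `deficit_right` (named integer vectors),
#'   `tolerated_species` (subset of `c("proton", "water")`).
#' @export
check_balance <- function(r, formulas) {
  report <- function(status, dl = integer(0), dr = integer(0),
                     tol = character(0)) {
    structure(list(status = status, deficit_left = dl, deficit_right = dr,
                   tolerated_species = tol), class = "balance_report")
  }
  side_total <- function(side) {
    total <- integer(0)
    for (i in seq_len(nrow(side))) {
      coef <- suppressWarnings(as.integer(side$coefficient[i]))
      if (is.na(coef)) return(NULL)          # symbolic coefficient
      f <- formulas[[side$compound_id[i]]]
      if (is.null(f)) return(NULL)
      if (is.character(f)) f <- formula_to_counts(f)
      if (f$has_unknown) return(NULL)
      cnt <- f$counts
      for (el in names(cnt)) {
        total[el] <- (if (el %in% names(total)) total[[el]] else 0L) +
          coef * cnt[[el]]
      }
    }
    total
  }
  lt <- side_total(r$left)
  rt <- side_total(r$right)
  if (is.null(lt) || is.null(rt)) return(report("undetermined"))
  els <- union(names(lt), names(rt))
  lv <- stats::setNames(rep(0L, length(els)), els)
  rv <- lv
  lv[names(lt)] <- lt
  rv[names(rt)] <- rt
  diff <- lv - rv
  if (all(diff == 0L)) return(report("balanced"))
  deficit_left <- pmax(-diff, 0L)    # atoms the substrate side is missing
  deficit_right <- pmax(diff, 0L)    # atoms the product side is missing
  deficit_left <- deficit_left[deficit_left > 0L]
  deficit_right <- deficit_right[deficit_right > 0L]
  one_sided <- xor(length(deficit_left) > 0L, length(deficit_right) > 0L)
  if (one_sided) {
    d <- if (length(deficit_left)) deficit_left else deficit_right
    if (all(names(d) %in% c("H", "O"))) {
      h <- if ("H" %in% names(d)) d[["H"]] else 0L
      o <- if ("O" %in% names(d)) d[["O"]] else 0L
      a <- h - 2L * o                # protons after accounting for waters
      if (a >= 0L) {
        tol <- c(if (a > 0L) "proton", if (o > 0L) "water")
        return(report("balanced_tolerated", deficit_left, deficit_right, tol))
      }
    }
  }
  report("incomplete", deficit_left, deficit_right)
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance: %s%s%s%s>\n", x$status,
              if (length(x$tolerated_species))
                paste0(" (", paste(x$tolerated_species, collapse = "+"), ")")
              else "",
              if (length(x$deficit_left))
                paste0(" missing substrate ", counts_to_formula(x$deficit_left))
              else "",
              if (length(x$deficit_right))
                paste0(" missing product ", counts_to_formula(x$deficit_right))
              else ""))
  invisible(x)
}

#' Formula lookup for one source dump
#'
#' Maps every compound of a dump to the element counts of its neutral-parent
#' InChI formula layer (the formula standard InChI prints before any `/p`
#' layer), so protonation differences surface as H-count differences and are
#' absorbed by the proton-tolerance rule.
#'
#' @param dump A `source_dump`.
#' @return Named list `compound_id -> element_counts`; compounds without a
#'   usable structure are absent.
#' @export
formula_map <- function(dump) {
  out <- list()
  comps <- dump$compounds
  mk <- function(f) formula_to_counts(f)
  for (i in seq_len(nrow(comps))) {
    if (!is.na(comps$inchi[i])) {
      layers <- parse_inchi(comps$inchi[i])
      if (nzchar(layers$formula)) {
        cnt <- formula_to_counts(layers$formula)
        if (!cnt$has_unknown) {
          out[[comps$compound_id[i]]] <- cnt
          next
        }
      } else {
        # bare proton InChI: counts as one hydrogen
        out[[comps$compound_id[i]]] <- mk("H")
        next
      }
    }
    # water/proton recognized by name so structure-less dumps still balance
    nms <- normalize_name(c(comps$name[i], comps$synonyms[[i]]))
    if (any(nms %in% c("h+", "proton", "hydron"))) {
      out[[comps$compound_id[i]]] <- mk("H")
    } else if (any(nms %in% c("h2o", "water"))) {
      out[[comps$compound_id[i]]] <- mk("H2O")
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Water/proton stripping

# names recognized as water / proton when no structure is available
.SMALL_SPECIES_NAMES <- c("h2o", "water", "h+", "proton", "hydron")
.WATER_KEY <- "H2O/h1H2"

#' Identify the water and proton compound classes
#'
#' A class is a small species when any member's reduced key equals the
#' water key, the member's InChI is the bare proton (`InChI=1S/p+1`), or a
#' normalized member name is one of `h2o`, `water`, `h+`, `proton`,
#' `hydron` — the name fallback keeps stripping functional for dumps
#' without structures.
#'
#' @param dumps List of `source_dump` objects.
#' @return Character vector of `source\rcompound_id` references.
#' @export
small_species_refs <- function(dumps) {
  refs <- character(0)
  for (d in dumps) {
    comps <- d$compounds
    for (i in seq_len(nrow(comps))) {
      is_small <- FALSE
      if (!is.na(comps$inchi[i])) {
        layers <- parse_inchi(comps$inchi[i])
        k <- reduce_inchi(layers)
        # water by key; bare proton by its empty formula layer ("InChI=1S/p+1")
        is_small <- identical(k, .WATER_KEY) || !nzchar(layers$formula)
      }
      if (!is_small) {
        nms <- normalize_name(c(comps$name[i], comps$synonyms[[i]]))
        is_small <- any(nms %in% .SMALL_SPECIES_NAMES)
      }
      if (is_small) {
        refs <- c(refs, paste(comps$source[i], comps$compound_id[i],
                              sep = "\r"))
      }
    }
  }
  refs
}

#' Remove water and proton participants from a reaction
#'
#' Water and protons are removed from both sides before reaction matching:
#' sources disagree on writing them out, and removing them significantly
#' improves the matching of otherwise identical reactions. A reaction whose
#' side becomes empty degenerates and is excluded from matching (`NULL`
#' returned, with a warning).
#'
#' @param r A `reaction_record`.
#' @param small_ids Compound ids (within `r`'s source) recognized as water
#'   or proton.
#' @return The stripped `reaction_record`, or `NULL` when a side emptied.
#' @export
strip_water_protons <- function(r, small_ids) {
  l <- r$left[!(r$left$compound_id %in% small_ids), , drop = FALSE]
  rr <- r$right[!(r$right$compound_id %in% small_ids), , drop = FALSE]
  if (nrow(l) == 0L || nrow(rr) == 0L) {
    warning("reaction ", r$source, ":", r$reaction_id,
            ": side empty after water/proton removal; excluded from matching",
            call. = FALSE)
    return(NULL)
  }
  r$left <- l
  r$right <- rr
  r
}

# ---------------------------------------------------------------------------
# Reaction keys

#' Compute the direction-agnostic reaction key
#'
#' Each side becomes a sorted multiset of `(compound class id, coefficient)`
#' pairs; the side whose rendering sorts lexicographically smaller is placed
#' first, so a reaction and its side-swapped writing collide. Coefficients
#' participate in the key (`A = 2 B` and `A = 3 B` differ); the symbolic
#' coefficient `n` matches only itself.
#'
#' @param r A `reaction_record` (after stripping/splitting).
#' @param class_of Named integer vector: `source\rcompound_id -> class_id`.
#' @return List with `key` (string), `side_a`, `side_b` (data.frames of
#'   `class_id`, `coefficient`), or `NULL` when a participant has no class.
#' @export
reaction_key <- function(r, class_of) {
  canon_side <- function(side) {
    refs <- paste(r$source, side$compound_id, sep = "\r")
    cls <- class_of[refs]
    if (anyNA(cls)) return(NULL)
    # aggregate duplicated classes within a side
    agg <- list()
    for (i in seq_along(cls)) {
      k <- as.character(cls[i])
      co <- side$coefficient[i]
      if (is.null(agg[[k]])) {
        agg[[k]] <- co
      } else {
        n1 <- suppressWarnings(as.integer(agg[[k]]))
        n2 <- suppressWarnings(as.integer(co))
        agg[[k]] <- if (is.na(n1) || is.na(n2)) paste0(agg[[k]], "+", co)
                    else as.character(n1 + n2)
      }
    }
    df <- data.frame(class_id = as.integer(names(agg)),
                     coefficient = unlist(agg), stringsAsFactors = FALSE)
    df <- df[order(df$class_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  a <- canon_side(r$left)
  b <- canon_side(r$right)
  if (is.null(a) || is.null(b)) return(NULL)
  render <- function(df) paste(paste0(df$class_id, "x", df$coefficient),
                               collapse = ",")
  ra <- render(a); rb <- render(b)
  if (rb < ra) { tmp <- a; a <- b; b <- tmp; tmp <- ra; ra <- rb; rb <- tmp }
  list(key = paste(ra, rb, sep = " || "), side_a = a, side_b = b)
}

#' Swap the two sides of a reaction
#' @param r A `reaction_record`.
#' @return The side-swapped record (direction label preserved).
#' @export
swap_sides <- function(r) {
  tmp <- r$left
  r$left <- r$right
  r$right <- tmp
  r
}
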