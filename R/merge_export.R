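# status quality ordering for combining member balance reports
.BALANCE_RANK <- c(balanced = 1L, balanced_tolerated = 2L, undetermined = 3L,
                   incomplete = 4L)

#' Collapse reactions sharing a key into unique merged reactions
#'
#' One merged reaction per distinct direction-agnostic [reaction_key()];
#' reactions whose key could not be computed (unresolved participants)
#' become singletons flagged unmatched. EC sets and pathway annotations are
#' unioned over members; the merged balance status is the best-documented
#' member status, except that any `incomplete` member downgrades the whole
#' group to `incomplete` (conservative QC: modelers selecting balanced
#' reactions must not pick up an imbalanced member).
#'
#' @param keyed List of entries `list(record, key)` where `key` is the
#'   result of [reaction_key()] (or `NULL`) and `record` the (stripped)
#'   `reaction_record`; each entry may carry `balance` (a
#'   `balance_report`).
#' @param classes Compound classes from [match_compounds()] (for rendering
#'   representative equations).
#' @return List of `merged_reaction` objects, ordered by key; each has
#'   `unified_id`, `members`, `sources`, `ec_set`, `pathways`, `balance`,
#'   `side_a`, `side_b`, `representative_equation`, `unmatched`.
#' @export
merge_reactions <- function(keyed, classes) {
  key_str <- vapply(keyed, function(e)
    if (is.null(e$key)) NA_character_ else e$key$key, character(1))
  groups <- split(seq_along(keyed), key_str)
  # keyless records become singletons
  singletons <- which(is.na(key_str))
  groups <- c(groups, as.list(singletons))
  ord <- order(vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (!is.na(key_str[g[1]])) key_str[g[1]]
    else paste0("~unmatched:", keyed[[g[1]]]$record$source, ":",
                keyed[[g[1]]]$record$reaction_id)
  }, character(1)))
  groups <- groups[ord]
  width <- max(5L, nchar(length(groups)))
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    recs <- lapply(keyed[g], `[[`, "record")
    balances <- lapply(keyed[g], `[[`, "balance")
    balances <- balances[!vapply(balances, is.null, logical(1))]
    unmatched <- is.na(key_str[g[1]])
    key0 <- if (unmatched) NULL else keyed[[g[1]]]$key
    members <- lapply(recs, function(r)
      list(source = r$source, reaction_id = r$reaction_id))
    ec_set <- sort(unique(unlist(lapply(recs, `[[`, "ec_numbers"))))
    pathways <- sort(unique(unlist(lapply(recs, `[[`, "pathways"))))
    balance <- .combine_balance(balances)
    side_a <- if (!unmatched) key0$side_a else
      data.frame(class_id = integer(0), coefficient = character(0))
    side_b <- if (!unmatched) key0$side_b else side_a
    m <- structure(list(
      unified_id = sprintf("UR%0*d", width, gi),
      members = members,
      sources = sort(unique(vapply(members, `[[`, character(1), "source"))),
      ec_set = ec_set,
      pathways = pathways,
      balance = balance,
      side_a = side_a,
      side_b = side_b,
      key = if (unmatched) NA_character_ else key0$key,
      unmatched = unmatched
    ), class = "merged_reaction")
    m$representative_equation <- render_equation(m, classes)
    out[[gi]] <- m
  }
  out
}

.combine_balance <- function(balances) {
  if (!length(balances)) {
    return(structure(list(status = "undetermined",
                          deficit_left = integer(0),
                          deficit_right = integer(0),
                          tolerated_species = character(0)),
                     class = "balance_report"))
  }
  statuses <- vapply(balances, `[[`, character(1), "status")
  if (any(statuses == "incomplete")) {
    return(balances[[which(statuses == "incomplete")[1]]])
  }
  balances[[which.min(.BALANCE_RANK[statuses])]]
}

#' Render a merged reaction as an equation string
#'
#' Uses the stereo-preferred representative name of each compound class;
#' coefficient 1 is omitted, symbolic coefficients print literally, sides
#' appear in canonical key order joined by `" <=> "`.
#'
#' @param merged A `merged_reaction`.
#' @param classes Compound classes (list indexed by `class_id`).
#' @return Equation string (`""` for unmatched singletons without sides).
#' @export
render_equation <- function(merged, classes) {
  if (!nrow(merged$side_a)) return("")
  name_of <- function(cid) classes[[cid]]$representative_name
  fmt <- function(df) {
    paste(vapply(seq_len(nrow(df)), function(i) {
      nm <- name_of(df$class_id[i])
      if (df$coefficient[i] == "1") nm else paste(df$coefficient[i], nm)
    }, character(1)), collapse = " + ")
  }
  paste(fmt(merged$side_a), "<=>", fmt(merged$side_b))
}

#' @export
print.merged_reaction <- function(x, ...) {
  cat(sprintf("<%s [%s] %s | %d member(s), %s>\n", x$unified_id,
              paste(x$sources, collapse = ","), x$representative_equation,
              length(x$members), x$balance$status))
  invisible(x)
}

#' Count (reaction, EC) combinations
#'
#' Some reactions are catalyzed by several enzymes, so the number of
#' EC/reaction combinations exceeds the number of unique reactions. Each
#' merged reaction contributes one combination per distinct EC label
#' (complete, incomplete or `SPONTANEOUS`), and one when its EC set is
#' empty.
#'
#' @param merged List of `merged_reaction`.
#' @return Integer.
#' @export
ec_reaction_combinations <- function(merged) {
  sum(vapply(merged, function(m) max(1L, length(m$ec_set)), integer(1)))
}

#' Overlap (Venn) statistics over the merged reaction set
#'
#' Assigns every unique reaction to the Venn cell of the set of sources
#' contributing at least one member, and reconciles the cell sums against
#' the unique-reaction count (stopping on mismatch — an internal invariant).
#'
#' @param merged List of `merged_reaction`.
#' @return An object of class `overlap_stats`: list with `cells` (named
#'   integer vector, names like `"BRENDA&KEGG"`), `per_source` totals,
#'   `unique_reaction_count`, `ec_reaction_combination_count`.
#' @export
overlap_stats <- function(merged) {
  cell_of <- vapply(merged, function(m) paste(m$sources, collapse = "&"),
                    character(1))
  cells <- table(cell_of)
  cells <- stats::setNames(as.integer(cells), names(cells))
  uniq <- length(merged)
  if (sum(cells) != uniq) {
    stop("internal invariant violated: Venn cell sum (", sum(cells),
         ") != unique reaction count (", uniq, ")")
  }
  sources <- sort(unique(unlist(lapply(merged, `[[`, "sources"))))
  per_source <- vapply(sources, function(s)
    sum(vapply(merged, function(m) s %in% m$sources, logical(1))),
    integer(1))
  structure(list(cells = cells, per_source = per_source,
                 unique_reaction_count = uniq,
                 ec_reaction_combination_count =
                   ec_reaction_combinations(merged)),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat("unique reactions:", x$unique_reaction_count, "\n")
  cat("EC/reaction combinations:", x$ec_reaction_combination_count, "\n")
  for (nm in names(x$cells)) cat(sprintf("  %-30s %d\n", nm, x$cells[[nm]]))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Run the full reconciliation pipeline
#'
#' End-to-end integration of two or more source dumps:
#' \enumerate{
#'   \item alias substitution per dump ([apply_aliases()]);
#'   \item NAD(P)/H placeholder splitting ([split_placeholders_in_dump()]);
#'   \item cross-source compound matching ([match_compounds()]);
#'   \item element-balance QC per reaction ([check_balance()]) — run
#'     \emph{before} water/proton removal;
#'   \item water/proton stripping ([strip_water_protons()]);
#'   \item direction-agnostic reaction keys ([reaction_key()]) and merging
#'     ([merge_reactions()]);
#'   \item overlap statistics ([overlap_stats()]).
#' }
#'
#' @param dumps List of `source_dump` objects.
#' @param stereo_relaxed Enable the stereo-relaxed compound-matching tier.
#' @return List with `classes`, `class_of` (ref -> class_id), `merged`,
#'   `stats`, `balance` (data.frame: source, reaction_id, status,
#'   missing_substrate, missing_product), `stripped_out` (reactions
#'   excluded because a side emptied), `conflicts`.
#' @export
reconcile <- function(dumps, stereo_relaxed = TRUE) {
  stopifnot(length(dumps) >= 1L,
            all(vapply(dumps, inherits, logical(1), "source_dump")))
  labels <- vapply(dumps, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate dump labels")
  dumps <- lapply(dumps, apply_aliases)
  dumps <- lapply(dumps, split_placeholders_in_dump)

  classes <- match_compounds(dumps, stereo_relaxed = stereo_relaxed)
  class_of <- integer(0)
  for (cl in classes) {
    for (m in cl$members) {
      class_of[paste(m$source, m$compound_id, sep = "\r")] <- cl$class_id
    }
  }

  # class-level formulas let structure-less members inherit the
  # representative's formula for balance checking
  class_formula <- lapply(classes, function(cl) {
    if (is.na(cl$formula)) return(NULL)
    f <- formula_to_counts(cl$formula)
    if (f$has_unknown) NULL else f
  })

  small <- small_species_refs(dumps)

  keyed <- list()
  balance_rows <- list()
  stripped_out <- list()
  for (d in dumps) {
    fmap <- formula_map(d)
    # inherit formulas from class representatives where the member lacks one
    for (i in seq_len(nrow(d$compounds))) {
      cid <- d$compounds$compound_id[i]
      if (!is.null(fmap[[cid]])) next
      cl <- class_of[paste(d$label, cid, sep = "\r")]
      if (!is.na(cl) && !is.null(class_formula[[cl]])) {
        fmap[[cid]] <- class_formula[[cl]]
      }
    }
    small_ids <- sub("^.*\r", "",
                     small[startsWith(small, paste0(d$label, "\r"))])
    for (r in d$reactions) {
      bal <- check_balance(r, fmap)
      balance_rows[[length(balance_rows) + 1L]] <- data.frame(
        source = r$source, reaction_id = r$reaction_id,
        status = bal$status,
        missing_substrate = counts_to_formula(bal$deficit_left),
        missing_product = counts_to_formula(bal$deficit_right),
        stringsAsFactors = FALSE)
      s <- strip_water_protons(r, small_ids)
      if (is.null(s)) {
        stripped_out[[length(stripped_out) + 1L]] <-
          list(source = r$source, reaction_id = r$reaction_id)
        next
      }
      keyed[[length(keyed) + 1L]] <-
        list(record = s, key = reaction_key(s, class_of), balance = bal)
    }
  }
  merged <- merge_reactions(keyed, classes)
  list(classes = classes,
       class_of = class_of,
       merged = merged,
       stats = overlap_stats(merged),
       balance = do.call(rbind, balance_rows),
       stripped_out = stripped_out,
       conflicts = attr(classes, "conflicts"))
}
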