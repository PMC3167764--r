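# ---------------------------------------------------------------------------
# Union-find with per-root structure-key bookkeeping. The tier-2/tier-3
# guards need to know, at union time, which reduced key (if any) each
# current class carries, so a plain connected-components pass would not do.

.uf_new <- function(n) {
  list(parent = seq_len(n), rank = integer(n))
}

.uf_find <- function(uf, i) {
  root <- i
  while (uf$parent[root] != root) root <- uf$parent[root]
  while (uf$parent[i] != root) {   # path compression
    nxt <- uf$parent[i]
    uf$parent[i] <- root
    i <- nxt
  }
  list(uf = uf, root = root)
}

.uf_union <- function(uf, i, j) {
  fi <- .uf_find(uf, i); uf <- fi$uf
  fj <- .uf_find(uf, j); uf <- fj$uf
  a <- fi$root; b <- fj$root
  if (a == b) return(list(uf = uf, root = a))
  if (uf$rank[a] < uf$rank[b]) { tmp <- a; a <- b; b <- tmp }
  uf$parent[b] <- a
  if (uf$rank[a] == uf$rank[b]) uf$rank[a] <- uf$rank[a] + 1L
  list(uf = uf, root = a)
}

# ---------------------------------------------------------------------------

#' Flatten dumps into one compound table with structure keys
#'
#' Binds the compound tables of all dumps and computes, per compound, the
#' reduced structure key, its stereo-stripped form, the count of defined
#' stereo descriptors and the formula-layer element counts.
#'
#' @param dumps List of `source_dump` objects.
#' @return A data.frame with one row per (source, compound_id), columns
#'   `key` (reduced key or `NA` when no structure), `stripped`,
#'   `n_stereo`, `has_stereo`, `formula`.
#' @export
compound_universe <- function(dumps) {
  comps <- do.call(rbind, lapply(dumps, `[[`, "compounds"))
  n <- nrow(comps)
  key <- rep(NA_character_, n)
  formula <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    inchi <- comps$inchi[i]
    if (!is.na(inchi)) {
      layers <- parse_inchi(inchi)
      k <- reduce_inchi(layers)
      if (nzchar(k)) {
        key[i] <- k
        formula[i] <- layers$formula
      }
    }
  }
  comps$key <- key
  comps$formula <- formula
  comps$stripped <- vapply(key, function(k)
    if (is.na(k)) NA_character_ else strip_stereo(k), character(1),
    USE.NAMES = FALSE)
  comps$n_stereo <- vapply(key, function(k)
    if (is.na(k)) 0L else count_stereo_descriptors(k), integer(1),
    USE.NAMES = FALSE)
  comps$has_stereo <- vapply(key, function(k)
    if (is.na(k)) FALSE else has_stereo_layers(k), logical(1),
    USE.NAMES = FALSE)
  rownames(comps) <- NULL
  comps
}

#' Build cross-source compound equivalence classes
#'
#' Compounds are merged by union-find over three edge generators applied in
#' order:
#' \enumerate{
#'   \item \strong{structure}: equal reduced InChI key (ionisation
#'     variants of one parent compound merge here);
#'   \item \strong{name}: equal normalized name (including synonyms and
#'     implicit-stereo expansions) where at least one endpoint has no
#'     structure — a name edge that would bridge two classes carrying
#'     different structure keys is refused and logged as a conflict,
#'     because identical synonyms can occur for different compounds;
#'   \item \strong{stereo_relaxed} (optional, default on): equal
#'     stereo-stripped key where exactly one endpoint's key carries no
#'     stereo layers (stereochemistry undefined in that source). Refused
#'     when it would bridge two classes with distinct fully-defined keys.
#' }
#'
#' @param dumps List of `source_dump` objects (typically after
#'   [apply_aliases()]).
#' @param stereo_relaxed Enable the third tier.
#' @param name_matching Enable the second (name) tier; disabling it leaves
#'   structure-less compounds as singletons (mainly for ablation studies).
#' @param stereo_table Implicit-stereo table for [build_name_index()].
#' @return List of `compound_class` objects: each has `class_id`,
#'   `members` (list of `list(source, compound_id)`), `tiers` (tier of the
#'   edge that attached each merge), `representative`
#'   (`list(source, compound_id)`), `representative_name`,
#'   `representative_key`, `formula` (element-count source for balance).
#'   `attr(result, "conflicts")` lists refused name merges.
#' @export
match_compounds <- function(dumps, stereo_relaxed = TRUE,
                            name_matching = TRUE,
                            stereo_table = default_implicit_stereo_table()) {
  comps <- compound_universe(dumps)
  n <- nrow(comps)
  uf <- .uf_new(n)
  # root -> defined structure key carried by the class (NA when none)
  root_key <- comps$key
  tiers_used <- character(0)
  edge_tiers <- rep(NA_character_, n)   # tier by which row i was attached
  conflicts <- character(0)

  get_key <- function(root) root_key[root]

  # --- tier 1: equal reduced key
  with_key <- which(!is.na(comps$key))
  for (grp in split(with_key, comps$key[with_key])) {
    if (length(grp) < 2L) next
    for (j in grp[-1]) {
      res <- .uf_union(uf, grp[1], j)
      uf <- res$uf
      root_key[res$root] <- comps$key[grp[1]]
      if (is.na(edge_tiers[j])) edge_tiers[j] <- "structure"
      if (is.na(edge_tiers[grp[1]])) edge_tiers[grp[1]] <- "structure"
    }
  }

  # --- tier 2: equal normalized name, >=1 endpoint structureless
  ref <- paste(comps$source, comps$compound_id, sep = "\r")
  idx <- if (name_matching) build_name_index(comps, stereo_table = stereo_table)
         else build_name_index(comps[0, ], stereo_table = stereo_table)
  idx$row <- match(paste(idx$source, idx$compound_id, sep = "\r"), ref)
  for (grp in split(idx$row, idx$key)) {
    grp <- unique(grp)
    if (length(grp) < 2L) next
    nostruct <- grp[is.na(comps$key[grp])]
    if (!length(nostruct)) next
    anchor <- nostruct[1]
    for (j in setdiff(grp, anchor)) {
      if (!is.na(comps$key[j]) && !is.na(comps$key[anchor])) next
      fa <- .uf_find(uf, anchor); uf <- fa$uf
      fj <- .uf_find(uf, j); uf <- fj$uf
      ka <- get_key(fa$root); kj <- get_key(fj$root)
      if (!is.na(ka) && !is.na(kj) && ka != kj) {
        conflicts <- c(conflicts, sprintf(
          "name merge refused (different structures): %s:%s ~ %s:%s",
          comps$source[anchor], comps$compound_id[anchor],
          comps$source[j], comps$compound_id[j]))
        next
      }
      res <- .uf_union(uf, anchor, j)
      uf <- res$uf
      root_key[res$root] <- if (!is.na(ka)) ka else kj
      if (is.na(edge_tiers[j])) edge_tiers[j] <- "name"
      if (is.na(edge_tiers[anchor])) edge_tiers[anchor] <- "name"
    }
  }

  # --- tier 3: equal stereo-stripped key, exactly one endpoint undefined
  if (stereo_relaxed) {
    with_struct <- which(!is.na(comps$key))
    for (grp in split(with_struct, comps$stripped[with_struct])) {
      grp <- unique(grp)
      if (length(grp) < 2L) next
      undef <- grp[!comps$has_stereo[grp]]
      def <- grp[comps$has_stereo[grp]]
      if (!length(undef) || !length(def)) next
      for (u in undef) {
        for (d in def) {
          fu <- .uf_find(uf, u); uf <- fu$uf
          fd <- .uf_find(uf, d); uf <- fd$uf
          if (fu$root == fd$root) next
          ku <- get_key(fu$root); kd <- get_key(fd$root)
          if (!is.na(ku) && !is.na(kd) && ku != kd &&
              has_stereo_layers(ku) && has_stereo_layers(kd)) {
            conflicts <- c(conflicts, sprintf(
              "stereo-relaxed merge refused (two defined forms): %s:%s ~ %s:%s",
              comps$source[u], comps$compound_id[u],
              comps$source[d], comps$compound_id[d]))
            next
          }
          res <- .uf_union(uf, u, d)
          uf <- res$uf
          # prefer the defined-stereo key for the merged class
          root_key[res$root] <-
            if (!is.na(kd) && has_stereo_layers(kd)) kd
            else if (!is.na(ku) && has_stereo_layers(ku)) ku
            else if (!is.na(kd)) kd else ku
          if (is.na(edge_tiers[u])) edge_tiers[u] <- "stereo_relaxed"
          if (is.na(edge_tiers[d])) edge_tiers[d] <- "stereo_relaxed"
          # flag the whole merge as relaxed
          edge_tiers[u] <- "stereo_relaxed"
        }
      }
    }
  }

  # --- emit classes
  roots <- integer(n)
  for (i in seq_len(n)) {
    f <- .uf_find(uf, i); uf <- f$uf
    roots[i] <- f$root
  }
  groups <- split(seq_len(n), roots)
  # deterministic ids: sort classes by the lexicographically smallest
  # (source, compound_id) member
  smallest <- vapply(groups, function(g) min(ref[g]), character(1))
  groups <- groups[order(smallest)]
  classes <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    g <- g[order(ref[g])]
    rep_i <- .pick_representative(comps, g)
    classes[[k]] <- structure(list(
      class_id = k,
      members = lapply(g, function(i)
        list(source = comps$source[i], compound_id = comps$compound_id[i])),
      tiers = ifelse(is.na(edge_tiers[g]), "singleton", edge_tiers[g]),
      representative = list(source = comps$source[rep_i],
                            compound_id = comps$compound_id[rep_i]),
      representative_name = comps$name[rep_i],
      representative_key = comps$key[rep_i],
      formula = comps$formula[rep_i],
      is_generic = any(comps$is_generic[g])
    ), class = "compound_class")
  }
  attr(classes, "conflicts") <- conflicts
  classes
}

# Representative: member with the greatest count of defined stereo
# descriptors in its reduced key; ties broken by (source, compound_id).
.pick_representative <- function(comps, g) {
  scores <- comps$n_stereo[g]
  # members with a structure outrank structureless ones
  scores <- scores + ifelse(is.na(comps$key[g]), -1L, 0L)
  best <- g[scores == max(scores)]
  refs <- paste(comps$source[best], comps$compound_id[best], sep = "\r")
  best[order(refs)][1]
}

#' Select the stereo-preferred representative of a compound class
#'
#' Standalone form of the rule applied inside [match_compounds()]:
#' the member whose reduced key defines the most stereo descriptors wins
#' (metabolites with complete stereochemistry are favored); ties are broken
#' by lexicographic (source, compound_id) order for determinism.
#'
#' @param members Data.frame with columns `source`, `compound_id`, `key`
#'   (reduced key or `NA`).
#' @return The winning row's `list(source, compound_id)`.
#' @export
select_representative <- function(members) {
  stopifnot(nrow(members) >= 1L)
  n_st <- vapply(members$key, function(k)
    if (is.na(k)) -1L else count_stereo_descriptors(k), integer(1),
    USE.NAMES = FALSE)
  best <- which(n_st == max(n_st))
  refs <- paste(members$source[best], members$compound_id[best], sep = "\r")
  i <- best[order(refs)][1]
  list(source = members$source[i], compound_id = members$compound_id[i])
}

#' Rewrite alias compound references to their canonical IDs
#'
#' Applies a source's alias map (e.g. KEGG glycan G numbers mapped to their
#' corresponding compound C numbers) to every reaction participant,
#' resolving alias chains transitively; alias compound records are absorbed
#' into the canonical record (their names join its synonym list) and
#' removed from the compound table.
#'
#' @param dump A `source_dump`.
#' @return The rewritten `source_dump`.
#' @export
apply_aliases <- function(dump) {
  stopifnot(inherits(dump, "source_dump"))
  if (!length(dump$aliases)) return(dump)
  resolve <- function(id) {
    seen <- character(0)
    while (id %in% names(dump$aliases)) {
      if (id %in% seen) stop("alias cycle involving '", id, "'")
      seen <- c(seen, id)
      id <- dump$aliases[[id]]
    }
    id
  }
  canon <- vapply(names(dump$aliases), resolve, character(1))
  missing <- setdiff(canon, dump$compounds$compound_id)
  if (length(missing)) {
    stop("alias map: canonical id(s) not in compound table: ",
         paste(missing, collapse = ", "))
  }
  comps <- dump$compounds
  alias_rows <- comps$compound_id %in% names(dump$aliases)
  for (i in which(alias_rows)) {
    tgt <- which(comps$compound_id == canon[[comps$compound_id[i]]])
    comps$synonyms[[tgt]] <- unique(c(comps$synonyms[[tgt]],
                                      comps$name[i], comps$synonyms[[i]]))
  }
  comps <- comps[!alias_rows, , drop = FALSE]
  rxns <- lapply(dump$reactions, function(r) {
    fix <- function(side) {
      hit <- side$compound_id %in% names(canon)
      side$compound_id[hit] <- unname(canon[side$compound_id[hit]])
      side
    }
    r$left <- fix(r$left)
    r$right <- fix(r$right)
    r
  })
  source_dump(dump$label, comps, rxns, character(0))
}

#' @export
print.compound_class <- function(x, ...) {
  cat(sprintf("<compound_class %d: %d member(s), rep %s:%s ('%s')>\n",
              x$class_id, length(x$members), x$representative$source,
              x$representative$compound_id, x$representative_name))
  invisible(x)
}
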