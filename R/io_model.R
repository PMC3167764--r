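#' Construct a compound record
#'
#' One compound as published by one source database: identifier, preferred
#' name, synonyms, and optionally a structure as InChI and/or Molfile.
#' Generic compounds ("an aldehyde", "an alcohol") carry no structure and
#' are matchable only by name.
#'
#' @param source Source-database label.
#' @param compound_id Source-local identifier.
#' @param name Preferred name.
#' @param synonyms Character vector of synonyms (may include externally
#'   generated systematic names).
#' @param inchi Optional InChI string (must start with `"InChI="`).
#' @param molfile Optional Molfile text.
#' @param is_generic Is this a generic compound class name? Implies no
#'   structure.
#' @return A one-row data.frame with a `synonyms` list-column.
#' @export
compound_record <- function(source, compound_id, name,
                            synonyms = character(0),
                            inchi = NA_character_, molfile = NA_character_,
                            is_generic = FALSE) {
  if (!is.na(inchi)) {
    if (!startsWith(inchi, "InChI=")) {
      stop("compound ", source, ":", compound_id,
           ": inchi does not start with 'InChI='")
    }
    if (is_generic) {
      stop("compound ", source, ":", compound_id,
           ": generic compounds cannot carry a structure")
    }
  }
  out <- data.frame(source = source, compound_id = compound_id, name = name,
                    inchi = inchi, molfile = molfile, is_generic = is_generic,
                    stringsAsFactors = FALSE)
  out$synonyms <- list(as.character(synonyms))
  out
}

#' Construct a reaction record
#'
#' One reaction as published by one source: participants with coefficients
#' on each side, EC numbers (complete, incomplete with trailing `-` fields,
#' the literal `SPONTANEOUS` label for uncatalyzed reactions, or none),
#' direction and pathway annotations.
#'
#' @param source Source-database label.
#' @param reaction_id Source-local identifier.
#' @param left,right Data.frames with columns `coefficient` (character:
#'   a positive integer or the symbol `"n"`) and `compound_id`.
#' @param ec_numbers Character vector of EC strings.
#' @param direction One of `"reversible"`, `"left_to_right"`,
#'   `"unspecified"`.
#' @param pathways Character vector of `"pathway-source:pathway-name"`
#'   annotations.
#' @return An object of class `reaction_record`.
#' @export
reaction_record <- function(source, reaction_id, left, right,
                            ec_numbers = character(0),
                            direction = c("reversible", "left_to_right",
                                          "unspecified"),
                            pathways = character(0)) {
  direction <- match.arg(direction)
  left <- .as_side(left)
  right <- .as_side(right)
  if (nrow(left) == 0L || nrow(right) == 0L) {
    stop("reaction ", source, ":", reaction_id,
         ": both sides must be non-empty")
  }
  for (side in list(left, right)) {
    num <- suppressWarnings(as.integer(side$coefficient))
    bad <- !is.na(num) & num < 1L
    if (any(bad)) stop("reaction ", source, ":", reaction_id,
                       ": numeric coefficients must be >= 1")
  }
  structure(list(source = source, reaction_id = reaction_id,
                 ec_numbers = as.character(ec_numbers),
                 left = left, right = right,
                 direction = direction,
                 pathways = as.character(pathways)),
            class = "reaction_record")
}

.as_side <- function(x) {
  if (is.null(x)) x <- data.frame(coefficient = character(0),
                                  compound_id = character(0))
  stopifnot(is.data.frame(x), all(c("coefficient", "compound_id") %in% names(x)))
  data.frame(coefficient = as.character(x$coefficient),
             compound_id = as.character(x$compound_id),
             stringsAsFactors = FALSE)
}

#' @export
print.reaction_record <- function(x, ...) {
  fmt <- function(s) paste(ifelse(s$coefficient == "1", s$compound_id,
                                  paste(s$coefficient, s$compound_id)),
                           collapse = " + ")
  arrow <- switch(x$direction, reversible = "<=>", left_to_right = "=>",
                  unspecified = "=")
  cat(sprintf("<%s:%s> %s %s %s\n", x$source, x$reaction_id,
              fmt(x$left), arrow, fmt(x$right)))
  invisible(x)
}

#' Construct a source dump
#'
#' A complete dump of one source database: its compound table, reaction
#' list and glycan/compound alias map.
#'
#' @param label Source-database label (e.g. `"KEGG"`).
#' @param compounds Data.frame of compound records (rbind of
#'   [compound_record()] rows).
#' @param reactions List of [reaction_record()] objects.
#' @param aliases Named character vector: `alias_id -> canonical_id`.
#' @return An object of class `source_dump`.
#' @export
source_dump <- function(label, compounds = NULL, reactions = list(),
                        aliases = character(0)) {
  if (is.null(compounds)) {
    compounds <- compound_record("x", "x", "x")[0, ]
  }
  dup <- duplicated(compounds[c("source", "compound_id")])
  if (any(dup)) {
    stop("dump '", label, "': duplicate compound ids: ",
         paste(unique(compounds$compound_id[dup]), collapse = ", "))
  }
  structure(list(label = label, compounds = compounds,
                 reactions = reactions, aliases = aliases),
            class = "source_dump")
}

#' @export
print.source_dump <- function(x, ...) {
  cat(sprintf("<source_dump '%s': %d compounds, %d reactions, %d aliases>\n",
              x$label, nrow(x$compounds), length(x$reactions),
              length(x$aliases)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dump reading / writing

#' Read a source dump from a JSON file or a TSV directory
#'
#' JSON dumps are a single object with fields `label`, `compounds`,
#' `reactions` (each reaction gives either an `equation` text or structured
#' `left`/`right` participant lists) and `aliases`. TSV dumps are a
#' directory containing `compounds.tsv`, `reactions.tsv` and optionally
#' `aliases.tsv` (columns documented in the package README); synonyms are
#' `|`-separated, EC numbers and pathways `;`-separated.
#'
#' Equations are parsed with [parse_equation()] and participant names
#' resolved against the dump's compound table. Reactions referencing a
#' compound that cannot be resolved are excluded with a warning and listed
#' in `attr(dump, "excluded")`.
#'
#' @param path Path to a `.json` file or a dump directory.
#' @param format `"json"` or `"tsv"`; inferred from `path` by default.
#' @return A `source_dump`.
#' @export
read_dump <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tsv" else "json"
  }
  dump <- if (format == "json") .read_dump_json(path) else .read_dump_tsv(path)
  .resolve_dump(dump)
}

.read_dump_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- do.call(rbind, lapply(j$compounds, function(cc) {
    compound_record(source = j$label,
                    compound_id = cc$compound_id,
                    name = cc$name,
                    synonyms = unlist(cc$synonyms) %||% character(0),
                    inchi = cc$inchi %||% NA_character_,
                    molfile = cc$molfile %||% NA_character_,
                    is_generic = isTRUE(cc$is_generic))
  }))
  rxns <- lapply(j$reactions, function(rr) {
    if (!is.null(rr$equation)) {
      list(reaction_id = rr$reaction_id,
           equation = rr$equation,
           ec_numbers = unlist(rr$ec_numbers) %||% character(0),
           pathways = unlist(rr$pathways) %||% character(0))
    } else {
      side <- function(s) do.call(rbind, lapply(s, function(p)
        data.frame(coefficient = as.character(p$coefficient),
                   compound_id = p$compound_id, stringsAsFactors = FALSE)))
      reaction_record(source = j$label, reaction_id = rr$reaction_id,
                      left = side(rr$left), right = side(rr$right),
                      ec_numbers = unlist(rr$ec_numbers) %||% character(0),
                      direction = .arrow_to_direction(rr$direction %||% "="),
                      pathways = unlist(rr$pathways) %||% character(0))
    }
  })
  aliases <- unlist(j$aliases) %||% character(0)
  source_dump(j$label, comps, rxns, aliases)
}

.read_dump_tsv <- function(path) {
  read_tsv0 <- function(f) {
    utils::read.delim(file.path(path, f), stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = NULL)
  }
  ct <- read_tsv0("compounds.tsv")
  label <- if (nrow(ct)) ct$source[1] else basename(path)
  comps <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
    syn <- if (nzchar(ct$synonyms[i]))
      strsplit(ct$synonyms[i], "|", fixed = TRUE)[[1]] else character(0)
    compound_record(source = ct$source[i], compound_id = ct$compound_id[i],
                    name = ct$name[i], synonyms = syn,
                    inchi = if (nzchar(ct$inchi[i])) ct$inchi[i] else NA_character_,
                    is_generic = ct$is_generic[i] %in% c("TRUE", "true", "1"))
  }))
  rt <- read_tsv0("reactions.tsv")
  rxns <- lapply(seq_len(nrow(rt)), function(i) {
    split0 <- function(x) if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1]]
                          else character(0)
    list(reaction_id = rt$reaction_id[i], equation = rt$equation[i],
         ec_numbers = split0(rt$ec_numbers[i]),
         pathways = split0(rt$pathways[i]))
  })
  aliases <- character(0)
  af <- file.path(path, "aliases.tsv")
  if (file.exists(af)) {
    at <- read_tsv0("aliases.tsv")
    aliases <- stats::setNames(at$canonical_id, at$alias_id)
  }
  source_dump(label, comps, rxns, aliases)
}

# Parse equations and resolve participant names to compound ids; exclude
# reactions with dangling references.
.resolve_dump <- function(dump) {
  excluded <- data.frame(reaction_id = character(0), problem = character(0),
                         stringsAsFactors = FALSE)
  resolved <- list()
  for (r in dump$reactions) {
    if (inherits(r, "reaction_record")) {
      missing <- setdiff(c(r$left$compound_id, r$right$compound_id),
                         c(dump$compounds$compound_id, names(dump$aliases)))
      if (length(missing)) {
        warning("dump '", dump$label, "': reaction ", r$reaction_id,
                " references unknown compound(s) ",
                paste(missing, collapse = ", "), "; excluded",
                call. = FALSE)
        excluded <- rbind(excluded, data.frame(
          reaction_id = r$reaction_id,
          problem = paste("unknown compound:", paste(missing, collapse = ",")),
          stringsAsFactors = FALSE))
        next
      }
      resolved[[length(resolved) + 1L]] <- r
      next
    }
    eq <- tryCatch(parse_equation(r$equation), error = function(e) e)
    if (inherits(eq, "error")) {
      warning("dump '", dump$label, "': reaction ", r$reaction_id, ": ",
              conditionMessage(eq), "; excluded", call. = FALSE)
      excluded <- rbind(excluded, data.frame(reaction_id = r$reaction_id,
                                             problem = conditionMessage(eq),
                                             stringsAsFactors = FALSE))
      next
    }
    res <- .resolve_names(eq, dump)
    if (!is.null(res$missing)) {
      warning("dump '", dump$label, "': reaction ", r$reaction_id,
              ": unresolved participant name(s) ",
              paste(res$missing, collapse = ", "), "; excluded",
              call. = FALSE)
      excluded <- rbind(excluded, data.frame(
        reaction_id = r$reaction_id,
        problem = paste("unresolved name:", paste(res$missing, collapse = ",")),
        stringsAsFactors = FALSE))
      next
    }
    resolved[[length(resolved) + 1L]] <-
      reaction_record(source = dump$label, reaction_id = r$reaction_id,
                      left = res$left, right = res$right,
                      ec_numbers = r$ec_numbers, direction = eq$direction,
                      pathways = r$pathways)
  }
  out <- source_dump(dump$label, dump$compounds, resolved, dump$aliases)
  attr(out, "excluded") <- excluded
  out
}

# Resolve participant names to compound ids within one source: exact
# preferred-name or synonym match first, normalized match as fallback.
.resolve_names <- function(eq, dump) {
  comps <- dump$compounds
  lookup <- function(nm) {
    hit <- which(comps$name == nm)
    if (!length(hit)) {
      hit <- which(vapply(comps$synonyms, function(s) nm %in% s, logical(1)))
    }
    if (!length(hit)) {
      key <- normalize_name(nm)
      norm_hit <- which(normalize_name(comps$name) == key)
      if (!length(norm_hit)) {
        norm_hit <- which(vapply(comps$synonyms, function(s)
          key %in% normalize_name(s), logical(1)))
      }
      hit <- norm_hit
    }
    if (!length(hit)) NA_character_ else comps$compound_id[hit[1]]
  }
  resolve_side <- function(side) {
    ids <- vapply(side$name, lookup, character(1))
    data.frame(coefficient = side$coefficient, compound_id = ids,
               stringsAsFactors = FALSE)
  }
  left <- resolve_side(eq$left)
  right <- resolve_side(eq$right)
  missing <- c(eq$left$name[is.na(left$compound_id)],
               eq$right$name[is.na(right$compound_id)])
  if (length(missing)) return(list(missing = missing))
  list(left = left, right = right)
}

#' Write a source dump to a JSON file
#'
#' Inverse of [read_dump()] for the JSON twin; reading the written file
#' round-trips to an identical dump.
#'
#' @param dump A `source_dump`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_dump <- function(dump, path) {
  stopifnot(inherits(dump, "source_dump"))
  comps <- lapply(seq_len(nrow(dump$compounds)), function(i) {
    cc <- dump$compounds[i, ]
    out <- list(compound_id = cc$compound_id, name = cc$name,
                synonyms = cc$synonyms[[1]])
    if (!is.na(cc$inchi)) out$inchi <- cc$inchi
    if (!is.na(cc$molfile)) out$molfile <- cc$molfile
    if (cc$is_generic) out$is_generic <- TRUE
    out
  })
  rxns <- lapply(dump$reactions, function(r) {
    side <- function(s) lapply(seq_len(nrow(s)), function(i)
      list(coefficient = s$coefficient[i], compound_id = s$compound_id[i]))
    list(reaction_id = r$reaction_id, ec_numbers = r$ec_numbers,
         left = side(r$left), right = side(r$right),
         direction = .direction_to_arrow(r$direction),
         pathways = r$pathways)
  })
  obj <- list(label = dump$label, compounds = comps, reactions = rxns,
              aliases = as.list(dump$aliases))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.arrow_to_direction <- function(arrow) {
  switch(arrow,
         "<=>" = "reversible",
         "=>" = , "->" = , "→" = "left_to_right",
         "=" = "unspecified",
         stop("unknown direction arrow: ", arrow))
}

.direction_to_arrow <- function(direction) {
  switch(direction, reversible = "<=>", left_to_right = "=>",
         unspecified = "=")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# SDF

#' Read Molfiles from an SDF file
#'
#' Parses a V2000 SDF (via ChemmineR) and returns the Molfile text of each
#' record keyed by its ID data field. Records lacking the ID field are
#' skipped with a warning; structurally invalid (truncated) records raise
#' an error naming the record index.
#'
#' @param path Path to the SDF file.
#' @param id_field Name of the data field holding the compound ID
#'   (default `"ID"`).
#' @return Named character vector: `compound_id -> Molfile text`.
#' @export
read_molfiles <- function(path, id_field = "ID") {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("read_molfiles requires the ChemmineR package")
  }
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfset)
  if (any(!valid)) {
    stop("truncated or invalid SDF record(s) at index: ",
         paste(which(!valid), collapse = ", "))
  }
  out <- character(0)
  skipped <- 0L
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    db <- ChemmineR::datablock(sdf)
    if (!(id_field %in% names(db)) || !nzchar(db[[id_field]])) {
      skipped <- skipped + 1L
      next
    }
    lines <- ChemmineR::sdf2str(sdf)
    endi <- which(trimws(lines) == "M  END" | trimws(lines) == "M END")[1]
    if (is.na(endi)) endi <- length(lines)
    out[[db[[id_field]]]] <- paste(lines[seq_len(endi)], collapse = "\n")
  }
  if (skipped > 0L) {
    warning(skipped, " SDF record(s) without '", id_field,
            "' field skipped", call. = FALSE)
  }
  out
}

# ---------------------------------------------------------------------------
# Three-table CSV export

#' Write the three-table CSV cross-reference
#'
#' Exports the merge result as three RFC 4180 CSV files: `Reactions.csv`
#' (one row per unique reaction with per-source member IDs, the union EC
#' set, the representative equation, the stoichiometry status and the
#' Missing Substrate / Missing Product deficit formulas), `Compounds.csv`
#' (one row per compound class) and `Links.csv` (one row per participant,
#' connecting reactions and compound classes with side and coefficient).
#'
#' @param merged List of merged reactions from [merge_reactions()].
#' @param classes List of compound classes from [match_compounds()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_output_tables <- function(merged, classes, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  sources <- sort(unique(unlist(lapply(merged, function(m)
    unique(vapply(m$members, `[[`, character(1), "source"))))))
  join <- function(x) paste(x, collapse = ";")

  rrows <- lapply(merged, function(m) {
    msrc <- vapply(m$members, `[[`, character(1), "source")
    mids <- vapply(m$members, `[[`, character(1), "reaction_id")
    row <- list(unified_id = m$unified_id)
    for (s in sources) row[[paste0("members_", s)]] <- join(mids[msrc == s])
    row$ec_numbers <- join(m$ec_set)
    row$equation <- m$representative_equation
    row$stoichiometry <- m$balance$status
    row$missing_substrate <- counts_to_formula(m$balance$deficit_left)
    row$missing_product <- counts_to_formula(m$balance$deficit_right)
    row$pathways <- join(m$pathways)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  reactions_df <- do.call(rbind, rrows)

  crows <- lapply(classes, function(cl) {
    msrc <- vapply(cl$members, `[[`, character(1), "source")
    mids <- vapply(cl$members, `[[`, character(1), "compound_id")
    row <- list(class_id = cl$class_id, name = cl$representative_name)
    for (s in sources) row[[paste0("members_", s)]] <- join(mids[msrc == s])
    row$reduced_key <- if (is.na(cl$representative_key)) "" else
      cl$representative_key
    row$stereo_relaxed <- any(cl$tiers == "stereo_relaxed")
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  compounds_df <- do.call(rbind, crows)

  lrows <- lapply(merged, function(m) {
    rbind(
      if (nrow(m$side_a)) data.frame(unified_id = m$unified_id,
                                     class_id = m$side_a$class_id,
                                     side = "substrate",
                                     coefficient = m$side_a$coefficient,
                                     stringsAsFactors = FALSE),
      if (nrow(m$side_b)) data.frame(unified_id = m$unified_id,
                                     class_id = m$side_b$class_id,
                                     side = "product",
                                     coefficient = m$side_b$coefficient,
                                     stringsAsFactors = FALSE))
  })
  links_df <- do.call(rbind, lrows)

  paths <- c(reactions = file.path(out_dir, "Reactions.csv"),
             compounds = file.path(out_dir, "Compounds.csv"),
             links = file.path(out_dir, "Links.csv"))
  utils::write.csv(reactions_df, paths[["reactions"]], row.names = FALSE)
  utils::write.csv(compounds_df, paths[["compounds"]], row.names = FALSE)
  utils::write.csv(links_df, paths[["links"]], row.names = FALSE)
  invisible(paths)
}
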