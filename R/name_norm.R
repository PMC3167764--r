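# Single-glyph Greek characters are transliterated to their spelled-out
# names before the deletion pass, so "β-D-glucose" and "beta-D-glucose"
# normalize identically.
.GREEK_MAP <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta", "θ" = "theta", "ι" = "iota",
  "κ" = "kappa", "λ" = "lambda", "μ" = "mu",
  "ν" = "nu", "ξ" = "xi", "ο" = "omicron",
  "π" = "pi", "ρ" = "rho", "σ" = "sigma",
  "τ" = "tau", "υ" = "upsilon", "φ" = "phi",
  "χ" = "chi", "ψ" = "psi", "ω" = "omega",
  "Α" = "alpha", "Β" = "beta", "Γ" = "gamma",
  "Δ" = "delta", "Ω" = "omega"
)

#' Normalize a compound name for exact matching
#'
#' Case-folds to lowercase and deletes every character outside
#' `[a-z0-9+']`: hyphens, parentheses, brackets, commas, spaces and other
#' punctuation vanish, so common spelling variants of one compound name
#' ("alpha, alpha-Trehalose" / "alpha, alpha-trehalose") collapse to one
#' string. `'+'` (charged cofactors such as NAD+) and the apostrophe
#' (primes in nucleotide names, 5'-phosphate) are retained. Single-glyph
#' Greek letters are transliterated first (see `greek`).
#'
#' @param name Character vector of names.
#' @param greek Transliterate Greek glyphs to spelled-out names
#'   (default `TRUE`).
#' @return Character vector of normalized names; `""` where the input
#'   contained no retained characters (such names are unusable for
#'   matching).
#' @examples
#' normalize_name(c("alpha, alpha-Trehalose", "NAD+", "D-Fructose 1,6-bisphosphate"))
#' @export
normalize_name <- function(name, greek = TRUE) {
  x <- tolower(name)
  if (greek) {
    for (g in names(.GREEK_MAP)) {
      x <- gsub(g, .GREEK_MAP[[g]], x, fixed = TRUE)
      x <- gsub(toupper(g), .GREEK_MAP[[g]], x, fixed = TRUE)
    }
  }
  gsub("[^a-z0-9+']", "", x, perl = TRUE)
}

#' Default implicit-stereo synonym table
#'
#' Biochemists routinely write "alanine" for L-alanine: for the standard
#' amino acids the bare name implicitly means the L- (S-) form. This table
#' maps the bare names of the 19 chiral proteinogenic amino acids (glycine
#' is achiral) to their L-qualified forms; the carboxylate ("-ate") spelling
#' variants are included for the acidic residues.
#'
#' @return A data.frame with columns `bare` and `qualified`.
#' @export
default_implicit_stereo_table <- function() {
  aa <- c("alanine", "arginine", "asparagine", "aspartate", "aspartic acid",
          "cysteine", "glutamate", "glutamic acid", "glutamine", "histidine",
          "isoleucine", "leucine", "lysine", "methionine", "phenylalanine",
          "proline", "serine", "threonine", "tryptophan", "tyrosine",
          "valine")
  data.frame(bare = aa, qualified = paste0("L-", aa),
             stringsAsFactors = FALSE)
}

#' Expand a name with its implicit-stereo qualified form
#'
#' Returns the input name plus, when the table lists the (case-insensitive)
#' bare name, the descriptor-qualified expansion. Used only to enrich
#' synonym lists before indexing; structures are never overwritten.
#'
#' @param name A single name string.
#' @param table Data.frame with columns `bare`, `qualified`
#'   (default [default_implicit_stereo_table()]).
#' @return Character vector: the name, possibly followed by expansions.
#' @examples
#' expand_implicit_stereo("alanine")
#' @export
expand_implicit_stereo <- function(name, table = default_implicit_stereo_table()) {
  hit <- table$qualified[tolower(table$bare) == tolower(name)]
  c(name, hit)
}

#' Build the synonym link index for name-based matching
#'
#' Indexes every preferred name, synonym and implicit-stereo expansion of
#' every compound under its normalized form. The index is non-judgemental:
#' a normalized name shared by two different structures yields one key with
#' two compound references; the conflict is resolved downstream by the
#' matching tiers.
#'
#' @param compounds A data.frame of compound records as produced by
#'   [compound_universe()] or a `source_dump`'s `compounds` table
#'   (columns `source`, `compound_id`, `name`, list-column `synonyms`).
#' @param stereo_table Implicit-stereo table passed to
#'   [expand_implicit_stereo()].
#' @return A data.frame (`name_index`) with columns `key` (normalized
#'   name), `source`, `compound_id`, `provenance`
#'   (`preferred`/`synonym`/`expanded`). Compounds whose every name
#'   normalizes to `""` are absent (logged via a message).
#' @export
build_name_index <- function(compounds,
                             stereo_table = default_implicit_stereo_table()) {
  rows <- vector("list", nrow(compounds))
  unusable <- character(0)
  for (i in seq_len(nrow(compounds))) {
    names_i <- c(compounds$name[i], compounds$synonyms[[i]])
    names_i <- names_i[!is.na(names_i) & nzchar(names_i)]
    prov <- c("preferred", rep("synonym", length(names_i) - 1L))[seq_along(names_i)]
    expanded <- unique(unlist(lapply(names_i, function(nm)
      setdiff(expand_implicit_stereo(nm, stereo_table), names_i))))
    all_names <- c(names_i, expanded)
    all_prov <- c(prov, rep("expanded", length(expanded)))
    keys <- normalize_name(all_names)
    ok <- nzchar(keys)
    if (!any(ok)) {
      if (length(all_names)) {
        unusable <- c(unusable,
                      paste0(compounds$source[i], ":", compounds$compound_id[i]))
      }
      next
    }
    rows[[i]] <- data.frame(key = keys[ok],
                            source = compounds$source[i],
                            compound_id = compounds$compound_id[i],
                            provenance = all_prov[ok],
                            stringsAsFactors = FALSE)
  }
  if (length(unusable)) {
    message("name index: ", length(unusable),
            " compound(s) with no usable name: ",
            paste(unusable, collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(key = character(0), source = character(0),
                      compound_id = character(0), provenance = character(0),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}
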