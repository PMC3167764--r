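# Layer prefixes in canonical InChI order (after the formula layer).
.INCHI_LAYER_ORDER <- c("c", "h", "q", "p", "b", "t", "m", "s", "i", "f", "r")

# Layers retained in the reduced structure key: formula, connectivity,
# hydrogens, and the stereo layers. Charge (/q), protonation (/p) and
# isotope (/i) layers are dropped so that e.g. acetic acid and the acetate
# ion reduce to the same key.
.DEFAULT_KEPT_LAYERS <- c("c", "h", "b", "t", "m", "s")

#' Decompose an InChI string into its layers
#'
#' Splits a (standard) InChI string into its version prefix, formula layer
#' and the letter-keyed optional layers (`/c`, `/h`, `/q`, `/p`, `/b`, `/t`,
#' `/m`, `/s`, `/i`, ...). The decomposition is lossless: pasting the pieces
#' back together in their original order reproduces the input.
#'
#' @param inchi A single InChI string, starting with `"InChI="`.
#' @return An object of class `inchi_layers`: a list with elements
#'   `version` (e.g. `"1S"`), `formula` (the formula layer; may be `""` for
#'   the standard proton InChI `"InChI=1S/p+1"`), and `layers`, a named
#'   character vector of layer payloads keyed by layer letter.
#' @examples
#' parse_inchi("InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)/p-1")
#' @export
parse_inchi <- function(inchi) {
  stopifnot(is.character(inchi), length(inchi) == 1L, !is.na(inchi))
  if (!startsWith(inchi, "InChI=")) {
    stop("not an InChI string (missing 'InChI=' prefix): ", inchi)
  }
  body <- substring(inchi, nchar("InChI=") + 1L)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    stop("InChI has no formula layer: ", inchi)
  }
  version <- parts[1]
  rest <- parts[-1]
  # A recognized layer is a single letter from the canonical set followed by
  # its payload. The first segment is the formula unless it is itself a
  # recognized layer (the standard proton InChI "InChI=1S/p+1" has an empty
  # formula layer).
  is_layer <- grepl(sprintf("^[%s][0-9+.,;*?()-]",
                            paste(.INCHI_LAYER_ORDER, collapse = "")),
                    rest)
  if (is_layer[1]) {
    formula <- ""
  } else {
    formula <- rest[1]
    rest <- rest[-1]
    is_layer <- is_layer[-1]
  }
  if (formula == "" && length(rest) == 0L) {
    stop("InChI has an empty formula layer and no other layers: ", inchi)
  }
  layers <- character(0)
  if (length(rest)) {
    keys <- substring(rest, 1L, 1L)
    payloads <- substring(rest, 2L)
    layers <- stats::setNames(payloads, keys)
  }
  structure(list(version = version, formula = formula, layers = layers),
            class = "inchi_layers")
}

#' Reassemble parsed layers into the original InChI string
#' @param layers An `inchi_layers` object from [parse_inchi()].
#' @return The InChI string.
#' @export
assemble_inchi <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  segs <- c(layers$version,
            if (nzchar(layers$formula)) layers$formula,
            if (length(layers$layers))
              paste0(names(layers$layers), unname(layers$layers)))
  paste0("InChI=", paste(segs, collapse = "/"))
}

#' Reduce an InChI to an ionisation-invariant structure key
#'
#' Drops the version prefix and the layers that depend on the ionisation
#' state (charge `/q`, protonation `/p`) as well as the isotope layer `/i`,
#' keeping formula, connectivity (`/c`), hydrogen (`/h`) and stereo
#' (`/b`, `/t`, `/m`, `/s`) layers. Protonation variants of one parent
#' compound (acetic acid / acetate) therefore reduce to the same key.
#'
#' Multi-component InChIs (salts, `.`-separated formulas with `;`-separated
#' layer payloads) are reduced per component and the per-component keys are
#' sorted before joining, so the key does not depend on component order.
#'
#' @param x An `inchi_layers` object or an InChI string.
#' @param kept_layers Layer letters to retain (default `c,h,b,t,m,s`).
#' @return A single string: the reduced structure key, e.g.
#'   `"C2H4O2/c1-2(3)4/h1H3,(H,3,4)"`. An empty string when the InChI
#'   carries no retained structural information (e.g. the bare proton).
#' @examples
#' reduce_inchi("InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)/p-1")
#' @export
reduce_inchi <- function(x, kept_layers = .DEFAULT_KEPT_LAYERS) {
  if (is.character(x)) x <- parse_inchi(x)
  stopifnot(inherits(x, "inchi_layers"))
  keep <- x$layers[names(x$layers) %in% kept_layers]
  # canonical order
  keep <- keep[order(match(names(keep), .INCHI_LAYER_ORDER))]
  if (!nzchar(x$formula)) return("")
  components <- .split_components(x$formula, keep)
  if (length(components) > 1L) {
    comp_keys <- vapply(components, .assemble_key, character(1))
    return(paste(sort(comp_keys), collapse = "."))
  }
  .assemble_key(components[[1]])
}

# Split a multi-component formula and its per-component layer payloads.
# Returns a list of list(formula=, layers=named chr). Leading integer
# multipliers in the formula ("2H2O") and "n*" repeats in payloads are
# expanded so components align positionally.
.split_components <- function(formula, layers) {
  fparts <- strsplit(formula, ".", fixed = TRUE)[[1]]
  expanded <- character(0)
  for (fp in fparts) {
    m <- regmatches(fp, regexec("^([0-9]+)(.*)$", fp))[[1]]
    if (length(m) == 3 && nzchar(m[2])) {
      expanded <- c(expanded, rep(m[3], as.integer(m[2])))
    } else {
      expanded <- c(expanded, fp)
    }
  }
  n <- length(expanded)
  if (n == 1L) {
    return(list(list(formula = expanded, layers = layers)))
  }
  per_layer <- lapply(layers, function(payload) {
    segs <- strsplit(payload, ";", fixed = TRUE)[[1]]
    out <- character(0)
    for (s in segs) {
      m <- regmatches(s, regexec("^([0-9]+)\\*(.*)$", s))[[1]]
      if (length(m) == 3 && nzchar(m[2])) {
        out <- c(out, rep(m[3], as.integer(m[2])))
      } else {
        out <- c(out, s)
      }
    }
    length(out) <- n   # pad with NA for trailing empties
    out
  })
  lapply(seq_len(n), function(i) {
    li <- vapply(per_layer, function(v) {
      x <- v[i]
      if (is.na(x)) "" else x
    }, character(1))
    li <- li[nzchar(li)]
    list(formula = expanded[i], layers = li)
  })
}

.assemble_key <- function(component) {
  segs <- component$formula
  if (length(component$layers)) {
    segs <- c(segs, paste0(names(component$layers), unname(component$layers)))
  }
  paste(segs, collapse = "/")
}

#' Strip stereochemistry layers from a reduced structure key
#'
#' Removes the `/b`, `/t`, `/m`, `/s` layers from a reduced key, keeping only
#' formula, connectivity and hydrogen layers. Two keys that differ only in
#' stereo descriptors (e.g. beta-D-glucose vs. glucose with an undefined
#' anomeric centre) strip to the same string.
#'
#' @param key A reduced structure key from [reduce_inchi()].
#' @return The stereo-stripped key string.
#' @export
strip_stereo <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  if (!nzchar(key)) return("")
  segs <- strsplit(key, "/", fixed = TRUE)[[1]]
  letter <- substring(segs, 1L, 1L)
  keep <- c(TRUE, letter[-1] %in% c("c", "h"))
  paste(segs[keep], collapse = "/")
}

#' Count the stereo descriptors defined in a reduced key
#'
#' Used to pick the stereo-preferred representative of a compound class:
#' the member with the most defined stereocentres/double-bond descriptors
#' wins. Counts comma-separated entries in the `/b` and `/t` layers without
#' question marks (undefined centres), plus 1 for a defined `/m` layer.
#'
#' @param key A reduced structure key.
#' @return Integer count (0 for keys with no stereo layers).
#' @export
count_stereo_descriptors <- function(key) {
  if (is.na(key) || !nzchar(key)) return(0L)
  segs <- strsplit(key, "/", fixed = TRUE)[[1]]
  n <- 0L
  for (s in segs[-1]) {
    l <- substring(s, 1, 1)
    if (l %in% c("b", "t")) {
      items <- strsplit(substring(s, 2), ",", fixed = TRUE)[[1]]
      n <- n + sum(!grepl("?", items, fixed = TRUE))
    } else if (l == "m") {
      n <- n + sum(strsplit(substring(s, 2), "")[[1]] %in% c("0", "1"))
    }
  }
  n
}

#' Does a reduced key carry any stereo layer?
#' @param key A reduced structure key.
#' @return Logical.
#' @export
has_stereo_layers <- function(key) {
  if (is.na(key) || !nzchar(key)) return(FALSE)
  segs <- strsplit(key, "/", fixed = TRUE)[[1]]
  any(substring(segs[-1], 1, 1) %in% c("b", "t", "m", "s"))
}

#' Parse a Hill-order molecular formula into element counts
#'
#' Handles `.`-separated multi-component formulas with optional leading
#' integer multipliers (`"2H3PO4"`, `"C6H12O6.Na"`). Repeating-unit or
#' otherwise unparsable notation (parentheses, `*`, `n` subscripts) sets
#' `has_unknown` and empties the counts, signalling that no element tally
#' is available for balance checking.
#'
#' @param formula A formula-layer string.
#' @return An object of class `element_counts`: list with `counts`
#'   (named integer vector, element symbol -> total count over all
#'   components) and `has_unknown` (logical).
#' @examples
#' formula_to_counts("C6H12O6.Na")
#' @export
formula_to_counts <- function(formula) {
  bad <- function() structure(list(counts = integer(0), has_unknown = TRUE),
                              class = "element_counts")
  if (is.na(formula) || !nzchar(formula)) return(bad())
  total <- integer(0)
  for (comp in strsplit(formula, ".", fixed = TRUE)[[1]]) {
    m <- regmatches(comp, regexec("^([0-9]*)([A-Za-z0-9]*)$", comp))[[1]]
    if (length(m) != 3 || !nzchar(m[3])) return(bad())
    mult <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    body <- m[3]
    toks <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)
    pieces <- regmatches(body, toks)[[1]]
    if (sum(attr(toks[[1]], "match.length")) != nchar(body)) return(bad())
    for (p in pieces) {
      mm <- regmatches(p, regexec("^([A-Z][a-z]?)([0-9]*)$", p))[[1]]
      el <- mm[2]
      cnt <- if (nzchar(mm[3])) as.integer(mm[3]) else 1L
      total[el] <- (if (el %in% names(total)) total[[el]] else 0L) + mult * cnt
    }
  }
  structure(list(counts = total, has_unknown = FALSE), class = "element_counts")
}

#' Render element counts as a Hill-order formula string
#'
#' Inverse-style rendering used for the Missing Substrate / Missing Product
#' QC columns: carbon first, then hydrogen, then the remaining elements
#' alphabetically; count 1 is omitted.
#'
#' @param counts Named integer vector (element -> count) or an
#'   `element_counts` object.
#' @return A formula string; `""` for an empty/zero tally.
#' @export
counts_to_formula <- function(counts) {
  if (inherits(counts, "element_counts")) counts <- counts$counts
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    sort(els)
  }
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

#' Convert a Molfile to a standard InChI via an external converter
#'
#' Adapter around a command-line structure converter (OpenBabel's `obabel`
#' by default). When no converter is available the function signals a
#' capability error; the pipeline then runs on the InChI strings supplied
#' in the dumps.
#'
#' @param molfile Molfile (V2000) text.
#' @param converter Path to the converter executable; found on `PATH` by
#'   default.
#' @return A standard InChI string.
#' @export
molfile_to_inchi <- function(molfile, converter = Sys.which("obabel")) {
  if (is.na(converter) || !nzchar(converter)) {
    stop("no Molfile->InChI converter available (obabel not found); ",
         "supply InChI strings in the dump instead", call. = FALSE)
  }
  if (is.na(molfile) || !nzchar(trimws(molfile))) {
    stop("empty Molfile")
  }
  tmp <- tempfile(fileext = ".mol")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(molfile, tmp)
  out <- suppressWarnings(
    system2(converter, c(tmp, "-oinchi"), stdout = TRUE, stderr = FALSE))
  out <- out[startsWith(out, "InChI=")]
  if (!length(out)) stop("converter produced no InChI for the Molfile")
  out[[1]]
}
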