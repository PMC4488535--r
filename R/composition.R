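# Glycan compositions: integer counts over the five monosaccharide kinds
# (Hex, HexNAc, dHex, Neu5Ac, Neu5Gc). The composition is the universal key
# joining masses, peak annotations and structural classifications.

#' Glycan composition
#'
#' Integer counts of the five supported monosaccharide kinds. Equality is by
#' counts only; the canonical text form is `"(Hex)5(HexNAc)2"` with kinds in
#' the fixed order Hex, HexNAc, dHex, Neu5Ac, Neu5Gc and zero counts
#' omitted.
#'
#' @param hex,hexnac,dhex,neu5ac,neu5gc Non-negative integer counts.
#' @return An object of class `glycan_composition`: a named integer vector
#'   of length 5.
#' @examples
#' glycan_composition(hex = 5, hexnac = 2)
#' @export
glycan_composition <- function(hex = 0L, hexnac = 0L, dhex = 0L,
                               neu5ac = 0L, neu5gc = 0L) {
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex,
              neu5ac = neu5ac, neu5gc = neu5gc)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("composition counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(counts), names = .KINDS, class = "glycan_composition")
}

#' Coerce to a glycan composition
#'
#' Accepts an existing composition, a named numeric vector of counts, or a
#' composition string (see [parse_composition()]).
#'
#' @param x Object to coerce.
#' @return A `glycan_composition`.
#' @export
as_glycan_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  if (is.numeric(x) && !is.null(names(x))) {
    unknown <- setdiff(names(x), .KINDS)
    if (length(unknown)) {
      stop("unknown residue kind(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    args <- as.list(x[intersect(.KINDS, names(x))])
    return(do.call(glycan_composition, args))
  }
  stop("cannot interpret object as a glycan composition", call. = FALSE)
}

#' Parse a composition string
#'
#' Understands the parenthesized dialect `"(Hex)5(HexNAc)2"` and the compact
#' dialect `"Hex5HexNAc2"`. Residue tokens are `Hex`, `HexNAc`, `dHex`,
#' `Neu5Ac`, `Neu5Gc`. [format_composition()] is the exact inverse for any
#' valid composition.
#'
#' @param text Composition string.
#' @return A `glycan_composition`.
#' @examples
#' parse_composition("(Hex)2(HexNAc)2(Neu5Ac)1")
#' parse_composition("Hex5HexNAc2")
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty composition string", call. = FALSE)
  # longest tokens first so "HexNAc" is not eaten as "Hex" + "NAc"
  tok <- "(Neu5Gc|Neu5Ac|HexNAc|dHex|Hex)"
  pat <- if (startsWith(text, "(")) {
    paste0("\\(", tok, "\\)([0-9]+)")
  } else {
    paste0(tok, "([0-9]+)")
  }
  m <- gregexpr(pat, text)[[1]]
  parts <- regmatches(text, gregexpr(pat, text))[[1]]
  if (length(parts) == 0L || sum(nchar(parts)) != nchar(text)) {
    # locate the first offending stretch for the error message
    consumed <- if (length(parts)) {
      max(m + attr(m, "match.length")) - 1L
    } else 0L
    stop("cannot parse composition near: \"",
         substr(text, consumed + 1L, nchar(text)), "\"", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(.KINDS)), .KINDS)
  for (p in parts) {
    g <- regmatches(p, regexec(pat, p))[[1]]
    kind <- names(.KIND_TOKEN)[match(g[2], .KIND_TOKEN)]
    counts[kind] <- counts[kind] + as.integer(g[3])
  }
  do.call(glycan_composition, as.list(counts))
}

#' Format a composition canonically
#'
#' @param comp A `glycan_composition` (or coercible).
#' @return Canonical string such as `"(Hex)5(HexNAc)2"`; zero counts are
#'   omitted, kind order is fixed.
#' @examples
#' format_composition(glycan_composition(hex = 5, hexnac = 2))
#' @export
format_composition <- function(comp) {
  comp <- as_glycan_composition(comp)
  nz <- which(comp > 0L)
  if (!length(nz)) return("(empty)")
  paste0("(", .KIND_TOKEN[.KINDS[nz]], ")", comp[nz], collapse = "")
}

#' @export
format.glycan_composition <- function(x, ...) format_composition(x)

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan_composition> ", format_composition(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.glycan_composition` <- function(e1, e2) {
  all(unclass(as_glycan_composition(e1)) == unclass(as_glycan_composition(e2)))
}

#' Total residue count of a composition
#' @param comp A `glycan_composition` (or coercible).
#' @return Integer total residue count.
#' @export
residue_count <- function(comp) {
  sum(as_glycan_composition(comp))
}

#' Sialic-acid residue count (Neu5Ac + Neu5Gc)
#' @param comp A `glycan_composition` (or coercible).
#' @return Integer count.
#' @export
sialic_count <- function(comp) {
  comp <- as_glycan_composition(comp)
  comp[["neu5ac"]] + comp[["neu5gc"]]
}
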