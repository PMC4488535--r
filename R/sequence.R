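# Condensed-IUPAC sequence grammar for glycan structures.
#
# A sequence is written non-reducing end first, e.g. "Galb1-4GlcNAcb1-3
# Galb1-4Glc". Residue tokens: Gal, Glc, GlcNAc, GalNAc, Man, Fuc, Neu5Ac,
# Neu5Gc; each non-reducing residue carries an anomer+linkage suffix
# ("b1-4", "a2-3"); branches are parenthesized groups attached to the
# residue that follows them. The reducing-end residue has no suffix.

# monosaccharide token -> composition kind
.RESIDUE_KIND <- c(
  Gal = "hex", Glc = "hex", Man = "hex",
  GlcNAc = "hexnac", GalNAc = "hexnac",
  Fuc = "dhex",
  Neu5Ac = "neu5ac", Neu5Gc = "neu5gc"
)

# A parsed structure is a tree of nodes:
#   list(residue = "Gal", linkage = "b1-4" or NA for the root,
#        children = list(<node>, ...))
# The root is the reducing-end residue (where the label sits).

.tokenize_sequence <- function(text) {
  # returns list of items: list(type = "res", residue, linkage) or
  # list(type = "branch", text = <subsequence>)
  items <- list()
  i <- 1L
  n <- nchar(text)
  res_pat <- "^(Neu5Gc|Neu5Ac|GlcNAc|GalNAc|Gal|Glc|Man|Fuc)(([ab])([12])-([0-9]))?"
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "(") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        cj <- substr(text, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("unbalanced parentheses in sequence: ", text,
                            call. = FALSE)
      items[[length(items) + 1L]] <-
        list(type = "branch", text = substr(text, i + 1L, j - 2L))
      i <- j
    } else {
      rest <- substr(text, i, n)
      m <- regexec(res_pat, rest)[[1]]
      if (m[1] == -1L) {
        stop("cannot parse sequence near: \"", rest, "\"", call. = FALSE)
      }
      g <- regmatches(rest, regexec(res_pat, rest))[[1]]
      linkage <- if (nzchar(g[3])) paste0(g[4], g[5], "-", g[6]) else NA_character_
      items[[length(items) + 1L]] <-
        list(type = "res", residue = g[2], linkage = linkage)
      i <- i + nchar(g[1])
    }
  }
  items
}

#' Parse a condensed glycan sequence into a tree
#'
#' @param text Condensed sequence, non-reducing end first, branches in
#'   parentheses attached to the following residue (e.g.
#'   `"GalNAcb1-4(Neu5Aca2-3)Galb1-4Glc"` for GM2).
#' @return The root node (reducing-end residue) of the structure tree; each
#'   node is a list with `residue`, `linkage` (NA at the root) and
#'   `children`.
#' @examples
#' tree <- parse_glycan_sequence("Galb1-4GlcNAcb1-3Galb1-4Glc")
#' tree$residue  # "Glc", the reducing end
#' @export
parse_glycan_sequence <- function(text) {
  root <- .parse_sequence_impl(text)
  if (!is.na(root$linkage)) {
    stop("reducing-end residue must not carry a linkage suffix: ", text,
         call. = FALSE)
  }
  root
}

# shared by the top-level parser and branch recursion; a branch's final
# residue keeps its linkage (it is the branch's attachment bond)
.parse_sequence_impl <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty glycan sequence", call. = FALSE)
  items <- .tokenize_sequence(text)
  prev <- NULL
  pending <- list()
  for (it in items) {
    if (it$type == "branch") {
      pending[[length(pending) + 1L]] <- .parse_sequence_impl(it$text)
    } else {
      node <- list(residue = it$residue, linkage = it$linkage,
                   children = list())
      if (!is.null(prev)) node$children <- c(node$children, list(prev))
      if (length(pending)) {
        node$children <- c(node$children, pending)
        pending <- list()
      }
      prev <- node
    }
  }
  if (length(pending)) {
    stop("dangling branch with no following residue in: ", text,
         call. = FALSE)
  }
  if (is.null(prev)) stop("no residues in sequence: ", text, call. = FALSE)
  prev
}

.tree_residues <- function(node) {
  out <- list(node)
  for (ch in node$children) out <- c(out, .tree_residues(ch))
  out
}

#' Composition tally of a structure tree or sequence
#'
#' @param x A tree from [parse_glycan_sequence()] or a sequence string.
#' @return A [glycan_composition()].
#' @export
sequence_composition <- function(x) {
  if (is.character(x)) x <- parse_glycan_sequence(x)
  kinds <- vapply(.tree_residues(x), function(nd) .RESIDUE_KIND[[nd$residue]],
                  character(1))
  counts <- table(factor(kinds, levels = .KINDS))
  do.call(glycan_composition, as.list(as.integer(counts)) |>
            stats::setNames(.KINDS))
}

#' Non-reducing terminal residues of a structure
#'
#' Leaves of the structure tree other than the reducing-end root (a
#' single-residue structure has no glycosidic termini).
#'
#' @param x A tree from [parse_glycan_sequence()] or a sequence string.
#' @return Data frame with columns `residue` and `linkage`.
#' @examples
#' terminal_residues("Galb1-4GlcNAcb1-3Galb1-4Glc")  # Gal b1-4
#' @export
terminal_residues <- function(x) {
  if (is.character(x)) x <- parse_glycan_sequence(x)
  leaves <- Filter(function(nd) length(nd$children) == 0L, .tree_residues(x))
  leaves <- Filter(function(nd) !is.na(nd$linkage), leaves)
  data.frame(
    residue = vapply(leaves, `[[`, character(1), "residue"),
    linkage = vapply(leaves, `[[`, character(1), "linkage"),
    stringsAsFactors = FALSE
  )
}
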