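# Structure records and the in-package structure database. Records pair a
# composition with a condensed sequence (with linkages) and a series/class
# label, emulating the kind of entry one extracts from SphinGOMAP or
# UniCarbKB; the database powers isomer-aware annotation and series calls.

#' Glycan structure record
#'
#' A database entry for one defined glycan structure. The composition and
#' the non-reducing terminal residues are derived from the sequence, so they
#' are always mutually consistent.
#'
#' @param name Trivial name (e.g. `"GM3"`, `"Gb4"`, `"nLc4"`, `"A2"`).
#' @param glycome One of `"N"`, `"O"`, `"GSL"`.
#' @param series_or_class Series/class tag: `Gg`, `Gb`, `nLc`, `Lac` for
#'   GSL-glycans; `PM`, `HM`, `CH` for N-glycans; `Tn`, `core1`, `core2`,
#'   `extended-core1` for O-glycans; `other` otherwise.
#' @param sequence Condensed sequence with linkages, see
#'   [parse_glycan_sequence()].
#' @return An object of class `glycan_record` with fields `name`, `glycome`,
#'   `series_or_class`, `sequence`, `composition` and `terminal_residues`.
#' @examples
#' glycan_record("nLc4", "GSL", "nLc", "Galb1-4GlcNAcb1-3Galb1-4Glc")
#' @export
glycan_record <- function(name, glycome, series_or_class, sequence) {
  glycome <- match.arg(glycome, c("N", "O", "GSL"))
  tree <- parse_glycan_sequence(sequence)
  structure(
    list(
      name = name,
      glycome = glycome,
      series_or_class = series_or_class,
      sequence = gsub("[[:space:]]", "", sequence),
      composition = sequence_composition(tree),
      terminal_residues = terminal_residues(tree)
    ),
    class = "glycan_record"
  )
}

#' @export
print.glycan_record <- function(x, ...) {
  cat(sprintf("<glycan_record> %s [%s/%s] %s  %s\n",
              x$name, x$glycome, x$series_or_class,
              format_composition(x$composition), x$sequence))
  invisible(x)
}

#' Structure database
#'
#' A searchable collection of [glycan_record()]s indexed by composition and
#' by name.
#'
#' @param records List of `glycan_record` objects.
#' @return An object of class `structure_db`.
#' @export
structure_db <- function(records) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "glycan_record")))
  names(records) <- vapply(records, `[[`, character(1), "name")
  if (anyDuplicated(names(records))) {
    stop("duplicate record names in structure database", call. = FALSE)
  }
  comp_keys <- vapply(records, function(r) format_composition(r$composition),
                      character(1))
  structure(
    list(records = records,
         comp_index = split(names(records), comp_keys)),
    class = "structure_db"
  )
}

#' @export
print.structure_db <- function(x, ...) {
  gl <- table(vapply(x$records, `[[`, character(1), "glycome"))
  cat(sprintf("<structure_db> %d records (%s)\n", length(x$records),
              paste(names(gl), gl, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' @export
length.structure_db <- function(x) length(x$records)

#' Look up structure records
#'
#' @param db A [structure_db()].
#' @param composition Optional composition (object or string): return all
#'   isomeric records with that composition.
#' @param name Optional record name.
#' @param glycome Optional glycome filter (`"N"`, `"O"`, `"GSL"`).
#' @return List of matching `glycan_record`s (possibly empty).
#' @examples
#' db <- default_structure_db()
#' db_lookup(db, composition = "(Hex)3(HexNAc)1", glycome = "GSL")
#' @export
db_lookup <- function(db, composition = NULL, name = NULL, glycome = NULL) {
  stopifnot(inherits(db, "structure_db"))
  hits <- db$records
  if (!is.null(name)) {
    hits <- hits[intersect(names(hits), name)]
  }
  if (!is.null(composition)) {
    key <- format_composition(as_glycan_composition(composition))
    hits <- hits[intersect(names(hits), db$comp_index[[key]])]
  }
  if (!is.null(glycome)) {
    hits <- Filter(function(r) r$glycome %in% glycome, hits)
  }
  unname(hits)
}

#' Write a structure database to JSON
#'
#' Serializes records as a JSON array with fields `name`, `glycome`,
#' `series_or_class`, `composition` (object of counts), `sequence` and
#' `terminal_residues`.
#'
#' @param db A [structure_db()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_db <- function(db, path) {
  stopifnot(inherits(db, "structure_db"))
  recs <- lapply(unname(db$records), function(r) {
    comp <- as.list(unclass(r$composition))
    list(name = r$name, glycome = r$glycome,
         series_or_class = r$series_or_class,
         composition = comp[vapply(comp, `>`, logical(1), 0L)],
         sequence = r$sequence,
         terminal_residues = r$terminal_residues)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a structure database from JSON
#'
#' Compositions and terminal residues are re-derived from each record's
#' sequence and checked against the stored values, so an inconsistent file
#' is rejected.
#'
#' @param path JSON file written by [write_structure_db()] (or compatible).
#' @return A [structure_db()].
#' @export
read_structure_db <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- lapply(raw, function(r) {
    rec <- glycan_record(r$name, r$glycome, r$series_or_class, r$sequence)
    stored <- as_glycan_composition(unlist(r$composition))
    if (!isTRUE(rec$composition == stored)) {
      stop("record ", r$name, ": stored composition ",
           format_composition(stored), " does not match sequence tally ",
           format_composition(rec$composition), call. = FALSE)
    }
    rec
  })
  structure_db(records)
}

# name | glycome | series_or_class | condensed sequence
.DEFAULT_RECORDS <- matrix(byrow = TRUE, ncol = 4L, c(
  # --- GSL glycans (reducing-end Glc; ceramide is removed upstream) ------
  "LacCer",        "GSL", "Lac", "Galb1-4Glc",
  "GM3",           "GSL", "Gg",  "Neu5Aca2-3Galb1-4Glc",
  "GM2",           "GSL", "Gg",  "GalNAcb1-4(Neu5Aca2-3)Galb1-4Glc",
  "GM1",           "GSL", "Gg",  "Galb1-3GalNAcb1-4(Neu5Aca2-3)Galb1-4Glc",
  "GM1b",          "GSL", "Gg",  "Neu5Aca2-3Galb1-3GalNAcb1-4Galb1-4Glc",
  "GD3",           "GSL", "Gg",  "Neu5Aca2-8Neu5Aca2-3Galb1-4Glc",
  "GD2",           "GSL", "Gg",  "GalNAcb1-4(Neu5Aca2-8Neu5Aca2-3)Galb1-4Glc",
  "GD1a",          "GSL", "Gg",  "Neu5Aca2-3Galb1-3GalNAcb1-4(Neu5Aca2-3)Galb1-4Glc",
  "GD1b",          "GSL", "Gg",  "Galb1-3GalNAcb1-4(Neu5Aca2-8Neu5Aca2-3)Galb1-4Glc",
  "GT1b",          "GSL", "Gg",  "Neu5Aca2-3Galb1-3GalNAcb1-4(Neu5Aca2-8Neu5Aca2-3)Galb1-4Glc",
  "Neu5Gc-GM3",    "GSL", "Gg",  "Neu5Gca2-3Galb1-4Glc",
  "Neu5Gc-GM2",    "GSL", "Gg",  "GalNAcb1-4(Neu5Gca2-3)Galb1-4Glc",
  "Fuc-GM1",       "GSL", "Gg",  "Fuca1-2Galb1-3GalNAcb1-4(Neu5Aca2-3)Galb1-4Glc",
  "Gb3",           "GSL", "Gb",  "Gala1-4Galb1-4Glc",
  "Gb4",           "GSL", "Gb",  "GalNAcb1-3Gala1-4Galb1-4Glc",
  "SSEA-3",        "GSL", "Gb",  "Galb1-3GalNAcb1-3Gala1-4Galb1-4Glc",
  "SSEA-4",        "GSL", "Gb",  "Neu5Aca2-3Galb1-3GalNAcb1-3Gala1-4Galb1-4Glc",
  "Globo-H",       "GSL", "Gb",  "Fuca1-2Galb1-3GalNAcb1-3Gala1-4Galb1-4Glc",
  "Gb-Hex5HexNAc2","GSL", "Gb",  "Galb1-4GlcNAcb1-6(Galb1-3)GalNAcb1-3Gala1-4Galb1-4Glc",
  "nLc-Hex5HexNAc2","GSL","nLc", "Gala1-3Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Galb1-4Glc",
  "Lc3",           "GSL", "nLc", "GlcNAcb1-3Galb1-4Glc",
  "nLc4",          "GSL", "nLc", "Galb1-4GlcNAcb1-3Galb1-4Glc",
  "nLc5",          "GSL", "nLc", "GlcNAcb1-3Galb1-4GlcNAcb1-3Galb1-4Glc",
  "nLc6",          "GSL", "nLc", "Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Galb1-4Glc",
  "sialyl-nLc4",   "GSL", "nLc", "Neu5Aca2-3Galb1-4GlcNAcb1-3Galb1-4Glc",
  "sialyl-Lex",    "GSL", "nLc", "Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAcb1-3Galb1-4Glc",
  "Lex",           "GSL", "nLc", "Galb1-4(Fuca1-3)GlcNAcb1-3Galb1-4Glc",
  "H-nLc4",        "GSL", "nLc", "Fuca1-2Galb1-4GlcNAcb1-3Galb1-4Glc",
  # --- N-glycans (reducing-end GlcNAc of the chitobiose core) ------------
  "Man1",   "N", "PM", "Manb1-4GlcNAcb1-4GlcNAc",
  "Man2",   "N", "PM", "Mana1-6Manb1-4GlcNAcb1-4GlcNAc",
  "Man3",   "N", "PM", "Mana1-3(Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "Man3F",  "N", "PM", "Mana1-3(Mana1-6)Manb1-4GlcNAcb1-4(Fuca1-6)GlcNAc",
  "Man4",   "N", "HM", "Mana1-2Mana1-3(Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "Man5",   "N", "HM", "Mana1-6(Mana1-3)Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAc",
  "Man6",   "N", "HM", "Mana1-2Mana1-3(Mana1-6(Mana1-3)Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "Man7",   "N", "HM", "Mana1-2Mana1-2Mana1-3(Mana1-6(Mana1-3)Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "Man8",   "N", "HM", "Mana1-2Mana1-2Mana1-3(Mana1-2Mana1-6(Mana1-3)Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "Man9",   "N", "HM", "Mana1-2Mana1-2Mana1-3(Mana1-2Mana1-6(Mana1-2Mana1-3)Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "A2",     "N", "CH", "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "A1",     "N", "CH", "Galb1-4GlcNAcb1-2Mana1-3(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "NA2",    "N", "CH", "Galb1-4GlcNAcb1-2Mana1-3(Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "A2F",    "N", "CH", "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4(Fuca1-6)GlcNAc",
  "A1F",    "N", "CH", "Galb1-4GlcNAcb1-2Mana1-3(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4(Fuca1-6)GlcNAc",
  "NA2F",   "N", "CH", "Galb1-4GlcNAcb1-2Mana1-3(Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4(Fuca1-6)GlcNAc",
  "NA2B",   "N", "CH", "Galb1-4GlcNAcb1-2Mana1-3(Galb1-4GlcNAcb1-2Mana1-6)(GlcNAcb1-4)Manb1-4GlcNAcb1-4GlcNAc",
  "NA4",    "N", "CH", "Galb1-4GlcNAcb1-2(Galb1-4GlcNAcb1-4)Mana1-3(Galb1-4GlcNAcb1-2(Galb1-4GlcNAcb1-6)Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
  "A2GN1",  "N", "CH", "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAc",
  # --- O-glycans (reducing-end GalNAc) -----------------------------------
  "Tn",              "O", "Tn",    "GalNAc",
  "sialyl-Tn",       "O", "Tn",    "Neu5Aca2-6GalNAc",
  "T",               "O", "core1", "Galb1-3GalNAc",
  "sialyl-T",        "O", "core1", "Neu5Aca2-3Galb1-3GalNAc",
  "disialyl-T",      "O", "core1", "Neu5Aca2-3Galb1-3(Neu5Aca2-6)GalNAc",
  "Neu5Gc-sialyl-T", "O", "core1", "Neu5Gca2-3Galb1-3GalNAc",
  "core2",           "O", "core2", "Galb1-3(GlcNAcb1-6)GalNAc",
  "core2-LacNAc",    "O", "core2", "Galb1-3(Galb1-4GlcNAcb1-6)GalNAc",
  "extended-core1",  "O", "extended-core1", "Galb1-4GlcNAcb1-3Galb1-3GalNAc",
  "sialyl-core2",    "O", "core2", "Neu5Aca2-3Galb1-3(Galb1-4GlcNAcb1-6)GalNAc",
  "sialyl-extended-core1", "O", "extended-core1",
      "Neu5Aca2-3Galb1-4GlcNAcb1-3Galb1-3GalNAc"
))

#' Default structure database
#'
#' The database shipped with the package: ganglio-, globo- and
#' (neo)lacto-series GSL glycans (including the two isomeric
#' (Hex)5(HexNAc)2 species resolvable by their signature Y-ions),
#' pauci-mannose, high-mannose and complex N-glycans (including the A2GN1
#' internal standard), and mucin-core O-glycans. The same content is shipped
#' as JSON under `extdata/structure_db.json`.
#'
#' @return A [structure_db()] with 50+ records.
#' @examples
#' default_structure_db()
#' @export
default_structure_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      recs <- apply(.DEFAULT_RECORDS, 1L, function(r) {
        glycan_record(r[1], r[2], r[3], r[4])
      })
      db <<- structure_db(recs)
    }
    db
  }
})
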