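# Structural taxonomies for the three glycomes.
#
# N-glycans: pauci-mannose (PM) / high-mannose (HM) / complex-hybrid (CH),
# with antennarity and bisecting / tetra-antennary composition signatures.
# GSL glycans: lacto root, ganglio (Gg), globo (Gb), (neo)lacto (nLc)
# series, with explicit "Gg-or-nLc" / "Gb-or-nLc" ambiguity classes that
# are resolved only by MS2 or digestion evidence.
# O-glycans: mucin cores (Tn, core 1, core 2, extended core 1), where the
# (Hex)2(HexNAc)2 backbone is ambiguous without digestion evidence.

#' N-glycan taxonomy parameters
#'
#' Boundaries of the PM/HM split and the peripheral composition signatures.
#' The invariant trimannosyl-chitobiose core (Hex3HexNAc2) is removed
#' before signature testing; the bisecting signature is an exact peripheral
#' match, the tetra-antennary signature a componentwise lower bound. These
#' are conventions, not measurements, and are exposed for overriding.
#'
#' @param pm_max_hex Maximum hexoses for pauci-mannose (default 3).
#' @param hm_hex_range Hexose range for high-mannose (default 4 to 12).
#' @param bisect_peripheries List of peripheral `(hex, hexnac)` pairs that
#'   signal a bisected glycan (defaults: Hex2HexNAc3 and Hex3HexNAc4).
#' @param tetra_periphery Minimum peripheral `(hex, hexnac)` for the
#'   tetra-antennary signature (default Hex4HexNAc4).
#' @return An object of class `n_taxonomy`.
#' @export
n_taxonomy <- function(pm_max_hex = 3L,
                       hm_hex_range = c(4L, 12L),
                       bisect_peripheries = list(c(hex = 2L, hexnac = 3L),
                                                 c(hex = 3L, hexnac = 4L)),
                       tetra_periphery = c(hex = 4L, hexnac = 4L)) {
  structure(list(pm_max_hex = pm_max_hex, hm_hex_range = hm_hex_range,
                 bisect_peripheries = bisect_peripheries,
                 tetra_periphery = tetra_periphery),
            class = "n_taxonomy")
}

#' Classify an N-glycan composition
#'
#' Families (a partition — exactly one per composition):
#' * `PM` (pauci-mannose): hexnac = 2, hex <= 3, dhex <= 1, no sialics.
#' * `HM` (high-mannose): hexnac = 2, hex 4-12, no dhex, no sialics.
#' * `CH` (complex/hybrid): everything else.
#'
#' For CH glycans, antennarity is `hexnac - 2` clamped to 1-4 (a bisecting
#' GlcNAc inflates this count; the bisect flag is reported alongside so
#' consumers can discount it). The bisect signature fires when the
#' periphery — the composition minus the Hex3HexNAc2 core, ignoring fucose
#' and sialics — equals exactly Hex2HexNAc3 or Hex3HexNAc4; the
#' tetra-antennary signature when the periphery is componentwise at least
#' Hex4HexNAc4 and the bisect signature did not fire.
#'
#' @param comp A composition with hexnac >= 2 (the chitobiose core is
#'   assumed by the caller).
#' @param taxonomy An [n_taxonomy()].
#' @return A list of class `n_glycan_class` with fields `family`,
#'   `acidity`, `antennae`, `bisect_signature`, `tetraantennary_signature`,
#'   `fucose_count`, `sialic_count`, `neu5gc_count`.
#' @examples
#' classify_n("(Hex)5(HexNAc)2")$family  # "HM" (Man5)
#' classify_n("(Hex)5(HexNAc)5")$bisect_signature  # TRUE
#' @export
classify_n <- function(comp, taxonomy = n_taxonomy()) {
  comp <- as_glycan_composition(comp)
  if (comp[["hexnac"]] < 2L) {
    stop("not an N-glycan: fewer than 2 HexNAc residues (chitobiose core)",
         call. = FALSE)
  }
  sia <- sialic_count(comp)
  family <- if (comp[["hexnac"]] == 2L && sia == 0L &&
                comp[["hex"]] <= taxonomy$pm_max_hex &&
                comp[["dhex"]] <= 1L) {
    "PM"
  } else if (comp[["hexnac"]] == 2L && sia == 0L && comp[["dhex"]] == 0L &&
             comp[["hex"]] >= taxonomy$hm_hex_range[1] &&
             comp[["hex"]] <= taxonomy$hm_hex_range[2]) {
    "HM"
  } else "CH"

  bisect <- FALSE
  tetra <- FALSE
  antennae <- NA_integer_
  if (family == "CH") {
    periph <- c(hex = max(0L, comp[["hex"]] - 3L),
                hexnac = max(0L, comp[["hexnac"]] - 2L))
    bisect <- any(vapply(taxonomy$bisect_peripheries, function(sig) {
      periph[["hex"]] == sig[["hex"]] && periph[["hexnac"]] == sig[["hexnac"]]
    }, logical(1)))
    tetra <- !bisect &&
      periph[["hex"]] >= taxonomy$tetra_periphery[["hex"]] &&
      periph[["hexnac"]] >= taxonomy$tetra_periphery[["hexnac"]]
    antennae <- min(max(comp[["hexnac"]] - 2L, 1L), 4L)
  }
  structure(
    list(family = family,
         acidity = if (sia >= 1L) "acidic" else "neutral",
         antennae = antennae,
         bisect_signature = bisect,
         tetraantennary_signature = tetra,
         fucose_count = comp[["dhex"]],
         sialic_count = sia,
         neu5gc_count = comp[["neu5gc"]]),
    class = "n_glycan_class"
  )
}

#' Classify a GSL glycan composition into its series
#'
#' Looks up all isomeric GSL records in the structure database. If every
#' hit belongs to one series the call is unique (`db_unique` evidence);
#' hits spanning ganglio and (neo)lacto yield `"Gg-or-nLc"`, globo and
#' (neo)lacto `"Gb-or-nLc"` — ambiguities that only MS2 signature ions or
#' exoglycosidase digestion can resolve. A bare Hex2 composition is the
#' lactosylceramide glycan (`"Lac"`). A composition absent from the
#' database is `"other"`.
#'
#' @param comp A composition.
#' @param db A [structure_db()].
#' @param evidence Optional resolution from [disambiguate_by_ms2()] or a
#'   digestion verdict: a list with `series` (`"Gg"`, `"Gb"` or `"nLc"`)
#'   and `source` (`"ms2"` or `"digestion"`).
#' @return A list of class `gsl_series_call` with fields `series`,
#'   `evidence`, `sialic_count`, `neu5gc_count`, `fucose_count`.
#' @examples
#' classify_gsl("(Hex)2")$series            # "Lac"
#' classify_gsl("(Hex)3(HexNAc)1")$series   # "Gb-or-nLc"
#' @export
classify_gsl <- function(comp, db = default_structure_db(), evidence = NULL) {
  comp <- as_glycan_composition(comp)
  sia <- sialic_count(comp)
  base <- list(sialic_count = sia, neu5gc_count = comp[["neu5gc"]],
               fucose_count = comp[["dhex"]])

  if (!is.null(evidence)) {
    stopifnot(is.list(evidence), evidence$series %in% c("Gg", "Gb", "nLc"),
              evidence$source %in% c("ms2", "digestion"))
    return(structure(c(list(series = evidence$series,
                            evidence = evidence$source), base),
                     class = "gsl_series_call"))
  }
  if (comp[["hex"]] == 2L && comp[["hexnac"]] == 0L && comp[["dhex"]] == 0L &&
      sia == 0L) {
    return(structure(c(list(series = "Lac", evidence = "db_unique"), base),
                     class = "gsl_series_call"))
  }
  hits <- db_lookup(db, composition = comp, glycome = "GSL")
  series_set <- sort(unique(vapply(hits, `[[`, character(1),
                                   "series_or_class")))
  call <- if (length(series_set) == 1L) {
    list(series = series_set, evidence = "db_unique")
  } else if (setequal(series_set, c("Gg", "nLc"))) {
    list(series = "Gg-or-nLc", evidence = "ambiguous")
  } else if (setequal(series_set, c("Gb", "nLc"))) {
    list(series = "Gb-or-nLc", evidence = "ambiguous")
  } else {
    list(series = "other", evidence = "ambiguous")
  }
  structure(c(call, base), class = "gsl_series_call")
}

#' Classify an O-glycan composition into its mucin core
#'
#' Core assignment from the (hex, hexnac) backbone, ignoring sialic acids
#' and fucose:
#' * `(0, 1)` — Tn antigen;
#' * `(1, 1)` — core 1 (T antigen and its sialylated forms);
#' * `(1, 2)` — core 2 (ungalactosylated branch);
#' * `(2, 2)` — ambiguous between core 2 and extended core 1; resolved only
#'   by exo-beta-galactosidase digestion evidence (a branched core 2 parent
#'   is degraded — "parent lost" — while assignment of the surviving linear
#'   species falls to extended core 1);
#' * anything else — `other`.
#'
#' @param comp A composition with hexnac >= 1.
#' @param evidence Optional digestion verdict for the Hex2HexNAc2 backbone:
#'   a list with logical `parent_lost` (e.g. from [simulate_digest()]);
#'   `TRUE` resolves to core 2, `FALSE` to extended core 1.
#' @return A list of class `o_glycan_class` with fields `core`,
#'   `sialic_count`, `neu5gc_count`.
#' @examples
#' classify_o("(Hex)1(HexNAc)1(Neu5Ac)2")$core  # "core1" (disialyl-T)
#' classify_o("(Hex)2(HexNAc)2(Neu5Ac)1")$core  # ambiguous
#' @export
classify_o <- function(comp, evidence = NULL) {
  comp <- as_glycan_composition(comp)
  if (comp[["hexnac"]] < 1L) {
    stop("not an O-glycan: no HexNAc residue", call. = FALSE)
  }
  hx <- comp[["hex"]]
  hn <- comp[["hexnac"]]
  core <- if (hn == 1L && hx == 0L) {
    "Tn"
  } else if (hn == 1L && hx == 1L) {
    "core1"
  } else if (hn == 2L && hx == 1L) {
    "core2"
  } else if (hn == 2L && hx == 2L) {
    if (!is.null(evidence)) {
      if (isTRUE(evidence$parent_lost)) "core2" else "extended-core1"
    } else "core1-or-core2-ambiguous"
  } else "other"
  structure(
    list(core = core, sialic_count = sialic_count(comp),
         neu5gc_count = comp[["neu5gc"]]),
    class = "o_glycan_class"
  )
}

#' Neu5Gc share of sialylated glycans
#'
#' Percentage of the total sialylated amount carried by species containing
#' at least one N-glycolylneuraminic acid residue — a marker of
#' incorporation of the non-human sialic acid from external sources.
#'
#' @param quants A `quantified_glycans` table, or any data frame with
#'   columns `composition` and `amount` on a common scale.
#' @return Percentage in `[0, 100]`, or `NA` when no sialylated species is
#'   present (undefined denominator).
#' @export
neu5gc_fraction <- function(quants) {
  stopifnot(is.data.frame(quants),
            all(c("composition", "amount") %in% names(quants)))
  if (!nrow(quants)) return(NA_real_)
  comps <- lapply(quants$composition, as_glycan_composition)
  sia <- vapply(comps, sialic_count, integer(1))
  gc <- vapply(comps, function(cc) cc[["neu5gc"]], integer(1))
  denom <- sum(quants$amount[sia >= 1L])
  if (denom <= 0) return(NA_real_)
  100 * sum(quants$amount[gc >= 1L]) / denom
}
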