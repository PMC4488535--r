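# Composition assignment: enumerate all candidate compositions whose
# derivatized m/z falls within a mass tolerance of an observed peak, then
# attach isomeric structure records from the database.

#' Annotation parameters
#'
#' Search settings for composition assignment. Defaults follow the standard
#' MALDI glycomics search: +/- 0.5 Da mass tolerance, singly protonated
#' derivatized glycans.
#'
#' @param tolerance Mass tolerance in Da (> 0, boundary inclusive).
#'   Default 0.5.
#' @param scheme A [derivatization_scheme()] or its name. Default `"aoWR"`.
#' @param bounds Named integer vector of maximum residue counts searched.
#'   Defaults: hex 15, hexnac 12, dhex 6, neu5ac 8, neu5gc 4. The search is
#'   exhaustive within these bounds.
#' @param require_db_hit If `TRUE`, candidates without a structure-database
#'   record are dropped.
#' @param snr_threshold Optional signal-to-noise cutoff; peaks with a
#'   reported S/N below it are dropped before annotation (the conventional
#'   peak-picking threshold is 1.5).
#' @return An object of class `annotation_params`.
#' @export
annotation_params <- function(tolerance = 0.5,
                              scheme = "aoWR",
                              bounds = c(hex = 15L, hexnac = 12L, dhex = 6L,
                                         neu5ac = 8L, neu5gc = 4L),
                              require_db_hit = FALSE,
                              snr_threshold = NULL) {
  stopifnot(is.numeric(tolerance), tolerance > 0)
  if (is.character(scheme)) scheme <- derivatization_scheme(scheme)
  stopifnot(inherits(scheme, "derivatization_scheme"))
  b <- stats::setNames(rep(0L, length(.KINDS)), .KINDS)
  b[names(bounds)] <- as.integer(bounds)
  if (any(b < 0L)) stop("bounds must be non-negative", call. = FALSE)
  structure(
    list(tolerance = tolerance, scheme = scheme, bounds = b,
         require_db_hit = isTRUE(require_db_hit),
         snr_threshold = snr_threshold),
    class = "annotation_params"
  )
}

# Exhaustive composition grid within bounds, cached per bounds vector.
# Columns: the five counts; plus precomputed base (free-glycan) mass and
# sialic count. Every composition with >= 1 residue within bounds appears
# exactly once, so candidate search cannot miss edge cases.
.grid_cache <- new.env(parent = emptyenv())

.composition_grid <- function(bounds) {
  key <- paste(bounds, collapse = ",")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  g <- as.matrix(expand.grid(
    hex = 0:bounds[["hex"]], hexnac = 0:bounds[["hexnac"]],
    dhex = 0:bounds[["dhex"]], neu5ac = 0:bounds[["neu5ac"]],
    neu5gc = 0:bounds[["neu5gc"]], KEEP.OUT.ATTRS = FALSE
  ))
  g <- g[rowSums(g) >= 1L, , drop = FALSE]
  tab <- monosaccharide_masses()
  out <- list(
    counts = g,
    base_mass = as.numeric(g %*% tab$residue_mass[.KINDS]) + tab$water_mass,
    sialics = g[, "neu5ac"] + g[, "neu5gc"],
    total = rowSums(g)
  )
  .grid_cache[[key]] <- out
  out
}

# Deterministic candidate ordering: ascending |error| (quantized to 1e-6 Da
# so exact-mass isomers — e.g. Hex+Neu5Ac vs dHex+Neu5Gc, identical
# elemental formulas — compare as true ties rather than by float noise),
# then fewer total residues, then descending lexicographic on (hex,
# hexnac, dhex, neu5ac, neu5gc) so the hexose-rich composition of an
# exact-mass tie ranks first.
.order_candidates <- function(err, counts, total) {
  order(round(abs(err), 6), total,
        -counts[, "hex"], -counts[, "hexnac"], -counts[, "dhex"],
        -counts[, "neu5ac"], -counts[, "neu5gc"])
}

#' Enumerate candidate compositions for an m/z value
#'
#' Returns exactly the compositions within the search bounds whose
#' derivatized m/z lies within +/- `tolerance` of the query (boundary
#' inclusive). Candidates are ordered by ascending absolute mass error
#' (quantized to 1e-6 Da so elementally identical compositions tie
#' exactly); ties break toward fewer total residues, then descending
#' lexicographically on the counts, which ranks the hexose-rich member of
#' an exact-mass pair (e.g. Hex+Neu5Ac vs dHex+Neu5Gc) first.
#'
#' @param mz Query m/z (> 0).
#' @param params An [annotation_params()].
#' @return Data frame with columns `composition` (canonical string),
#'   `error_da` (candidate m/z minus query), plus the five count columns.
#'   Zero rows when nothing matches.
#' @examples
#' p <- annotation_params(scheme = "aoWR")
#' enumerate_candidates(1664.65, p)  # (Hex)5(HexNAc)2
#' @export
enumerate_candidates <- function(mz, params = annotation_params()) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
  grid <- .composition_grid(params$bounds)
  sch <- params$scheme
  ester <- if (sch$esterify_sialics) grid$sialics * sch$methylester_delta else 0
  cand_mz <- (grid$base_mass + sch$label_delta + ester +
                sch$adduct_mass * sch$charge) / sch$charge
  err <- cand_mz - mz
  keep <- which(abs(err) <= params$tolerance)
  counts <- grid$counts[keep, , drop = FALSE]
  err <- err[keep]
  total <- grid$total[keep]
  o <- .order_candidates(err, counts, total)
  counts <- counts[o, , drop = FALSE]
  comp_str <- vapply(seq_len(nrow(counts)), function(i) {
    format_composition(as_glycan_composition(counts[i, ]))
  }, character(1))
  out <- data.frame(composition = comp_str, error_da = err[o],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts, row.names = seq_len(nrow(counts))))
}

#' Annotate a peak list with glycan compositions
#'
#' Applies the optional S/N filter, then searches each peak for candidate
#' compositions, attaches isomeric structure records from the database, and
#' flags the internal-standard peak by exact composition match. One
#' composition may match several structures; the ambiguity is preserved —
#' no single structure is guessed without MS2 or digestion evidence.
#'
#' @param peaks Data frame with columns `mz`, `area` and optionally `snr`.
#' @param params An [annotation_params()].
#' @param db A [structure_db()] (default the shipped database).
#' @param is_composition Composition of the spiked internal standard
#'   (object or string), or `NULL` when no internal standard is expected.
#' @return An object of class `peak_annotations`: a data frame with one row
#'   per retained peak (`mz`, `area`, `snr`, `status`, `top_composition`,
#'   `error_da`, `n_candidates`, `structures`) and a `candidates` attribute
#'   holding the full candidate table for each peak. `status` is one of
#'   `assigned` (single candidate composition), `ambiguous` (several),
#'   `unassigned` (none) or `internal_standard`.
#' @export
annotate_peaklist <- function(peaks, params = annotation_params(),
                              db = default_structure_db(),
                              is_composition = NULL) {
  stopifnot(is.data.frame(peaks), all(c("mz", "area") %in% names(peaks)),
            nrow(peaks) >= 1L)
  if (!is.null(params$snr_threshold) && "snr" %in% names(peaks)) {
    keep <- is.na(peaks$snr) | peaks$snr >= params$snr_threshold
    peaks <- peaks[keep, , drop = FALSE]
  }
  if (!nrow(peaks)) stop("no peaks left after S/N filtering", call. = FALSE)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  is_key <- if (!is.null(is_composition)) {
    format_composition(as_glycan_composition(is_composition))
  } else NA_character_

  cand_list <- vector("list", nrow(peaks))
  status <- character(nrow(peaks))
  top_comp <- rep(NA_character_, nrow(peaks))
  err <- rep(NA_real_, nrow(peaks))
  ncand <- integer(nrow(peaks))
  structs <- rep(NA_character_, nrow(peaks))

  for (i in seq_len(nrow(peaks))) {
    cand <- enumerate_candidates(peaks$mz[i], params)
    if (nrow(cand)) {
      hits <- lapply(cand$composition, function(cc) {
        db_lookup(db, composition = cc)
      })
      if (params$require_db_hit) {
        keep <- vapply(hits, length, integer(1)) > 0L
        cand <- cand[keep, , drop = FALSE]
        hits <- hits[keep]
      }
      cand$structures <- vapply(hits, function(h) {
        paste(vapply(h, `[[`, character(1), "name"), collapse = ";")
      }, character(1))
    } else {
      cand$structures <- character(0)
    }
    cand_list[[i]] <- cand
    ncand[i] <- nrow(cand)
    if (nrow(cand) == 0L) {
      status[i] <- "unassigned"
    } else {
      top_comp[i] <- cand$composition[1]
      err[i] <- cand$error_da[1]
      structs[i] <- cand$structures[1]
      status[i] <- if (!is.na(is_key) && is_key %in% cand$composition) {
        "internal_standard"
      } else if (nrow(cand) > 1L) "ambiguous" else "assigned"
    }
  }

  if (!is.na(is_key) && !any(status == "internal_standard")) {
    stop("missing internal standard: no peak within ", params$tolerance,
         " Da of the ", is_key, " internal standard m/z ",
         round(derivatized_mz(is_key, params$scheme), 3),
         call. = FALSE)
  }

  out <- data.frame(
    mz = peaks$mz, area = peaks$area,
    snr = if ("snr" %in% names(peaks)) peaks$snr else NA_real_,
    status = status, top_composition = top_comp, error_da = err,
    n_candidates = ncand, structures = structs,
    stringsAsFactors = FALSE
  )
  attr(out, "candidates") <- cand_list
  attr(out, "params") <- params
  class(out) <- c("peak_annotations", "data.frame")
  out
}

#' Write an annotation table to CSV
#'
#' The search parameters (tolerance, scheme, bounds) are recorded in
#' '#'-prefixed header lines so that every report carries its settings.
#'
#' @param annotations A [annotate_peaklist()] result.
#' @param path Output CSV path.
#' @param header Write the provenance header block (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(annotations, path, header = TRUE) {
  stopifnot(inherits(annotations, "peak_annotations"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    p <- attr(annotations, "params")
    writeLines(c(
      sprintf("# glycopanel %s annotation table",
              as.character(utils::packageVersion("glycopanel"))),
      sprintf("# scheme=%s tolerance_da=%g", p$scheme$name, p$tolerance),
      sprintf("# bounds=%s", paste(names(p$bounds), p$bounds, sep = "<=",
                                   collapse = " "))
    ), con)
  }
  utils::write.csv(as.data.frame(annotations), con, row.names = FALSE)
  invisible(path)
}
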