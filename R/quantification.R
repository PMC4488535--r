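# Internal-standard absolute quantification: converts annotated peak areas
# into pmol per 100 ug protein, subtracts negative controls, and aggregates
# replicates.

#' Internal standard reference
#'
#' @param name Standard name, conventionally `"A2GN1"` (N- and GSL-glycans,
#'   composition Hex5HexNAc3Neu5Ac2) or `"GN4"` (O-glycans; modeled with a
#'   configurable composition defaulting to HexNAc4).
#' @param composition Composition of the standard (object or string).
#' @param spiked_amount Spiked amount in pmol (> 0).
#' @return An object of class `internal_standard`.
#' @examples
#' internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10)
#' internal_standard("GN4", "(HexNAc)4", 10)
#' @export
internal_standard <- function(name, composition, spiked_amount) {
  stopifnot(is.numeric(spiked_amount), spiked_amount > 0)
  structure(
    list(name = name,
         composition = as_glycan_composition(composition),
         spiked_amount = spiked_amount),
    class = "internal_standard"
  )
}

# labeled m/z below which MALDI response falls off and amounts may be
# underestimated; flagged, not corrected
.LOW_MASS_MZ <- 1000

#' Quantify annotated peaks against the internal standard
#'
#' Absolute amount of each assigned glycan:
#' `amount = (area / area_IS) * spiked_amount * (100 / protein_amount)`,
#' in pmol per 100 ug protein. The internal standard itself is excluded
#' from the output. Peaks whose labeled m/z is below 1000 are flagged
#' `low_mass`: quantitative MALDI response is only mass-independent above
#' roughly 1 kDa, so such amounts may be underestimated.
#'
#' @param annotations A [annotate_peaklist()] result containing exactly one
#'   internal-standard peak.
#' @param is_ref An [internal_standard()].
#' @param protein_amount Total protein in the sample, in ug (> 0).
#' @return An object of class `quantified_glycans`: data frame with columns
#'   `composition`, `structures`, `mz`, `amount` (pmol/100 ug),
#'   `low_mass`, `control_flag` (`"clean"` at this stage). Peaks sharing a
#'   composition are pooled by summed area.
#' @export
quantify <- function(annotations, is_ref, protein_amount) {
  stopifnot(inherits(annotations, "peak_annotations"),
            inherits(is_ref, "internal_standard"))
  if (!is.numeric(protein_amount) || length(protein_amount) != 1L ||
      !is.finite(protein_amount) || protein_amount <= 0) {
    stop("invalid metadata: protein_amount must be a positive number (ug)",
         call. = FALSE)
  }
  is_rows <- annotations$status == "internal_standard"
  if (!any(is_rows)) {
    stop("missing internal standard: no annotated peak matches ",
         format_composition(is_ref$composition), call. = FALSE)
  }
  area_is <- sum(annotations$area[is_rows])
  if (area_is <= 0) {
    stop("missing internal standard: internal-standard peak area is zero",
         call. = FALSE)
  }
  q <- annotations[!is_rows &
                     annotations$status %in% c("assigned", "ambiguous"), ,
                   drop = FALSE]
  if (!nrow(q)) {
    out <- data.frame(composition = character(0), structures = character(0),
                      mz = numeric(0), amount = numeric(0),
                      low_mass = logical(0), control_flag = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("quantified_glycans", "data.frame")
    return(out)
  }
  amount <- q$area / area_is * is_ref$spiked_amount * (100 / protein_amount)
  out <- data.frame(
    composition = q$top_composition,
    structures = q$structures,
    mz = q$mz,
    amount = amount,
    low_mass = q$mz < .LOW_MASS_MZ,
    control_flag = "clean",
    stringsAsFactors = FALSE
  )
  # pool peaks that resolved to the same composition
  if (anyDuplicated(out$composition)) {
    sp <- split(out, out$composition)
    out <- do.call(rbind, lapply(sp, function(d) {
      d$amount[1] <- sum(d$amount)
      d[1, , drop = FALSE]
    }))
    out <- out[order(out$mz), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("quantified_glycans", "data.frame")
  out
}

#' Subtract a negative control from a quantified table
#'
#' Used for GSL glycans, where free oligosaccharides recovered from a
#' digestion performed without endoglycoceramidase serve as a negative
#' control: per composition, `amount <- max(0, sample - control)`.
#' Compositions driven to zero are flagged `excluded_in_control`; those
#' reduced but not removed are flagged `control_subtracted`. Subtraction
#' operates on amounts, not raw areas, so sample and control may have
#' different internal-standard recoveries.
#'
#' @param sample,control `quantified_glycans` tables on the same scale.
#' @return The corrected `quantified_glycans` table.
#' @export
subtract_control <- function(sample, control) {
  stopifnot(inherits(sample, "quantified_glycans"),
            inherits(control, "quantified_glycans"))
  if (!nrow(control)) return(sample)
  for (i in seq_len(nrow(sample))) {
    j <- match(sample$composition[i], control$composition)
    if (is.na(j)) next
    c_amt <- control$amount[j]
    if (c_amt <= 0) next
    new_amt <- max(0, sample$amount[i] - c_amt)
    sample$amount[i] <- new_amt
    sample$control_flag[i] <- if (new_amt == 0) "excluded_in_control"
                              else "control_subtracted"
  }
  sample
}

#' Aggregate replicate quantifications
#'
#' Unions the compositions across replicate tables (a glycan missing from a
#' replicate counts as 0 pmol — absence, not missing-at-random) and reports
#' per-composition mean and dispersion. With three or more replicates the
#' dispersion is the sample standard deviation (n-1 denominator); with two
#' it is the half-range, tagged `"range/2"` (the conventional "mean +/-
#' range of two analyses"); a single replicate reports 0, tagged
#' `"single"`.
#'
#' @param tables List of `quantified_glycans` tables (>= 1).
#' @return Data frame with columns `composition`, `structures`,
#'   `replicate_mean`, `replicate_dispersion`, `dispersion_kind`,
#'   `n_replicates`, `control_flag`, `low_mass`.
#' @export
aggregate_replicates <- function(tables) {
  if (!length(tables)) stop("no replicate tables supplied", call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1), "quantified_glycans")))
  n <- length(tables)
  comps <- unique(unlist(lapply(tables, `[[`, "composition")))
  rows <- lapply(comps, function(cc) {
    amts <- vapply(tables, function(tb) {
      i <- match(cc, tb$composition)
      if (is.na(i)) 0 else tb$amount[i]
    }, numeric(1))
    first <- Filter(Negate(is.null), lapply(tables, function(tb) {
      i <- match(cc, tb$composition)
      if (is.na(i)) NULL else tb[i, , drop = FALSE]
    }))[[1]]
    disp <- if (n >= 3L) stats::sd(amts)
            else if (n == 2L) diff(range(amts)) / 2
            else 0
    data.frame(
      composition = cc,
      structures = first$structures,
      replicate_mean = mean(amts),
      replicate_dispersion = disp,
      dispersion_kind = c("single", "range/2", "sd")[min(n, 3L)],
      n_replicates = n,
      control_flag = first$control_flag,
      low_mass = first$low_mass,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
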