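# Elemental and residue mass bookkeeping. All mass arithmetic in the package
# routes through the table returned by monosaccharide_masses(); residue and
# label masses are derived from molecular formulas at build time so the
# elemental table is the single source of truth.

# Monoisotopic atomic masses (Da), CODATA/IUPAC values.
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196
)

.PROTON_MASS <- 1.00727646688

# Residue (in-chain, dehydro) molecular formulas of the five supported
# monosaccharide kinds.
.RESIDUE_FORMULA <- c(
  hex    = "C6H10O5",
  hexnac = "C8H13NO5",
  dhex   = "C6H10O4",
  neu5ac = "C11H17NO8",
  neu5gc = "C11H17NO9"
)

.KINDS <- names(.RESIDUE_FORMULA)

# Canonical display token for each kind, used by composition formatting.
.KIND_TOKEN <- c(
  hex = "Hex", hexnac = "HexNAc", dhex = "dHex",
  neu5ac = "Neu5Ac", neu5gc = "Neu5Gc"
)

#' Monoisotopic mass of a molecular formula
#'
#' Computes the monoisotopic mass of a CHNO molecular formula such as
#' `"C6H10O5"` from the package's elemental mass table.
#'
#' @param formula A molecular formula string restricted to C, H, N, O.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")       # 18.0106
#' formula_mass("C6H10O5")   # hexose residue
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([CHNO])([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([CHNO])([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("unsupported symbol in formula: ", formula, call. = FALSE)
  }
  total <- 0
  for (p in parts) {
    el <- substr(p, 1L, 1L)
    n <- substr(p, 2L, nchar(p))
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + .ELEMENT_MASS[[el]] * n
  }
  total
}

#' Monosaccharide mass table
#'
#' Immutable table of monoisotopic residue masses used by every mass
#' computation in the package. Residue masses are the dehydro (in-chain)
#' masses, so the mass of a free reducing glycan is the sum of its residue
#' masses plus one water.
#'
#' @return An object of class `mass_table`: a list with `residue_mass`
#'   (named vector over `hex`, `hexnac`, `dhex`, `neu5ac`, `neu5gc`),
#'   `water_mass` and `proton_mass`, all in Da.
#' @examples
#' monosaccharide_masses()$residue_mass[["hex"]]  # 162.0528
#' @export
monosaccharide_masses <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      residue <- vapply(.RESIDUE_FORMULA, formula_mass, numeric(1))
      tab <<- structure(
        list(
          residue_mass = residue,
          water_mass = formula_mass("H2O"),
          proton_mass = .PROTON_MASS
        ),
        class = "mass_table"
      )
    }
    tab
  }
})

# Net label mass deltas, derived from molecular formulas:
#  - aoWR (aminooxyacetyl-Trp-Arg methyl ester, C20H29N7O5) condenses with
#    the reducing end as an oxime, losing one water.
#  - bis-PMP labeling adds two PMP units (C10H10N2O each) and loses one
#    water overall.
.label_delta <- function(name) {
  w <- formula_mass("H2O")
  switch(name,
    aoWR = formula_mass("C20H29N7O5") - w,
    bisPMP = 2 * formula_mass("C10H10N2O") - w,
    none = 0,
    stop("unknown derivatization scheme: ", name, call. = FALSE)
  )
}

#' Derivatization scheme
#'
#' Describes the reducing-end labeling chemistry that maps a glycan
#' composition to an observable MALDI m/z. Two chemistries are registered:
#'
#' * `"aoWR"` — glycoblotting with the dipeptidic aminooxy tag aoWR
#'   (oxime condensation), used for N- and GSL-glycans. Sialic-acid
#'   carboxyls are methyl-esterified on-bead, so each sialic residue adds
#'   one methyl-ester mass (+CH2).
#' * `"bisPMP"` — bis-PMP labeling of O-glycans released by beta-elimination
#'   in the presence of pyrazolone (BEP). No methyl esterification.
#' * `"none"` — free reducing glycan, no label.
#'
#' All schemes assume singly protonated ions (charge 1+), as appropriate for
#' the high proton affinity of the labels in positive-mode MALDI.
#'
#' @param name One of `"aoWR"`, `"bisPMP"`, `"none"`.
#' @return An object of class `derivatization_scheme` with fields `name`,
#'   `label_delta` (Da), `methylester_delta` (Da per esterified sialic
#'   residue), `esterify_sialics` (logical), `charge` (1) and `adduct_mass`
#'   (proton, Da).
#' @examples
#' derivatization_scheme("aoWR")$label_delta    # 429.2125
#' derivatization_scheme("bisPMP")$label_delta  # 330.1481
#' @export
derivatization_scheme <- function(name = c("aoWR", "bisPMP", "none")) {
  name <- match.arg(name)
  structure(
    list(
      name = name,
      label_delta = .label_delta(name),
      methylester_delta = formula_mass("CH2"),
      esterify_sialics = identical(name, "aoWR"),
      charge = 1L,
      adduct_mass = .PROTON_MASS
    ),
    class = "derivatization_scheme"
  )
}

#' @export
print.derivatization_scheme <- function(x, ...) {
  cat(sprintf(
    "<derivatization_scheme %s> label +%.4f Da, %s, [M+%dH]%d+\n",
    x$name, x$label_delta,
    if (x$esterify_sialics) "sialics methyl-esterified (+14.0157 Da each)"
    else "no methyl esterification",
    x$charge, x$charge
  ))
  invisible(x)
}

#' Monoisotopic mass of a free reducing glycan
#'
#' Sum of the in-chain residue masses plus one water.
#'
#' @param comp A [glycan_composition()].
#' @param table A mass table from [monosaccharide_masses()].
#' @return Mass in Da at full floating precision.
#' @examples
#' composition_mass(glycan_composition(hex = 5, hexnac = 2))  # 1234.4334
#' @export
composition_mass <- function(comp, table = monosaccharide_masses()) {
  comp <- as_glycan_composition(comp)
  if (sum(comp) < 1L) {
    stop("invalid composition: at least one residue required", call. = FALSE)
  }
  sum(as.numeric(comp) * table$residue_mass[.KINDS]) + table$water_mass
}

#' Observable m/z of a derivatized glycan
#'
#' Applies a derivatization scheme to a composition: free glycan mass plus
#' label delta, plus one methyl-ester mass per sialic residue when the
#' scheme esterifies sialics, plus the proton adduct, divided by the charge
#' (always 1).
#'
#' @param comp A [glycan_composition()].
#' @param scheme A [derivatization_scheme()] or its name.
#' @param table A mass table from [monosaccharide_masses()].
#' @return m/z at full floating precision. Report to one decimal for
#'   display; the package carries full precision internally.
#' @examples
#' derivatized_mz(glycan_composition(hex = 2, hexnac = 1), "aoWR")  # 975.4
#' @export
derivatized_mz <- function(comp, scheme, table = monosaccharide_masses()) {
  if (is.character(scheme)) scheme <- derivatization_scheme(scheme)
  stopifnot(inherits(scheme, "derivatization_scheme"))
  comp <- as_glycan_composition(comp)
  sialics <- comp[["neu5ac"]] + comp[["neu5gc"]]
  ester <- if (scheme$esterify_sialics) sialics * scheme$methylester_delta else 0
  (composition_mass(comp, table) + scheme$label_delta + ester +
     scheme$adduct_mass * scheme$charge) / scheme$charge
}
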