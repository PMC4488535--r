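# Ground-truth panel simulation: five-stage glycan panels with planted
# stage-to-stage fold changes, rendered as noisy MALDI peak lists (MS1,
# MS2 ladders, digestion products) so the whole pipeline can be exercised
# against known answers without any external data.

#' Panel specification
#'
#' Defines the ground truth of a simulated multi-stage panel: the glycans,
#' their baseline amounts, and per-transition fold multipliers.
#'
#' @param stages Ordered character vector of stage labels (default the
#'   five-stage astrocyte transformation panel NHA, NHA/T, NHA/TS,
#'   NHA/TSR, NHA/TSRA, where each step adds one genetic element).
#' @param glycans List of entries `list(record = <glycan_record>,
#'   base = <pmol/100 ug at the first stage>)`.
#' @param multipliers Numeric matrix, one row per glycan and one column per
#'   transition (`length(stages) - 1`); entry `(g, t)` multiplies glycan
#'   g's amount across transition t (positive, or exactly 0 for
#'   extinction).
#' @param protein_amounts Protein content per stage in ug (recycled;
#'   default 100).
#' @param is_ref An [internal_standard()] spiked into every sample.
#' @param replicates Replicates per stage (default 3).
#' @param scheme Derivatization scheme name for rendering (default
#'   `"aoWR"`).
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(stages = c("NHA", "NHA/T", "NHA/TS", "NHA/TSR",
                                  "NHA/TSRA"),
                       glycans,
                       multipliers,
                       protein_amounts = 100,
                       is_ref = internal_standard(
                         "A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10),
                       replicates = 3L,
                       scheme = "aoWR") {
  stopifnot(length(stages) >= 2L, length(glycans) >= 1L)
  multipliers <- as.matrix(multipliers)
  if (nrow(multipliers) != length(glycans) ||
      ncol(multipliers) != length(stages) - 1L) {
    stop("multiplier table must be n_glycans x (n_stages - 1)",
         call. = FALSE)
  }
  if (any(multipliers < 0)) {
    stop("multipliers must be positive, or exactly 0 for extinction",
         call. = FALSE)
  }
  stopifnot(inherits(is_ref, "internal_standard"), replicates >= 1L)
  structure(
    list(stages = stages, glycans = glycans, multipliers = multipliers,
         protein_amounts = rep_len(protein_amounts, length(stages)),
         is_ref = is_ref, replicates = as.integer(replicates),
         scheme = scheme),
    class = "panel_spec"
  )
}

#' Noise specification
#'
#' @param mz_jitter_sd Gaussian m/z jitter standard deviation in Da.
#' @param intensity_cv Coefficient of variation of the multiplicative
#'   log-normal intensity noise (MALDI area variability is multiplicative).
#' @param n_contaminant_peaks Contaminant peaks per spectrum, uniform in
#'   `contaminant_mz_range`.
#' @param contaminant_mz_range Length-2 numeric m/z range.
#' @param dropout_probability Per-peak dropout probability (< 1; never
#'   applied to the internal standard).
#' @param seed Integer seed; all randomness in rendering flows from it.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mz_jitter_sd = 0.05, intensity_cv = 0.05,
                       n_contaminant_peaks = 5L,
                       contaminant_mz_range = c(700, 4000),
                       dropout_probability = 0, seed = 1L) {
  stopifnot(mz_jitter_sd >= 0, intensity_cv >= 0,
            n_contaminant_peaks >= 0L,
            dropout_probability >= 0, dropout_probability < 1)
  structure(
    list(mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
         n_contaminant_peaks = as.integer(n_contaminant_peaks),
         contaminant_mz_range = contaminant_mz_range,
         dropout_probability = dropout_probability,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Exact ground-truth stage panel from a specification
#'
#' Amount of glycan g at stage k is its base amount times the cumulative
#' product of its multipliers up to transition k-1; replicates are
#' identical before noise. Fully deterministic.
#'
#' @param spec A [panel_spec()].
#' @return A [stage_panel()] with `meta` columns `glycome`,
#'   `series_or_class` and `composition`, and the spec attached as
#'   attribute `spec`.
#' @export
make_truth_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  nm <- vapply(spec$glycans, function(g) g$record$name, character(1))
  base <- vapply(spec$glycans, `[[`, numeric(1), "base")
  m <- t(apply(cbind(1, spec$multipliers), 1L, cumprod)) * base
  dimnames(m) <- list(nm, spec$stages)
  meta <- data.frame(
    glycome = vapply(spec$glycans, function(g) g$record$glycome,
                     character(1)),
    series_or_class = vapply(spec$glycans, function(g) g$record$series_or_class,
                             character(1)),
    composition = vapply(spec$glycans, function(g)
      format_composition(g$record$composition), character(1)),
    stringsAsFactors = FALSE
  )
  panel <- stage_panel(m, meta)
  attr(panel, "spec") <- spec
  panel
}

# run expr with a private RNG stream seeded from `seed`, restoring any
# pre-existing global seed afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# peak area per pmol of analyte actually deposited; arbitrary instrument
# response scale shared by analytes and internal standard
.AREA_PER_PMOL <- 1000

.lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Render noisy MS1 peak lists from a truth panel
#'
#' For every stage and replicate, each glycan contributes one peak at its
#' derivatized m/z plus Gaussian jitter, with an area proportional to the
#' picomoles deposited (truth amount scaled by the sample's protein
#' content) under multiplicative log-normal noise; the internal standard is
#' added the same way; contaminant peaks are drawn uniformly over the m/z
#' range; dropout removes analyte peaks at random (never the internal
#' standard). Deterministic for a fixed seed.
#'
#' @param truth A [make_truth_panel()] result.
#' @param noise A [noise_spec()].
#' @param dir Optional directory: write each peak list as a TSV
#'   (`mz`, `area` columns) named `<stage>_rep<r>.tsv` and return the
#'   manifest.
#' @return A nested list `peaklists[[stage]][[replicate]]` of peak data
#'   frames, with the stage/replicate design as attribute `design`; when
#'   `dir` is given, files are written as a side effect.
#' @export
render_peaklist <- function(truth, noise = noise_spec(), dir = NULL) {
  spec <- attr(truth, "spec")
  stopifnot(inherits(spec, "panel_spec"), inherits(noise, "noise_spec"))
  params_tol <- 0.5
  if (noise$mz_jitter_sd >= params_tol / 2) {
    warning("m/z jitter sd (", noise$mz_jitter_sd,
            " Da) is at least half the usual 0.5 Da search tolerance; ",
            "annotation may fail by design", call. = FALSE)
  }
  scheme <- derivatization_scheme(spec$scheme)
  glycan_mz <- vapply(spec$glycans, function(g) {
    derivatized_mz(g$record$composition, scheme)
  }, numeric(1))
  is_mz <- derivatized_mz(spec$is_ref$composition, scheme)

  .with_seed(noise$seed, {
    out <- lapply(seq_along(spec$stages), function(si) {
      stage <- spec$stages[si]
      lapply(seq_len(spec$replicates), function(r) {
        amounts <- truth$matrix[, si]
        pmol <- amounts * spec$protein_amounts[si] / 100
        present <- pmol > 0
        n <- sum(present)
        mz <- glycan_mz[present] + stats::rnorm(n, 0, noise$mz_jitter_sd)
        area <- pmol[present] * .AREA_PER_PMOL *
          .lognorm_factor(n, noise$intensity_cv)
        if (noise$dropout_probability > 0 && n > 0) {
          keep <- stats::runif(n) >= noise$dropout_probability
          mz <- mz[keep]; area <- area[keep]
        }
        # internal standard (never dropped)
        mz <- c(mz, is_mz + stats::rnorm(1, 0, noise$mz_jitter_sd))
        area <- c(area, spec$is_ref$spiked_amount * .AREA_PER_PMOL *
                    .lognorm_factor(1, noise$intensity_cv))
        if (noise$n_contaminant_peaks > 0L) {
          cmz <- stats::runif(noise$n_contaminant_peaks,
                              noise$contaminant_mz_range[1],
                              noise$contaminant_mz_range[2])
          carea <- stats::median(area) *
            .lognorm_factor(noise$n_contaminant_peaks, 0.5)
          mz <- c(mz, cmz); area <- c(area, carea)
        }
        pl <- data.frame(mz = mz, area = area)
        pl[order(pl$mz), , drop = FALSE]
      })
    })
    names(out) <- spec$stages
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (stage in spec$stages) {
        for (r in seq_len(spec$replicates)) {
          fn <- file.path(dir, paste0(gsub("/", "-", stage), "_rep", r,
                                      ".tsv"))
          utils::write.table(out[[stage]][[r]], fn, sep = "\t",
                             row.names = FALSE, quote = FALSE)
        }
      }
    }
    attr(out, "design") <- data.frame(
      stage = rep(spec$stages, each = spec$replicates),
      replicate = rep(seq_len(spec$replicates), length(spec$stages))
    )
    out
  })
}

#' Render MS2 ladders and digestion tables from a truth panel
#'
#' For each glycan whose composition is shared by several database isomers,
#' emits a simulated MS2 peak list at its Y-ion ladder m/z values; also
#' simulates digestion of the whole panel pool with each supplied enzyme
#' and returns the pre/post quantified tables (first-stage amounts).
#'
#' @param truth A [make_truth_panel()] result.
#' @param enzymes Named list of [enzyme_spec()]s (default
#'   [default_enzymes()]).
#' @param db A [structure_db()] used to find isomeric partners.
#' @param noise A [noise_spec()]; MS2 areas share the intensity noise
#'   model (m/z jitter is applied to fragment peaks as well).
#' @return A list with `ms2` (per ambiguous glycan: the simulated peak
#'   list and the candidate records) and `digests` (per enzyme: `pre` and
#'   `post` amount tables and the per-parent verdicts).
#' @export
render_ms2_and_digests <- function(truth, enzymes = default_enzymes(),
                                   db = default_structure_db(),
                                   noise = noise_spec()) {
  spec <- attr(truth, "spec")
  stopifnot(inherits(spec, "panel_spec"))
  scheme <- derivatization_scheme(spec$scheme)

  .with_seed(noise$seed + 1L, {
    ms2 <- list()
    for (g in spec$glycans) {
      partners <- db_lookup(db, composition = g$record$composition,
                            glycome = g$record$glycome)
      if (length(partners) < 2L) next
      ladder <- y_ion_ladder(g$record, scheme)
      if (!nrow(ladder)) next
      pl <- data.frame(
        mz = ladder$mz + stats::rnorm(nrow(ladder), 0, noise$mz_jitter_sd),
        area = 100 * .lognorm_factor(nrow(ladder), noise$intensity_cv)
      )
      ms2[[g$record$name]] <- list(peaks = pl[order(pl$mz), , drop = FALSE],
                                   candidates = partners)
    }

    pool <- lapply(seq_along(spec$glycans), function(i) {
      list(record = spec$glycans[[i]]$record,
           amount = unname(truth$matrix[i, 1L]))
    })
    pool <- Filter(function(p) p$amount > 0, pool)
    digests <- lapply(enzymes, function(enz) {
      res <- simulate_digest(pool, enz, scheme = scheme)
      pre <- data.frame(
        composition = vapply(pool, function(p)
          format_composition(p$record$composition), character(1)),
        amount = vapply(pool, `[[`, numeric(1), "amount"),
        stringsAsFactors = FALSE
      )
      list(pre = pre, post = res$products[, c("composition", "amount")],
           verdicts = res$verdicts)
    })
    list(ms2 = ms2, digests = digests)
  })
}

#' Example five-stage GSL panel specification
#'
#' An illustrative ground truth that plants the qualitative hallmarks of
#' staged astrocyte transformation: a transient GD3 spike (x16) and a
#' LacCer rise (x7) at the first (hTERT) transition, a ganglio-to-globo
#' switch across the SV40ER and H-RasV12 transitions with an SSEA-4 spike
#' at the H-RasV12 step, and a strong (neo)lacto / fucosylation surge at
#' the myrAKT transition. Amounts are illustrative of MALDI glycomics
#' scale, not measurements.
#'
#' @param replicates Replicates per stage (default 3).
#' @param is_amount Spiked internal-standard amount in pmol (default 10).
#' @return A [panel_spec()].
#' @export
example_gsl_panel_spec <- function(replicates = 3L, is_amount = 10) {
  db <- default_structure_db()
  rec <- function(nm) db_lookup(db, name = nm)[[1]]
  #            name              base   T     S     R     A
  plan <- list(
    list("LacCer",          20,  c(7,    0.6,  0.8,  1.5)),
    list("GM3",             60,  c(1,    0.35, 0.4,  0.8)),
    list("GM2",             25,  c(0.9,  0.3,  0.45, 0.7)),
    list("GM1",             18,  c(1,    0.3,  0.4,  0.6)),
    list("GD3",              2,  c(16,   0.1,  1.2,  1)),
    list("GD1a",            12,  c(1.1,  0.25, 0.5,  0.7)),
    list("Gb3",             0.8, c(1,    3,    4,    3)),
    list("Gb4",             0.6, c(1.1,  3.5,  4,    3)),
    list("SSEA-3",          0.3, c(1,    1.5,  6,    0.8)),
    list("SSEA-4",          0.4, c(1,    1.4,  7,    0.7)),
    list("Gb-Hex5HexNAc2",  0.2, c(1,    2.5,  8,    1)),
    list("nLc-Hex5HexNAc2", 1.5, c(1,    0.4,  0.9,  4)),
    list("Lc3",              3,  c(1,    0.3,  1,    5)),
    list("nLc4",             4,  c(0.9,  0.3,  1,    16)),
    list("nLc6",             2,  c(1,    0.35, 1.1,  6)),
    list("sialyl-nLc4",      3,  c(1,    0.4,  1,    4)),
    list("Neu5Gc-GM3",       1,  c(1,    1.5,  1,    1))
  )
  panel_spec(
    glycans = lapply(plan, function(p) list(record = rec(p[[1]]),
                                            base = p[[2]])),
    multipliers = do.call(rbind, lapply(plan, `[[`, 3L)),
    is_ref = internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2",
                               is_amount),
    replicates = replicates,
    scheme = "aoWR"
  )
}
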