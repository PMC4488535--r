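# Ground-truth panel generation and noisy rendering.

test_that("truth amounts are cumulative products of the multipliers", {
  db <- default_structure_db()
  spec <- panel_spec(
    glycans = list(list(record = db_lookup(db, name = "GD3")[[1]], base = 1)),
    multipliers = matrix(c(16, 0.1, 1.2, 1.0), nrow = 1),
    replicates = 1L)
  truth <- make_truth_panel(spec)
  expect_equal(unname(truth$matrix[1, ]), c(1, 16, 1.6, 1.92, 1.92))

  flat <- panel_spec(
    glycans = list(list(record = db_lookup(db, name = "GM3")[[1]], base = 7)),
    multipliers = matrix(rep(1, 4), nrow = 1), replicates = 1L)
  expect_equal(unname(make_truth_panel(flat)$matrix[1, ]), rep(7, 5))

  expect_error(panel_spec(
    glycans = list(list(record = db_lookup(db, name = "GM3")[[1]], base = 7)),
    multipliers = matrix(1, nrow = 2, ncol = 4)), "multiplier table")
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- example_gsl_panel_spec(replicates = 2L)
  truth <- make_truth_panel(spec)
  n1 <- noise_spec(seed = 99L)
  p1 <- render_peaklist(truth, n1)
  p2 <- render_peaklist(truth, n1)
  expect_identical(p1, p2)
  p3 <- render_peaklist(truth, noise_spec(seed = 100L))
  expect_false(identical(p1, p3))

  d1 <- tempfile(); d2 <- tempfile()
  render_peaklist(truth, n1, dir = d1)
  render_peaklist(truth, n1, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(1234)
  a <- stats::runif(1)
  set.seed(1234)
  invisible(render_peaklist(make_truth_panel(example_gsl_panel_spec()),
                            noise_spec(seed = 7L)))
  expect_identical(stats::runif(1), a)
})

test_that("a noiseless render recovers planted amounts exactly", {
  spec <- example_gsl_panel_spec(replicates = 1L)
  truth <- make_truth_panel(spec)
  quiet <- noise_spec(mz_jitter_sd = 0, intensity_cv = 0,
                      n_contaminant_peaks = 0L, seed = 1L)
  pls <- render_peaklist(truth, quiet)
  params <- annotation_params(scheme = spec$scheme)
  db <- default_structure_db()

  # planted truth aggregated by composition (isomers co-migrate in MS1)
  planted <- rowsum(truth$matrix, truth$meta$composition)
  for (si in seq_along(spec$stages)) {
    ann <- annotate_peaklist(pls[[si]][[1]], params, db,
                             spec$is_ref$composition)
    q <- quantify(ann, spec$is_ref, spec$protein_amounts[si])
    for (cc in rownames(planted)) {
      got <- q$amount[q$composition == cc]
      expect_equal(got, unname(planted[cc, si]), tolerance = 1e-9,
                   label = paste(cc, "stage", si))
    }
  }
})

test_that("moderate jitter never defeats the 0.5 Da database search", {
  spec <- example_gsl_panel_spec(replicates = 1L)
  truth <- make_truth_panel(spec)
  # database-restricted search, as in a compositional database workflow:
  # chemically implausible near-isobars (e.g. penta-fucosyl species) are
  # not allowed to outrank a documented composition under jitter
  params <- annotation_params(scheme = spec$scheme, require_db_hit = TRUE)
  db <- default_structure_db()
  planted <- unique(truth$meta$composition)
  for (seed in 1:20) {
    nz <- noise_spec(mz_jitter_sd = 0.1, intensity_cv = 0,
                     n_contaminant_peaks = 0L, seed = seed)
    pl <- render_peaklist(truth, nz)[[1]][[1]]
    ann <- annotate_peaklist(pl, params, db, spec$is_ref$composition)
    expect_true(all(planted %in% ann$top_composition),
                label = paste("seed", seed))
  }
})

test_that("contaminant peaks surface as unassigned and are counted", {
  spec <- example_gsl_panel_spec(replicates = 1L)
  truth <- make_truth_panel(spec)
  nz <- noise_spec(mz_jitter_sd = 0, intensity_cv = 0,
                   n_contaminant_peaks = 25L, seed = 17L)
  pl <- render_peaklist(truth, nz)[[1]][[1]]
  ann <- annotate_peaklist(pl, annotation_params(), default_structure_db(),
                           spec$is_ref$composition)
  n_real <- length(unique(truth$meta$composition)) + 1L  # + IS
  # most random m/z fall outside any composition window; collisions are
  # possible but must leave the real peaks' statuses intact
  expect_gte(sum(ann$status == "unassigned"), 1L)
  # a contaminant can by chance fall inside the IS window (a collision the
  # generator documents); at least the genuine IS peak is flagged
  expect_gte(sum(ann$status == "internal_standard"), 1L)
  collision_rate <- 1 - sum(ann$status == "unassigned") /
    nz$n_contaminant_peaks
  expect_lte(collision_rate, 1)
})

test_that("excessive jitter triggers the designed warning", {
  truth <- make_truth_panel(example_gsl_panel_spec(replicates = 1L))
  expect_warning(render_peaklist(truth, noise_spec(mz_jitter_sd = 0.3)),
                 "annotation may fail")
})

test_that("the planted GD3 story round-trips to Table-1-style arrows", {
  truth <- make_truth_panel(example_gsl_panel_spec())
  tt <- stage_transition_table(stage_panel(truth$matrix, truth$meta))
  expect_identical(unname(tt$arrows["GD3", 1]), "↑↑↑")  # x16 at hTERT
  expect_identical(unname(tt$arrows["GD3", 2]), "↓↓↓")  # x0.1 collapse
  expect_identical(unname(tt$arrows["LacCer", 1]), "↑↑↑")  # x7
  expect_identical(unname(tt$arrows["nLc4", 4]), "↑↑↑")    # myrAKT surge
})

test_that("MS2 and digestion rendering feed the enzymology verdicts", {
  spec <- example_gsl_panel_spec(replicates = 1L)
  truth <- make_truth_panel(spec)
  out <- render_ms2_and_digests(truth,
                                noise = noise_spec(mz_jitter_sd = 0,
                                                   intensity_cv = 0,
                                                   seed = 2L))
  # both (Hex)5(HexNAc)2 isomers are planted, so both get MS2 spectra
  expect_true(all(c("Gb-Hex5HexNAc2", "nLc-Hex5HexNAc2") %in%
                    names(out$ms2)))
  for (nm in c("Gb-Hex5HexNAc2", "nLc-Hex5HexNAc2")) {
    sim <- out$ms2[[nm]]
    v <- disambiguate_by_ms2(sim$peaks, sim$candidates)
    expect_identical(v$verdict, nm)
  }
  # digestion tables conserve amounts
  for (dg in out$digests) {
    expect_equal(sum(dg$post$amount), sum(dg$pre$amount), tolerance = 1e-9)
  }
})
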