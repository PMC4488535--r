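# Y-ion ladders, MS2 isomer resolution, digestion simulation.

db <- default_structure_db()
enz <- default_enzymes()

test_that("Y-ion ladders separate the isomeric (Hex)5(HexNAc)2 species", {
  nlc <- y_ion_ladder(db_lookup(db, name = "nLc-Hex5HexNAc2")[[1]], "aoWR")
  gb <- y_ion_ladder(db_lookup(db, name = "Gb-Hex5HexNAc2")[[1]], "aoWR")

  # the (neo)lacto ladder contains the 975.4 Hex2HexNAc1 signature ion
  expect_true(any(round(nlc$mz, 1) == 975.4))
  expect_true("(Hex)2(HexNAc)1" %in% nlc$composition)
  # the globo ladder has the Hex3 fragment but never Hex2HexNAc1
  expect_true("(Hex)3" %in% gb$composition)
  expect_false("(Hex)2(HexNAc)1" %in% gb$composition)

  # single-residue structure: no glycosidic bond, empty ladder
  expect_identical(nrow(y_ion_ladder(db_lookup(db, name = "Tn")[[1]],
                                     "bisPMP")), 0L)
})

test_that("fragments are lighter than and contained in the parent", {
  for (nm in c("GD1a", "A2", "NA4", "sialyl-core2", "GM2")) {
    rec <- db_lookup(db, name = nm)[[1]]
    scheme <- if (rec$glycome == "O") "bisPMP" else "aoWR"
    parent_mz <- derivatized_mz(rec$composition, scheme)
    lad <- y_ion_ladder(rec, scheme)
    expect_identical(nrow(lad), residue_count(rec$composition) - 1L)
    for (i in seq_len(nrow(lad))) {
      expect_lt(lad$mz[i], parent_mz)
      frag <- as_glycan_composition(lad$composition[i])
      expect_true(all(unclass(frag) <= unclass(rec$composition)))
    }
  }
})

test_that("MS2 spectra call single isomers, mixtures, and unresolved", {
  cands <- c(db_lookup(db, name = "Gb-Hex5HexNAc2"),
             db_lookup(db, name = "nLc-Hex5HexNAc2"))
  lad <- lapply(cands, y_ion_ladder, scheme = "aoWR")

  for (i in 1:2) {
    self <- data.frame(mz = lad[[i]]$mz, area = 100)
    v <- disambiguate_by_ms2(self, cands)
    expect_identical(v$verdict, cands[[i]]$name)
    expect_identical(v$series, cands[[i]]$series_or_class)
  }

  both <- data.frame(mz = c(lad[[1]]$mz, lad[[2]]$mz), area = 50)
  vm <- disambiguate_by_ms2(both, cands)
  expect_identical(vm$verdict, "mixture")
  expect_true(all(vm$diagnostics$matched_area > 0))

  empty <- data.frame(mz = numeric(0), area = numeric(0))
  expect_identical(disambiguate_by_ms2(empty, cands)$verdict, "unresolved")

  # identical ladders cannot be told apart
  twin <- cands[c(1, 1)]
  twin[[2]]$name <- "copy"
  expect_error(disambiguate_by_ms2(both, twin), "indistinguishable")
})

test_that("digestion removes exactly the enzyme's terminal residues", {
  nlc4 <- db_lookup(db, name = "nLc4")[[1]]
  out <- simulate_digest(list(list(record = nlc4, amount = 5)),
                         enz[["beta1,4-galactosidase"]])
  expect_identical(out$products$composition, "(Hex)2(HexNAc)1")
  expect_equal(out$products$amount, 5)
  expect_true(out$verdicts$nLc4$parent_lost)

  # Gb4 terminates in GalNAc: resistant to every galactosidase
  gb4 <- db_lookup(db, name = "Gb4")[[1]]
  for (e in enz[c("beta1,3-galactosidase", "beta1,4-galactosidase",
                  "beta1-3,6-galactosidase")]) {
    out <- simulate_digest(list(list(record = gb4, amount = 2)), e)
    expect_identical(out$products$composition, "(Hex)3(HexNAc)1")
    expect_false(out$verdicts$Gb4$parent_lost)
  }

  # alpha2,3-neuraminidase removes a2-3 sialic acids but not a2-6
  a2 <- db_lookup(db, name = "A2")[[1]]          # both sialics a2-6
  ssea4 <- db_lookup(db, name = "SSEA-4")[[1]]   # one a2-3 sialic
  out <- simulate_digest(list(list(record = a2, amount = 1),
                              list(record = ssea4, amount = 1)),
                         enz[["alpha2,3-neuraminidase"]])
  expect_false(out$verdicts$A2$parent_lost)
  expect_true(out$verdicts[["SSEA-4"]]$parent_lost)
  expect_identical(out$verdicts[["SSEA-4"]]$product_composition,
                   "(Hex)4(HexNAc)1")
})

test_that("digestion conserves total amount", {
  pool <- lapply(c("GM3", "GM1", "nLc4", "nLc6", "Gb4", "sialyl-nLc4"),
                 function(nm) list(record = db_lookup(db, name = nm)[[1]],
                                   amount = stats::runif(1, 1, 20)))
  total_in <- sum(vapply(pool, `[[`, numeric(1), "amount"))
  for (e in enz) {
    out <- simulate_digest(pool, e)
    expect_equal(sum(out$products$amount), total_in, tolerance = 1e-9)
  }
})

test_that("exhaustive digestion cascades along exposed termini", {
  # nLc6 under broad beta-galactosidase loses only the b1-4 terminal Gal
  # (the next Gal stays buried under GlcNAc), but an all-Gal chain is
  # stripped completely
  chain <- glycan_record("tri-Gal", "GSL", "other", "Galb1-3Galb1-3Galb1-4Glc")
  bg <- enz[["beta1-3,6-galactosidase"]]
  out <- simulate_digest(list(list(record = chain, amount = 1)), bg)
  # two b1-3 Gal removed one pass at a time; final b1-4 Gal resists
  expect_identical(out$products$composition, "(Hex)2")
  expect_identical(out$verdicts[["tri-Gal"]]$n_removed, 2L)

  once <- enzyme_spec(bg$name, bg$cleaves, exhaustive = FALSE)
  out1 <- simulate_digest(list(list(record = chain, amount = 1)), once)
  expect_identical(out1$verdicts[["tri-Gal"]]$n_removed, 1L)
})

test_that("the alpha2,6 fraction is recovered from pre/post tables", {
  # hand example: pre {A2: 10 x 2SA, A1: 10 x 1SA} = 30 SA-pmol,
  # post {A2: 2, A1: 4} = 8 SA-pmol -> 26.7%
  pre <- data.frame(composition = c("Hex5HexNAc4Neu5Ac2", "Hex5HexNAc4Neu5Ac1"),
                    amount = c(10, 10))
  post <- data.frame(composition = c("Hex5HexNAc4Neu5Ac2", "Hex5HexNAc4Neu5Ac1"),
                     amount = c(2, 4))
  expect_equal(alpha26_fraction(pre, post), 100 * 8 / 30)
  expect_equal(alpha26_fraction(pre, pre), 100)
  expect_equal(alpha26_fraction(pre, data.frame(composition = "Hex5HexNAc4",
                                                amount = 20)), 0)
  asialo <- data.frame(composition = "Hex5HexNAc4", amount = 10)
  expect_true(is.na(alpha26_fraction(asialo, asialo)))
})

test_that("planted linkage mixtures round-trip through digestion exactly", {
  # 10 pmol with two a2-6 caps (survive) + 15 pmol with two a2-3 caps
  # (fully desialylated): planted a2,6 share = 20 / 50 = 40%
  a26 <- db_lookup(db, name = "A2")[[1]]
  a23 <- glycan_record(
    "A2-a23", "N", "CH",
    "Neu5Aca2-3Galb1-4GlcNAcb1-2Mana1-3(Neu5Aca2-3Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4GlcNAc")
  pool <- list(list(record = a26, amount = 10),
               list(record = a23, amount = 15))
  out <- simulate_digest(pool, enz[["alpha2,3-neuraminidase"]])
  pre <- data.frame(
    composition = vapply(pool, function(p)
      format_composition(p$record$composition), character(1)),
    amount = vapply(pool, `[[`, numeric(1), "amount"))
  expect_equal(alpha26_fraction(pre, out$products), 40, tolerance = 1e-9)
  expect_equal(sum(out$products$amount), 25, tolerance = 1e-9)
})
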