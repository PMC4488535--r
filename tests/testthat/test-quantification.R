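# Internal-standard quantification, control subtraction, replicates.

.mini_annotations <- function(areas, is_area = 1e4) {
  # GM3 and Gb4 peaks plus the A2GN1 internal standard
  db <- default_structure_db()
  is_comp <- "(Hex)5(HexNAc)3(Neu5Ac)2"
  peaks <- data.frame(
    mz = c(derivatized_mz("Hex2Neu5Ac1", "aoWR"),
           derivatized_mz("Hex3HexNAc1", "aoWR"),
           derivatized_mz(is_comp, "aoWR")),
    area = c(areas, is_area)
  )
  annotate_peaklist(peaks, annotation_params(), db, is_comp)
}

test_that("amounts follow the internal-standard ratio and protein scale", {
  # area 30000 vs IS 10000 at 10 pmol, 250 ug protein -> 12 pmol/100 ug
  q <- quantify(.mini_annotations(c(30000, 10000)),
                internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10),
                protein_amount = 250)
  expect_equal(q$amount[q$composition == "(Hex)2(Neu5Ac)1"], 12)
  # area equal to IS area at 100 ug -> amount equals the spiked amount
  expect_equal(q$amount[q$composition == "(Hex)3(HexNAc)1"], 4)
  q2 <- quantify(.mini_annotations(c(10000, 10000)),
                 internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10),
                 protein_amount = 100)
  expect_equal(q2$amount, c(10, 10))
  # IS itself never appears in the output
  expect_false("(Hex)5(HexNAc)3(Neu5Ac)2" %in% q$composition)
})

test_that("quantification is linear in areas", {
  is_ref <- internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10)
  base <- quantify(.mini_annotations(c(25000, 5000), 1e4), is_ref, 100)
  # scaling everything (analytes and IS) leaves amounts unchanged
  all_scaled <- quantify(.mini_annotations(c(25000, 5000) * 3.7, 3.7e4),
                         is_ref, 100)
  expect_equal(all_scaled$amount, base$amount, tolerance = 1e-12)
  # scaling only analytes scales amounts
  part_scaled <- quantify(.mini_annotations(c(25000, 5000) * 2, 1e4),
                          is_ref, 100)
  expect_equal(part_scaled$amount, base$amount * 2, tolerance = 1e-12)
})

test_that("invalid metadata and absent standards are rejected", {
  is_ref <- internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10)
  expect_error(quantify(.mini_annotations(c(1, 1)), is_ref, 0),
               "protein_amount")
  expect_error(quantify(.mini_annotations(c(1, 1)), is_ref, -10),
               "protein_amount")
  expect_error(internal_standard("A2GN1", "(HexNAc)4", 0))
  ann <- .mini_annotations(c(1, 1))
  ann$status[ann$status == "internal_standard"] <- "assigned"
  expect_error(quantify(ann, is_ref, 100), "missing internal standard")
  ann2 <- .mini_annotations(c(1, 1), is_area = 0)
  expect_error(quantify(ann2, is_ref, 100), "zero")
})

test_that("species below m/z 1000 carry the low-mass caveat flag", {
  is_comp <- "(Hex)5(HexNAc)3(Neu5Ac)2"
  peaks <- data.frame(
    mz = c(derivatized_mz("Hex2", "aoWR"),         # LacCer glycan, ~772
           derivatized_mz("Hex3HexNAc1", "aoWR"),  # Gb4 glycan, ~1120
           derivatized_mz(is_comp, "aoWR")),
    area = c(100, 100, 1e4))
  ann <- annotate_peaklist(peaks, annotation_params(),
                           default_structure_db(), is_comp)
  q <- quantify(ann, internal_standard("A2GN1", is_comp, 10), 100)
  expect_true(q$low_mass[q$composition == "(Hex)2"])
  expect_false(q$low_mass[q$composition == "(Hex)3(HexNAc)1"])
})

test_that("control subtraction clips at zero, flags, and is idempotent", {
  is_ref <- internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10)
  sample <- quantify(.mini_annotations(c(10000, 5000)), is_ref, 100)
  ctl_full <- quantify(.mini_annotations(c(1, 5000)), is_ref, 100)
  ctl_full <- ctl_full[ctl_full$composition == "(Hex)3(HexNAc)1", ]
  class(ctl_full) <- class(sample)

  out <- subtract_control(sample, ctl_full)
  expect_equal(out$amount[out$composition == "(Hex)3(HexNAc)1"], 0)
  expect_identical(out$control_flag[out$composition == "(Hex)3(HexNAc)1"],
                   "excluded_in_control")
  expect_identical(out$control_flag[out$composition == "(Hex)2(Neu5Ac)1"],
                   "clean")

  # partial subtraction
  ctl_part <- quantify(.mini_annotations(c(2500, 1)), is_ref, 100)
  ctl_part <- ctl_part[ctl_part$composition == "(Hex)2(Neu5Ac)1", ]
  class(ctl_part) <- class(sample)
  out2 <- subtract_control(sample, ctl_part)
  expect_equal(out2$amount[out2$composition == "(Hex)2(Neu5Ac)1"], 7.5)
  expect_identical(out2$control_flag[out2$composition == "(Hex)2(Neu5Ac)1"],
                   "control_subtracted")

  # idempotence: re-subtracting an already clipped table with the same
  # control only re-clips what the control already consumed
  expect_equal(subtract_control(out, ctl_full)$amount, out$amount)

  # empty control is the identity
  empty <- sample[0, ]
  class(empty) <- class(sample)
  expect_equal(subtract_control(sample, empty), sample)
})

test_that("replicate aggregation follows the n-dependent dispersion rule", {
  is_ref <- internal_standard("A2GN1", "(Hex)5(HexNAc)3(Neu5Ac)2", 10)
  reps <- lapply(c(10000, 12000, 14000), function(a) {
    quantify(.mini_annotations(c(a, 5000)), is_ref, 100)
  })
  agg <- aggregate_replicates(reps)
  gm3 <- agg[agg$composition == "(Hex)2(Neu5Ac)1", ]
  expect_equal(gm3$replicate_mean, 12)
  expect_equal(gm3$replicate_dispersion, 2)   # sample sd of 10, 12, 14
  expect_identical(gm3$dispersion_kind, "sd")

  agg2 <- aggregate_replicates(reps[c(1, 3)])
  gm3_2 <- agg2[agg2$composition == "(Hex)2(Neu5Ac)1", ]
  expect_equal(gm3_2$replicate_mean, 12)
  expect_equal(gm3_2$replicate_dispersion, 2)  # half-range of 10, 14
  expect_identical(gm3_2$dispersion_kind, "range/2")

  agg1 <- aggregate_replicates(reps[1])
  expect_equal(agg1$replicate_dispersion, c(0, 0))
  expect_identical(unique(agg1$dispersion_kind), "single")

  # a glycan missing from one replicate counts as zero there
  reps_m <- reps
  reps_m[[2]] <- reps_m[[2]][reps_m[[2]]$composition != "(Hex)2(Neu5Ac)1", ]
  class(reps_m[[2]]) <- class(reps[[2]])
  aggm <- aggregate_replicates(reps_m)
  expect_equal(aggm$replicate_mean[aggm$composition == "(Hex)2(Neu5Ac)1"],
               mean(c(10, 0, 14)))
  expect_error(aggregate_replicates(list()), "no replicate")
})
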