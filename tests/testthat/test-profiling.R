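# Class totals, arrow codes, transition tables, clustering.

.toy_panel <- function() {
  m <- rbind(
    GM3 = c(70, 70, 20, 10, 8),
    Gb4 = c(2, 2, 8, 30, 60),
    nLc4 = c(28, 28, 12, 10, 100)
  )
  colnames(m) <- c("NHA", "NHA/T", "NHA/TS", "NHA/TSR", "NHA/TSRA")
  stage_panel(m, data.frame(series = c("Gg", "Gb", "nLc")))
}

test_that("class totals conserve stage sums and normalize to 100", {
  ct <- class_totals(.toy_panel(), "series")
  expect_equal(colSums(ct$totals), colSums(.toy_panel()$matrix))
  expect_equal(unname(colSums(ct$percent)), rep(100, 5))
  expect_equal(unname(ct$percent[, "NHA"]), c(2, 70, 28))

  # an all-zero stage reports absent percentages
  m <- .toy_panel()$matrix
  m[, 2] <- 0
  p2 <- stage_panel(m, .toy_panel()$meta)
  ct2 <- class_totals(p2, "series")
  expect_true(all(is.na(ct2$percent[, 2])))
  expect_false(anyNA(ct2$percent[, -2]))
})

test_that("arrow codes bin folds with boundaries on the milder symbol", {
  expect_identical(arrow_code(16), "↑↑↑")
  expect_identical(arrow_code(1.0), "→")
  expect_identical(arrow_code(0.3), "↓↓")
  expect_identical(arrow_code(7), "↑↑↑")
  expect_identical(arrow_code(0.1), "↓↓↓")
  # documented boundary assignments
  expect_identical(unname(arrow_code(c(0.2, 0.5, 0.75, 1.25, 2, 5))),
                   c("↓↓", "↓", "→", "→",
                     "↑", "↑↑"))
  # zero-baseline extensions
  expect_identical(arrow_code(Inf), "new")
  expect_identical(arrow_code(NaN), "absent")
  expect_error(arrow_code(-0.5), "non-negative")
})

test_that("every non-negative fold maps to exactly one symbol", {
  set.seed(21)
  folds <- c(stats::runif(200, 0, 8), 0, stats::rexp(50, 0.1))
  codes <- arrow_code(folds)
  expect_false(anyNA(codes))
  expect_true(all(codes %in% c("↓↓↓", "↓↓",
                               "↓", "→", "↑",
                               "↑↑", "↑↑↑")))
})

test_that("transition tables encode planted folds and derived features", {
  panel <- .toy_panel()
  tt <- stage_transition_table(panel)
  expect_identical(dim(tt$arrows), c(3L, 4L))
  expect_identical(unname(tt$arrows["GM3", ]),
                   c("→", "↓↓", "↓", "→"))
  expect_identical(unname(tt$arrows["Gb4", 1]), "→")
  expect_identical(unname(tt$arrows["nLc4", 4]), "↑↑↑")

  # derived feature: series total via class_totals
  tt2 <- stage_transition_table(panel, features = list(
    "total Gg" = function(p) class_totals(p, "series")$totals["Gg", ],
    GM3 = "GM3"))
  expect_identical(unname(tt2$arrows["total Gg", ]),
                   unname(tt$arrows["GM3", ]))

  expect_error(stage_transition_table(panel, features = list(x = "nope")),
               "unknown feature")
})

test_that("identical columns merge first at height zero", {
  res <- hcluster(.toy_panel())
  expect_equal(min(res$stage_tree$height), 0, tolerance = 1e-12)
  first <- res$stage_tree$merge[1, ]
  expect_setequal(res$stage_tree$labels[-first], c("NHA", "NHA/T"))
  expect_identical(res$groups[["NHA"]], res$groups[["NHA/T"]])
})

test_that("clustering matches the brute-force average-linkage oracle", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(stats::runif(6 * 20, 0, 50), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
    res <- hcluster(stage_panel(m), metric = "uncentered",
                    linkage = "average", cluster_rows = FALSE)
    d_oracle <- oracle_uncentered_dist(m)
    expect_equal(res$distance, d_oracle, tolerance = 1e-12)
    coph <- as.matrix(stats::cophenetic(res$stage_tree))
    want <- oracle_upgma_cophenetic(d_oracle)
    expect_equal(coph[rownames(want), colnames(want)], want,
                 tolerance = 1e-9)
  }
})

test_that("clustering is invariant to row permutation", {
  set.seed(41)
  m <- matrix(stats::rlnorm(5 * 12), nrow = 12,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  r1 <- hcluster(stage_panel(m), cluster_rows = FALSE)
  r2 <- hcluster(stage_panel(m[sample(12), ]), cluster_rows = FALSE)
  expect_identical(r1$leaf_order, r2$leaf_order)
  expect_equal(r1$stage_tree$height, r2$stage_tree$height)
})

test_that("planted two-group panels split at k = 2", {
  set.seed(51)
  for (rep in 1:10) {
    p1 <- stats::runif(15, 10, 20)
    p2 <- p1 + 100                      # far between-group separation
    m <- cbind(A = p1 + stats::rnorm(15, 0, 0.5),
               B = p1 + stats::rnorm(15, 0, 0.5),
               C = p2 + stats::rnorm(15, 0, 0.5),
               D = p2 + stats::rnorm(15, 0, 0.5),
               E = p2 + stats::rnorm(15, 0, 0.5))
    rownames(m) <- paste0("g", 1:15)
    res <- hcluster(stage_panel(m), metric = "euclidean", k = 2,
                    cluster_rows = FALSE)
    expect_identical(res$groups[["A"]], res$groups[["B"]])
    expect_identical(res$groups[["C"]], res$groups[["D"]])
    expect_identical(res$groups[["D"]], res$groups[["E"]])
    expect_false(res$groups[["A"]] == res$groups[["C"]])
  }
})

test_that("cluster trees export as Newick text", {
  res <- hcluster(.toy_panel())
  nwk <- cluster_newick(res)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "NHA")
  tmp <- tempfile(fileext = ".newick")
  cluster_newick(res, tmp)
  expect_true(file.exists(tmp))
  phy <- ape::read.tree(tmp)
  expect_setequal(phy$tip.label, colnames(.toy_panel()$matrix))
})
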