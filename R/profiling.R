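# Stage-to-stage differential summaries: class totals, fold-change arrow
# matrices, and hierarchical clustering of stage profiles.

.ARROWS <- c(down3 = "\u2193\u2193\u2193", down2 = "\u2193\u2193",
             down1 = "\u2193", flat = "\u2192",
             up1 = "\u2191", up2 = "\u2191\u2191",
             up3 = "\u2191\u2191\u2191",
             new = "new", absent = "absent")

#' Stage panel
#'
#' A glycan-by-stage matrix of absolute amounts (pmol per 100 ug protein)
#' with per-glycan metadata. Stage order is meaningful: each transition
#' from stage i to i+1 corresponds to one introduced genetic element.
#'
#' @param matrix Numeric matrix, glycans in rows, stages in columns
#'   (non-negative amounts). Row and column names required.
#' @param meta Data frame with one row per glycan (same order as matrix
#'   rows); typically columns `glycome` and `series_or_class`. Optional.
#' @return An object of class `stage_panel` with fields `stages`,
#'   `matrix`, `meta`.
#' @export
stage_panel <- function(matrix, meta = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  if (any(matrix < 0)) stop("amounts must be non-negative", call. = FALSE)
  if (is.null(meta)) {
    meta <- data.frame(row.names = rownames(matrix))
  }
  stopifnot(nrow(meta) == nrow(matrix))
  rownames(meta) <- rownames(matrix)
  structure(list(stages = colnames(matrix), matrix = matrix, meta = meta),
            class = "stage_panel")
}

#' @export
print.stage_panel <- function(x, ...) {
  cat(sprintf("<stage_panel> %d glycans x %d stages (%s)\n",
              nrow(x$matrix), length(x$stages),
              paste(x$stages, collapse = ", ")))
  invisible(x)
}

#' Group totals and within-stage percentages
#'
#' Sums panel amounts by a metadata key (e.g. GSL series or N-glycan
#' family) per stage; group totals conserve the stage totals exactly.
#'
#' @param panel A [stage_panel()].
#' @param group_by Name of a `panel$meta` column present for all glycans.
#' @return A list with `totals` (group x stage matrix) and `percent`
#'   (within-stage percentages, columns summing to 100; `NA` for an
#'   all-zero stage).
#' @export
class_totals <- function(panel, group_by) {
  stopifnot(inherits(panel, "stage_panel"),
            group_by %in% names(panel$meta))
  g <- panel$meta[[group_by]]
  if (anyNA(g)) stop("metadata key '", group_by,
                     "' is missing for some glycans", call. = FALSE)
  totals <- rowsum(panel$matrix, group = g)
  stage_sum <- colSums(totals)
  percent <- sweep(totals, 2L, stage_sum, "/") * 100
  percent[, stage_sum == 0] <- NA_real_
  list(totals = totals, percent = percent)
}

#' Encode a fold change as an arrow symbol
#'
#' Bins (boundaries assigned to the milder symbol):
#' down3 `[0, 0.2)`, down2 `[0.2, 0.5)`, down1 `[0.5, 0.75)`,
#' flat `[0.75, 1.25]`, up1 `(1.25, 2]`, up2 `(2, 5]`, up3 `(5, Inf)`.
#' A zero baseline with a positive value is `"new"`, zero over zero is
#' `"absent"` (the arrow scheme is extended to zero baselines to avoid
#' infinite folds).
#'
#' @param fold Non-negative fold change(s); `Inf` encodes appearance from a
#'   zero baseline, `NaN` absence in both stages.
#' @return Character vector of symbols (up/down arrows, the right arrow,
#'   `"new"`, `"absent"`).
#' @examples
#' arrow_code(16)    # three up arrows
#' arrow_code(1.0)   # right arrow
#' arrow_code(0.3)   # two down arrows
#' @export
arrow_code <- function(fold) {
  vapply(fold, function(f) {
    if (is.nan(f)) return(.ARROWS[["absent"]])
    if (is.infinite(f)) return(.ARROWS[["new"]])
    if (is.na(f) || f < 0) stop("fold must be non-negative", call. = FALSE)
    if (f < 0.2) .ARROWS[["down3"]]
    else if (f < 0.5) .ARROWS[["down2"]]
    else if (f < 0.75) .ARROWS[["down1"]]
    else if (f <= 1.25) .ARROWS[["flat"]]
    else if (f <= 2) .ARROWS[["up1"]]
    else if (f <= 5) .ARROWS[["up2"]]
    else .ARROWS[["up3"]]
  }, character(1))
}

#' Stage-transition arrow matrix
#'
#' For each feature — a panel row or a derived per-stage summary — the
#' fold change across every consecutive stage transition is computed and
#' encoded with [arrow_code()].
#'
#' @param panel A [stage_panel()] with at least 2 stages.
#' @param features Named list. Each element is either a glycan (row) name
#'   or a function taking the panel and returning one value per stage
#'   (e.g. a series total or a Neu5Gc percentage). Defaults to all rows.
#' @return A list of class `transition_table` with `folds` (numeric
#'   feature x transition matrix) and `arrows` (matching symbol matrix);
#'   transition columns are named `"stage_i->stage_i+1"`.
#' @export
stage_transition_table <- function(panel, features = NULL) {
  stopifnot(inherits(panel, "stage_panel"), length(panel$stages) >= 2L)
  if (is.null(features)) {
    features <- stats::setNames(as.list(rownames(panel$matrix)),
                                rownames(panel$matrix))
  }
  values <- t(vapply(names(features), function(nm) {
    f <- features[[nm]]
    if (is.character(f)) {
      if (!f %in% rownames(panel$matrix)) {
        stop("unknown feature '", f, "'; available rows: ",
             paste(rownames(panel$matrix), collapse = ", "), call. = FALSE)
      }
      panel$matrix[f, ]
    } else if (is.function(f)) {
      v <- f(panel)
      stopifnot(length(v) == length(panel$stages))
      v
    } else stop("feature must be a row name or a function", call. = FALSE)
  }, numeric(length(panel$stages))))

  k <- length(panel$stages)
  folds <- values[, -1L, drop = FALSE] / values[, -k, drop = FALSE]
  colnames(folds) <- paste(panel$stages[-k], panel$stages[-1L], sep = "->")
  arrows <- apply(folds, c(1L, 2L), arrow_code)
  structure(list(values = values, folds = folds, arrows = arrows),
            class = "transition_table")
}

# Uncentered Pearson correlation distance between matrix columns, with a
# zero-variance guard: a column with zero norm has similarity 0 (distance
# 1) to everything.
.uncentered_cor_dist <- function(m) {
  norms <- sqrt(colSums(m^2))
  k <- ncol(m)
  sim <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      sim[i, j] <- if (norms[i] == 0 || norms[j] == 0) 0
                   else sum(m[, i] * m[, j]) / (norms[i] * norms[j])
    }
  }
  diag(sim) <- 1
  1 - sim
}

.panel_dist <- function(m, metric) {
  switch(metric,
    uncentered = stats::as.dist(.uncentered_cor_dist(m)),
    pearson = {
      v <- apply(m, 2L, stats::var)
      cc <- suppressWarnings(stats::cor(m))
      cc[v == 0, ] <- 0
      cc[, v == 0] <- 0
      stats::as.dist(1 - cc)
    },
    euclidean = stats::dist(t(m)),
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Hierarchical clustering of stage profiles
#'
#' Agglomerative clustering of the stage columns (and optionally the
#' glycan rows) of a panel. The default distance is the uncentered Pearson
#' correlation distance and the default linkage is average — the classic
#' defaults of Eisen-style clustering of abundance matrices; amounts are
#' used untransformed.
#'
#' @param panel A [stage_panel()] (or a plain numeric matrix) with >= 2
#'   stages and >= 2 glycans.
#' @param metric `"uncentered"` (default), `"pearson"` or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param k Number of flat groups to cut the stage tree into (default 2).
#' @param cluster_rows Also cluster glycan rows (default `TRUE`).
#' @return A list of class `cluster_result`: `stage_tree` (an
#'   [stats::hclust] object), `leaf_order` (stage labels in dendrogram
#'   order), `groups` (flat stage groups at `k`), `distance` (stage
#'   distance matrix), `row_tree` (or `NULL`), `metric`, `linkage`.
#' @export
hcluster <- function(panel, metric = c("uncentered", "pearson", "euclidean"),
                     linkage = c("average", "complete", "single"),
                     k = 2L, cluster_rows = TRUE) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- if (inherits(panel, "stage_panel")) panel$matrix else panel
  stopifnot(is.matrix(m), ncol(m) >= 2L, nrow(m) >= 2L)
  d <- .panel_dist(m, metric)
  tree <- stats::hclust(d, method = linkage)
  row_tree <- if (cluster_rows && nrow(m) >= 3L) {
    stats::hclust(.panel_dist(t(m), metric), method = linkage)
  } else NULL
  structure(
    list(stage_tree = tree,
         leaf_order = tree$labels[tree$order],
         groups = stats::cutree(tree, k = min(k, ncol(m))),
         distance = as.matrix(d),
         row_tree = row_tree,
         metric = metric, linkage = linkage),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s distance, %s linkage\nleaf order: %s\n",
              x$metric, x$linkage, paste(x$leaf_order, collapse = ", ")))
  invisible(x)
}

#' Export a cluster tree as Newick text
#'
#' @param result A [hcluster()] result.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
cluster_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  phy <- ape::as.phylo(result$stage_tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write an arrow matrix (and its folds) to CSV
#'
#' @param tt A [stage_transition_table()] result.
#' @param arrows_path,folds_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, the list of written paths.
#' @export
write_transition_csv <- function(tt, arrows_path = NULL, folds_path = NULL) {
  stopifnot(inherits(tt, "transition_table"))
  if (!is.null(arrows_path)) {
    utils::write.csv(as.data.frame(tt$arrows), arrows_path)
  }
  if (!is.null(folds_path)) {
    utils::write.csv(as.data.frame(tt$folds), folds_path)
  }
  invisible(list(arrows = arrows_path, folds = folds_path))
}
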