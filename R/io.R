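# File I/O and pipeline orchestration: peak-list reading, run configuration
# and the annotate -> quantify -> classify -> profile pipeline. The exported
# functions are the package's interface; they are what a wrapper script
# would call.

#' Read a centroided peak list
#'
#' Reads a TSV or CSV peak list with columns `mz`, `area` and optionally
#' `snr` (the separator is sniffed from the header line). Rows are returned
#' sorted by ascending m/z; when both a threshold and an `snr` column are
#' present, sub-threshold rows are dropped.
#'
#' @param path Peak-list file.
#' @param snr_threshold Optional signal-to-noise cutoff (the conventional
#'   peak-picking threshold is 1.5).
#' @return Data frame with columns `mz`, `area` (and `snr` if present).
#' @export
read_peaklist <- function(path, snr_threshold = NULL) {
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "#")
  for (col in c("mz", "area")) {
    if (!col %in% names(df)) {
      stop("peak list ", path, ": missing mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  for (col in intersect(c("mz", "area", "snr"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("peak list ", path, ": non-numeric '", col, "' at line ",
           bad[1] + 1L, call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(df$mz <= 0, na.rm = TRUE)) {
    stop("peak list ", path, ": non-positive m/z", call. = FALSE)
  }
  if (!is.null(snr_threshold) && "snr" %in% names(df)) {
    df <- df[is.na(df$snr) | df$snr >= snr_threshold, , drop = FALSE]
  }
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.validate_config <- function(config) {
  req <- c("glycome", "internal_standard", "samples", "stages")
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    stop("invalid run config: missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  is_cfg <- config$internal_standard
  for (f in c("name", "composition", "spiked_amount")) {
    if (is.null(is_cfg[[f]])) {
      stop("invalid run config: internal_standard$", f, " is required",
           call. = FALSE)
    }
  }
  if (!is.numeric(is_cfg$spiked_amount) || is_cfg$spiked_amount <= 0) {
    stop("invalid run config: internal_standard$spiked_amount must be > 0",
         call. = FALSE)
  }
  for (s in config$samples) {
    for (f in c("stage", "replicate", "path", "protein_amount")) {
      if (is.null(s[[f]])) {
        stop("invalid run config: every sample needs '", f, "'",
             call. = FALSE)
      }
    }
    if (!s$stage %in% config$stages) {
      stop("invalid run config: sample stage '", s$stage,
           "' not in stages", call. = FALSE)
    }
    if (!file.exists(s$path)) {
      stop("invalid run config: sample file not found: ", s$path,
           call. = FALSE)
    }
  }
  for (s in config$controls %||% list()) {
    if (!file.exists(s$path)) {
      stop("invalid run config: control file not found: ", s$path,
           call. = FALSE)
    }
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.provenance_header <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  # the hash covers the analytical inputs, not where results are written
  config$out_dir <- NULL
  yaml::write_yaml(config, tmp)
  c(sprintf("# glycopanel %s",
            as.character(utils::packageVersion("glycopanel"))),
    sprintf("# config_md5=%s", unname(tools::md5sum(tmp))),
    sprintf("# seed=%s", config$seed %||% "none"))
}

.write_table_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full profiling pipeline from a configuration
#'
#' Executes annotate -> quantify -> subtract control (GSL only) ->
#' aggregate replicates -> classify -> stage profiling (arrow matrix and
#' hierarchical clustering). The configuration is schema-validated before
#' any file is read; any stage failure is reported with the stage and
#' sample that caused it.
#'
#' Configuration (a YAML file path or an equivalent nested list):
#' \describe{
#'   \item{glycome}{`"N"`, `"O"` or `"GSL"`. Determines the default scheme
#'     (bis-PMP for O-glycans, aoWR otherwise) and whether negative-control
#'     subtraction applies (GSL only).}
#'   \item{stages}{Ordered stage labels.}
#'   \item{samples}{List of `stage`, `replicate`, `path`,
#'     `protein_amount` (ug) entries.}
#'   \item{controls}{Optional per-stage negative-control samples
#'     (`stage`, `path`, `protein_amount`).}
#'   \item{internal_standard}{`name`, `composition`, `spiked_amount`
#'     (pmol).}
#'   \item{tolerance, snr_threshold, scheme}{Optional annotation settings
#'     (defaults 0.5 Da, 1.5, glycome-dependent scheme).}
#'   \item{clustering}{Optional `metric`, `linkage`, `k`.}
#'   \item{out_dir}{Optional output directory for the CSV bundle.}
#'   \item{seed}{Optional integer recorded in output headers.}
#' }
#'
#' @param config YAML path or config list.
#' @param db A [structure_db()].
#' @return A result bundle (list): `annotations`, `quantified` (per stage,
#'   replicate-aggregated), `panel` (a [stage_panel()] of replicate
#'   means), `classification` (per-glycan class columns), `transitions`
#'   (arrow matrix), `clustering` (a [hcluster()] result, when >= 2 stages
#'   and glycans), and `config`.
#' @export
run_pipeline <- function(config, db = default_structure_db()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_config(config)

  glycome <- match.arg(config$glycome, c("N", "O", "GSL"))
  scheme <- config$scheme %||% if (glycome == "O") "bisPMP" else "aoWR"
  params <- annotation_params(
    tolerance = config$tolerance %||% 0.5,
    scheme = scheme,
    snr_threshold = config$snr_threshold %||% 1.5
  )
  is_ref <- internal_standard(config$internal_standard$name,
                              config$internal_standard$composition,
                              config$internal_standard$spiked_amount)

  step <- function(stage_name, sample_id, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s | %s] %s", stage_name, sample_id,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # negative controls, quantified once per stage
  controls <- list()
  for (ctl in config$controls %||% list()) {
    ann <- step("annotate", paste0("control:", ctl$stage), {
      annotate_peaklist(read_peaklist(ctl$path), params, db,
                        is_ref$composition)
    })
    controls[[ctl$stage]] <- step("quantify", paste0("control:", ctl$stage),
                                  quantify(ann, is_ref, ctl$protein_amount))
  }

  annotations <- list()
  quant_by_stage <- stats::setNames(
    vector("list", length(config$stages)), config$stages)
  for (s in config$samples) {
    id <- paste0(s$stage, "/rep", s$replicate)
    ann <- step("annotate", id, {
      annotate_peaklist(read_peaklist(s$path), params, db,
                        is_ref$composition)
    })
    annotations[[id]] <- ann
    q <- step("quantify", id, quantify(ann, is_ref, s$protein_amount))
    if (glycome == "GSL" && !is.null(controls[[s$stage]])) {
      q <- step("subtract_control", id,
                subtract_control(q, controls[[s$stage]]))
    }
    quant_by_stage[[s$stage]] <- c(quant_by_stage[[s$stage]], list(q))
  }

  quantified <- lapply(config$stages, function(st) {
    reps <- quant_by_stage[[st]]
    if (is.null(reps)) return(NULL)
    step("aggregate", st, aggregate_replicates(reps))
  })
  names(quantified) <- config$stages
  quantified <- Filter(Negate(is.null), quantified)

  # glycan x stage matrix of replicate means
  comps <- unique(unlist(lapply(quantified, `[[`, "composition")))
  m <- vapply(names(quantified), function(st) {
    tb <- quantified[[st]]
    vapply(comps, function(cc) {
      i <- match(cc, tb$composition)
      if (is.na(i)) 0 else tb$replicate_mean[i]
    }, numeric(1))
  }, numeric(length(comps)))
  m <- matrix(m, nrow = length(comps),
              dimnames = list(comps, names(quantified)))

  classification <- data.frame(
    composition = comps,
    class = vapply(comps, function(cc) {
      switch(glycome,
        GSL = classify_gsl(cc, db)$series,
        N = tryCatch(classify_n(cc)$family, error = function(e) "other"),
        O = tryCatch(classify_o(cc)$core, error = function(e) "other"))
    }, character(1)),
    sialic_count = vapply(comps, function(cc)
      sialic_count(as_glycan_composition(cc)), integer(1)),
    stringsAsFactors = FALSE
  )
  panel <- stage_panel(m, data.frame(
    glycome = glycome,
    series_or_class = classification$class,
    stringsAsFactors = FALSE
  ))

  transitions <- if (ncol(m) >= 2L) stage_transition_table(panel) else NULL
  clustering <- if (ncol(m) >= 2L && nrow(m) >= 2L) {
    cl <- config$clustering %||% list()
    hcluster(panel, metric = cl$metric %||% "uncentered",
             linkage = cl$linkage %||% "average", k = cl$k %||% 2L)
  } else NULL

  bundle <- list(annotations = annotations, quantified = quantified,
                 panel = panel, classification = classification,
                 transitions = transitions, clustering = clustering,
                 config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .provenance_header(config)
    for (st in names(quantified)) {
      .write_table_with_header(
        quantified[[st]],
        file.path(config$out_dir,
                  paste0("quantified_", gsub("/", "-", st), ".csv")), hdr)
    }
    .write_table_with_header(
      classification, file.path(config$out_dir, "classification.csv"), hdr)
    if (!is.null(transitions)) {
      .write_table_with_header(
        as.data.frame(transitions$arrows),
        file.path(config$out_dir, "transition_arrows.csv"), hdr)
      .write_table_with_header(
        as.data.frame(transitions$folds),
        file.path(config$out_dir, "transition_folds.csv"), hdr)
    }
    if (!is.null(clustering)) {
      cluster_newick(clustering,
                     file.path(config$out_dir, "stage_tree.newick"))
      writeLines(clustering$leaf_order,
                 file.path(config$out_dir, "leaf_order.txt"))
    }
  }
  bundle
}
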