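# Independent oracles used across the suite. These deliberately share no
# code with the package: masses are assembled atom by atom from a separate
# elemental table, candidate enumeration is a naive quintuple loop, and
# agglomeration is a literal re-merge of cluster lists.

# --- elemental-formula mass oracle ----------------------------------------

# atoms per residue / adduct, counted by hand from the structures
.oracle_atoms <- list(
  hex    = c(C = 6,  H = 10, N = 0, O = 5),
  hexnac = c(C = 8,  H = 13, N = 1, O = 5),
  dhex   = c(C = 6,  H = 10, N = 0, O = 4),
  neu5ac = c(C = 11, H = 17, N = 1, O = 8),
  neu5gc = c(C = 11, H = 17, N = 1, O = 9),
  water  = c(C = 0,  H = 2,  N = 0, O = 1),
  aoWR   = c(C = 20, H = 29, N = 7, O = 5),  # before oxime water loss
  pmp    = c(C = 10, H = 10, N = 2, O = 1),
  ch2    = c(C = 1,  H = 2,  N = 0, O = 0)
)

.oracle_atomic_mass <- c(C = 12.0, H = 1.00782503207,
                         N = 14.0030740048, O = 15.9949146196)
.oracle_proton <- 1.00727646688

oracle_atoms_mass <- function(atoms) {
  sum(atoms * .oracle_atomic_mass[names(atoms)])
}

# free reducing glycan: total atom tally of residues + one water
oracle_free_mass <- function(hex = 0, hexnac = 0, dhex = 0,
                             neu5ac = 0, neu5gc = 0) {
  atoms <- hex * .oracle_atoms$hex + hexnac * .oracle_atoms$hexnac +
    dhex * .oracle_atoms$dhex + neu5ac * .oracle_atoms$neu5ac +
    neu5gc * .oracle_atoms$neu5gc + .oracle_atoms$water
  oracle_atoms_mass(atoms)
}

oracle_mz <- function(hex = 0, hexnac = 0, dhex = 0, neu5ac = 0,
                      neu5gc = 0, scheme = "aoWR") {
  base <- oracle_free_mass(hex, hexnac, dhex, neu5ac, neu5gc)
  label <- switch(scheme,
    aoWR = oracle_atoms_mass(.oracle_atoms$aoWR) -
      oracle_atoms_mass(.oracle_atoms$water),
    bisPMP = 2 * oracle_atoms_mass(.oracle_atoms$pmp) -
      oracle_atoms_mass(.oracle_atoms$water),
    none = 0
  )
  ester <- if (scheme == "aoWR") {
    (neu5ac + neu5gc) * oracle_atoms_mass(.oracle_atoms$ch2)
  } else 0
  base + label + ester + .oracle_proton
}

# --- naive quintuple-loop candidate enumeration ---------------------------

# builds the full composition list by explicit nested loops (computed once
# per bounds/scheme and cached), then filters and orders with its own rule
.oracle_enum_cache <- new.env(parent = emptyenv())

oracle_composition_table <- function(bounds, scheme) {
  key <- paste(c(bounds, scheme), collapse = "|")
  if (!is.null(.oracle_enum_cache[[key]])) {
    return(.oracle_enum_cache[[key]])
  }
  rows <- vector("list", prod(bounds + 1L))
  n <- 0L
  for (h in 0:bounds[["hex"]])
    for (hn in 0:bounds[["hexnac"]])
      for (dh in 0:bounds[["dhex"]])
        for (na in 0:bounds[["neu5ac"]])
          for (ng in 0:bounds[["neu5gc"]]) {
            if (h + hn + dh + na + ng < 1) next
            n <- n + 1L
            rows[[n]] <- c(h, hn, dh, na, ng,
                           oracle_mz(h, hn, dh, na, ng, scheme))
          }
  tab <- do.call(rbind, rows[seq_len(n)])
  colnames(tab) <- c("hex", "hexnac", "dhex", "neu5ac", "neu5gc", "mz")
  .oracle_enum_cache[[key]] <- tab
  tab
}

oracle_enumerate <- function(mz, tolerance, bounds, scheme) {
  tab <- oracle_composition_table(bounds, scheme)
  err <- tab[, "mz"] - mz
  hit <- which(abs(err) <= tolerance)
  tab <- tab[hit, , drop = FALSE]
  err <- err[hit]
  total <- rowSums(tab[, 1:5, drop = FALSE])
  o <- order(round(abs(err), 6), total, -tab[, "hex"], -tab[, "hexnac"],
             -tab[, "dhex"], -tab[, "neu5ac"], -tab[, "neu5gc"])
  list(counts = tab[o, 1:5, drop = FALSE], error = err[o])
}

# --- brute-force average-linkage agglomeration ----------------------------

# merges cluster index sets greedily by smallest average inter-cluster
# distance (average over all cross pairs of the original matrix); returns
# the cophenetic distance matrix
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  avg_dist <- function(a, b) mean(d[a, b, drop = FALSE])
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1L), length(clusters))) {
        dd <- avg_dist(clusters[[i]], clusters[[j]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# uncentered Pearson distance, re-derived with scalar loops
oracle_uncentered_dist <- function(m) {
  k <- ncol(m)
  out <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ni <- sqrt(sum(m[, i]^2))
      nj <- sqrt(sum(m[, j]^2))
      s <- if (ni == 0 || nj == 0) 0 else sum(m[, i] * m[, j]) / (ni * nj)
      out[i, j] <- 1 - s
    }
  }
  diag(out) <- 0
  out
}

# --- shared small fixtures -------------------------------------------------

# a minimal noiseless annotated+quantified table for one record set
quantify_records <- function(names_amounts, is_amount = 10,
                             protein = 100, scheme = "aoWR",
                             db = default_structure_db()) {
  is_comp <- "(Hex)5(HexNAc)3(Neu5Ac)2"
  recs <- lapply(names(names_amounts), function(nm) {
    db_lookup(db, name = nm)[[1]]
  })
  pmol <- unname(names_amounts) * protein / 100
  peaks <- data.frame(
    mz = c(vapply(recs, function(r) derivatized_mz(r$composition, scheme),
                  numeric(1)),
           derivatized_mz(is_comp, scheme)),
    area = c(pmol, is_amount) * 1000
  )
  ann <- annotate_peaklist(peaks, annotation_params(scheme = scheme), db,
                           is_comp)
  quantify(ann, internal_standard("A2GN1", is_comp, is_amount), protein)
}

default_bounds <- c(hex = 15L, hexnac = 12L, dhex = 6L,
                    neu5ac = 8L, neu5gc = 4L)
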