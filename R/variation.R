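#' All-pairs C-alpha RMSD summary
#'
#' Superposes every unordered pair of units on their shared C-alpha atoms
#' (matched by author residue number) and reports the minimized RMSD per
#' pair, the overall mean and maximum, and each unit's mean RMSD against
#' all others (used to compare, e.g., structures measured at higher
#' temperature against the rest of the ensemble).
#'
#' @param units List of `structure_unit` objects (at least 2).
#' @param min_shared Pairs sharing fewer C-alpha atoms than this are
#'   excluded with a warning.
#' @return Object of class `rmsd_summary`: list with `pairs` (data frame
#'   `unit_i`, `unit_j`, `rmsd`, `n_atoms`), `mean`, `max`, `per_unit`
#'   (named mean RMSD per unit) and `n_units`.
#' @export
rmsd_summary <- function(units, min_shared = 3L) {
  check_units(units, min_n = 2L)
  ca <- lapply(units, unit_ca)
  ids <- vapply(units, function(u) u$unit_id, character(1L))
  n <- length(units)
  rows <- vector("list", pair_combinations(n))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- intersect(rownames(ca[[i]]), rownames(ca[[j]]))
      k <- k + 1L
      if (length(shared) < min_shared) {
        warning("pair ", ids[i], " / ", ids[j], " shares fewer than ",
                min_shared, " C-alpha atoms; excluded")
        next
      }
      sup <- superpose_kabsch(ca[[i]][shared, , drop = FALSE],
                              ca[[j]][shared, , drop = FALSE])
      rows[[k]] <- data.frame(unit_i = ids[i], unit_j = ids[j],
                              rmsd = sup$rmsd, n_atoms = sup$n_pairs,
                              stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no comparable unit pairs")
  per_unit <- vapply(ids, function(id) {
    mean(pairs$rmsd[pairs$unit_i == id | pairs$unit_j == id])
  }, numeric(1L))
  structure(
    list(pairs = pairs,
         mean = mean(pairs$rmsd),
         max = max(pairs$rmsd),
         per_unit = per_unit,
         n_units = n),
    class = "rmsd_summary")
}

#' @export
print.rmsd_summary <- function(x, ...) {
  cat("<rmsd_summary> ", x$n_units, " units, ", nrow(x$pairs), " pairs\n",
      "  mean RMSD: ", format(x$mean, digits = 3), " A",
      "   max RMSD: ", format(x$max, digits = 3), " A\n", sep = "")
  invisible(x)
}

#' @export
summary.rmsd_summary <- function(object, ...) {
  c(mean = object$mean, max = object$max,
    per_unit_min = min(object$per_unit), per_unit_max = max(object$per_unit))
}

#' Per-residue C-alpha variation between units
#'
#' For every unordered pair of units, superposes on all shared C-alpha atoms
#' (global fit) and records the post-superposition distance \eqn{\delta_{ik}}
#' of each residue's C-alpha. The variation of residue i is the mean over the
#' M contributing pairs,
#' \deqn{[\mathrm{Variation\ between\ units}]_i = \frac{1}{M}\sum_k \delta_{ik},}
#' pairs in which the residue is unresolved being dropped from that
#' residue's M.
#'
#' @param units List of `structure_unit` objects (at least 2).
#' @param keep_pairs If `TRUE`, attach the per-pair distances as attribute
#'   `"pair_distances"` (a list keyed by residue number).
#' @return Data frame with columns `resno`, `resname`, `atom_role` ("CA"),
#'   `variation` (Angstrom, `NA` when a residue appears in fewer than 2
#'   units) and `n_pairs` (M), plus attribute `"mean_variation"` (mean over
#'   residues with defined variation).
#' @export
calpha_variation <- function(units, keep_pairs = FALSE) {
  check_units(units, min_n = 2L)
  ca <- lapply(units, unit_ca)
  n <- length(units)
  all_res <- sort(unique(as.integer(unlist(lapply(ca, rownames)))))
  key <- as.character(all_res)
  sums <- stats::setNames(numeric(length(all_res)), key)
  counts <- stats::setNames(integer(length(all_res)), key)
  pair_d <- if (keep_pairs) stats::setNames(vector("list", length(all_res)), key)

  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- intersect(rownames(ca[[i]]), rownames(ca[[j]]))
      if (length(shared) < 3L) next
      sup <- superpose_kabsch(ca[[i]][shared, , drop = FALSE],
                              ca[[j]][shared, , drop = FALSE])
      delta <- sup$residuals
      sums[shared] <- sums[shared] + delta
      counts[shared] <- counts[shared] + 1L
      if (keep_pairs) {
        for (s in seq_along(shared)) {
          pair_d[[shared[s]]] <- c(pair_d[[shared[s]]], delta[s])
        }
      }
    }
  }

  resname <- vapply(key, function(r) {
    for (u in units) {
      hit <- u$atoms$resname[u$atoms$resno == as.integer(r)]
      if (length(hit)) return(hit[1L])
    }
    NA_character_
  }, character(1L))
  out <- data.frame(
    resno = all_res,
    resname = unname(resname),
    atom_role = "CA",
    variation = ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_),
    n_pairs = as.integer(counts),
    stringsAsFactors = FALSE
  )
  attr(out, "mean_variation") <- mean(out$variation, na.rm = TRUE)
  if (keep_pairs) attr(out, "pair_distances") <- pair_d
  rownames(out) <- NULL
  out
}

#' Side-chain reporter atoms
#'
#' The side-chain atom(s) positioned furthest from the main chain, used to
#' quantify side-chain variation. Where two chemically equivalent atoms
#' exist (Arg NH1/NH2, Glu OE1/OE2, Val CG1/CG2, Asp OD1/OD2, Leu CD1/CD2)
#' the per-atom variations are averaged with fixed name correspondence.
#'
#' @return Named list mapping three-letter amino-acid codes to reporter
#'   atom-name vectors.
#' @export
reporter_table <- function() {
  list(
    ALA = "CB",
    ARG = c("NH1", "NH2"),
    ASN = "ND2",
    ASP = c("OD1", "OD2"),
    CYS = "SG",
    GLN = "NE2",
    GLU = c("OE1", "OE2"),
    HIS = "NE2",
    ILE = "CD1",
    LEU = c("CD1", "CD2"),
    LYS = "NZ",
    MET = "CE",
    PHE = "CZ",
    PRO = "CG",
    SER = "OG",
    THR = "OG1",
    TRP = "CH2",
    TYR = "OH",
    VAL = c("CG1", "CG2")
  )
}

#' Side-chain variation between units
#'
#' For each pair of units, the residue's main-chain N/CA/C atoms alone are
#' superposed (local fit, so the measure is invariant to rigid motion of the
#' whole unit), and \eqn{\delta_{ik}} is the distance between the reporter
#' atoms after the transform; multi-atom reporters are averaged with fixed
#' name correspondence. The variation is the mean over contributing pairs.
#'
#' @param units List of `structure_unit` objects.
#' @param residues Residue numbers to analyse; `NULL` means every residue
#'   whose amino-acid type has a reporter entry.
#' @param reporters Reporter-atom table, see [reporter_table()].
#' @return Data frame `resno`, `resname`, `atom_role` (reporter names,
#'   "+"-joined), `variation`, `n_pairs`. Requesting a single residue whose
#'   type has no reporter entry is an error; in `residues = NULL` mode such
#'   residues (e.g. Gly) are silently skipped.
#' @export
sidechain_variation <- function(units, residues = NULL,
                                reporters = reporter_table()) {
  check_units(units, min_n = 2L)
  explicit <- !is.null(residues)
  if (is.null(residues)) {
    residues <- sort(unique(unlist(lapply(units, function(u) u$atoms$resno))))
  }
  rows <- vector("list", length(residues))
  for (r in seq_along(residues)) {
    rows[[r]] <- sidechain_variation_one(units, residues[r], reporters,
                                         strict = explicit)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(resno = integer(), resname = character(),
                      atom_role = character(), variation = numeric(),
                      n_pairs = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

sidechain_variation_one <- function(units, resno, reporters, strict) {
  main <- c("N", "CA", "C")
  per_unit <- lapply(units, function(u) {
    at <- residue_atoms(u, resno)
    if (nrow(at) == 0L) return(NULL)
    rep_atoms <- reporters[[at$resname[1L]]]
    if (is.null(rep_atoms)) {
      if (strict) stop("no reporter atom defined for amino acid '",
                       at$resname[1L], "' (residue ", resno, ")")
      return(NA)
    }
    if (!all(main %in% at$name) || !all(rep_atoms %in% at$name)) return(NULL)
    list(resname = at$resname[1L],
         mc = xyz_mat(at[match(main, at$name), , drop = FALSE]),
         rep = xyz_mat(at[match(rep_atoms, at$name), , drop = FALSE]),
         rep_names = rep_atoms)
  })
  if (any(vapply(per_unit, function(p) identical(p, NA), logical(1L)))) {
    return(NULL)  # amino acid without reporter entry, non-strict mode
  }
  ok <- which(!vapply(per_unit, is.null, logical(1L)))
  if (length(ok) < 2L) {
    if (strict) {
      return(data.frame(resno = resno,
                        resname = if (length(ok)) per_unit[[ok]]$resname else NA_character_,
                        atom_role = NA_character_, variation = NA_real_,
                        n_pairs = 0L, stringsAsFactors = FALSE))
    }
    return(NULL)
  }
  deltas <- numeric(0L)
  for (a in seq_along(ok)[-length(ok)]) {
    for (b in seq.int(a + 1L, length(ok))) {
      pi <- per_unit[[ok[a]]]
      pj <- per_unit[[ok[b]]]
      sup <- superpose_kabsch(pi$mc, pj$mc)
      moved <- apply_superposition(sup, pi$rep)
      deltas <- c(deltas, mean(sqrt(rowSums((pj$rep - moved)^2))))
    }
  }
  p1 <- per_unit[[ok[1L]]]
  data.frame(resno = resno,
             resname = p1$resname,
             atom_role = paste(p1$rep_names, collapse = "+"),
             variation = mean(deltas),
             n_pairs = length(deltas),
             stringsAsFactors = FALSE)
}

check_units <- function(units, min_n = 1L) {
  if (!is.list(units) || length(units) < min_n ||
      !all(vapply(units, inherits, logical(1L), "structure_unit"))) {
    stop("need a list of at least ", min_n, " structure_unit objects")
  }
  invisible(TRUE)
}
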