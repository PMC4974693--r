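#' Van der Waals radii used for surface calculation
#'
#' @return Named vector of radii in Angstrom (C 1.70, N 1.55, O 1.52,
#'   S 1.80).
#' @export
sasa_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

# Deterministic spherical Fibonacci lattice, n points on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples each atom's solvent-expanded sphere (van der Waals radius plus
#' probe radius) on a deterministic spherical Fibonacci lattice and counts
#' the points not buried inside any neighbouring atom's expanded sphere.
#' Waters and the ligand are excluded: only the unit's protein heavy atoms
#' enter the calculation, matching the exposed-surface-area convention of
#' cocrystal ensemble surveys.
#'
#' @param unit A `structure_unit`, or a data frame of atoms with columns
#'   `resno`, `resname`, `element`, `x`, `y`, `z`.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Lattice points per atom.
#' @param radii Named radius table; elements missing from it are an error.
#' @return Data frame `resno`, `resname`, `area` (Angstrom squared), with
#'   attribute `"atom_area"` (per-atom areas).
#' @export
residue_sasa <- function(unit, probe_radius = 1.4, n_points = 960L,
                         radii = sasa_radii()) {
  atoms <- if (inherits(unit, "structure_unit")) unit$atoms else unit
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  el <- atoms$element
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) {
    stop("no radius entry for element(s): ", paste(unknown, collapse = ", "))
  }
  r <- unname(radii[el]) + probe_radius
  xyz <- xyz_mat(atoms)
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)

  # Candidate occluders: centre distance below the sum of expanded radii.
  cutoff2 <- outer(r, r, "+")^2
  atom_area <- numeric(n)
  d2all <- dist2_cross(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2all[i, ] < cutoff2[i, ] & seq_len(n) != i)
    sp <- pts * r[i] + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    if (length(nb)) {
      d2 <- dist2_cross(sp, xyz[nb, , drop = FALSE])
      lim <- matrix(r[nb]^2, n_points, length(nb), byrow = TRUE)
      exposed <- rowSums(d2 < lim) == 0L
    } else {
      exposed <- rep(TRUE, n_points)
    }
    atom_area[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }

  agg <- stats::aggregate(atom_area,
                          by = list(resno = atoms$resno),
                          FUN = sum)
  resname <- vapply(agg$resno, function(rn) {
    atoms$resname[match(rn, atoms$resno)]
  }, character(1L))
  out <- data.frame(resno = agg$resno, resname = resname, area = agg$x,
                    stringsAsFactors = FALSE)
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "atom_area") <- atom_area
  out
}

#' Ensemble-averaged exposed surface area
#'
#' Computes [residue_sasa()] for each unit and averages per residue over the
#' units in which the residue is resolved.
#'
#' @inheritParams residue_sasa
#' @param units List of `structure_unit` objects.
#' @return Data frame `resno`, `resname`, `area` (ensemble mean), `n_units`.
#' @export
ensemble_sasa <- function(units, probe_radius = 1.4, n_points = 960L,
                          radii = sasa_radii()) {
  check_units(units, min_n = 1L)
  per <- lapply(units, residue_sasa, probe_radius = probe_radius,
                n_points = n_points, radii = radii)
  all <- do.call(rbind, per)
  agg <- stats::aggregate(all$area, by = list(resno = all$resno), FUN = mean)
  cnt <- stats::aggregate(all$area, by = list(resno = all$resno), FUN = length)
  resname <- all$resname[match(agg$resno, all$resno)]
  out <- data.frame(resno = agg$resno, resname = resname,
                    area = agg$x, n_units = cnt$x, stringsAsFactors = FALSE)
  out[order(out$resno), , drop = FALSE]
}
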