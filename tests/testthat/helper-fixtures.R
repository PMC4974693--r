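# Shared fixture builders and independent oracles.

# Atom data frame in the package's internal schema.
make_atoms <- function(name, xyz, resno, resname = "GLY", chain = "A",
                       rectype = "ATOM", b = 25, occ = 1,
                       element = NULL) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  name <- rep_len(name, n)
  if (is.null(element)) element <- xtalvar:::derive_element(name)
  data.frame(
    rectype = rep_len(rectype, n), eleno = seq_len(n), name = name,
    altloc = rep_len("", n), resname = rep_len(resname, n),
    chain = rep_len(chain, n), resno = rep_len(resno, n),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occ = rep_len(occ, n), b = rep_len(b, n),
    element = rep_len(element, n),
    is_water = rep_len(FALSE, n), is_hetero = rep_len(rectype == "HETATM", n),
    stringsAsFactors = FALSE)
}

# Assemble a structure_unit directly from atom tables.
make_unit <- function(atoms, ligand_atoms = NULL, water_xyz = NULL,
                      water_b = 30, unit_id = "TOY_A",
                      span = range(atoms$resno)) {
  waters <- make_atoms("O", matrix(numeric(0L), 0L, 3L), integer(0L))
  if (!is.null(water_xyz)) {
    water_xyz <- matrix(water_xyz, ncol = 3L)
    waters <- make_atoms("O", water_xyz,
                         resno = 5000L + seq_len(nrow(water_xyz)),
                         resname = "HOH", rectype = "HETATM",
                         b = water_b)
    waters$is_water <- TRUE
    waters$is_hetero <- FALSE
    waters$eleno <- max(atoms$eleno) + seq_len(nrow(waters))
  }
  ligand <- NULL
  if (!is.null(ligand_atoms)) {
    ligand <- list(id = paste(ligand_atoms$resname[1L], ligand_atoms$chain[1L],
                              ligand_atoms$resno[1L], sep = "_"),
                   comp_id = ligand_atoms$resname[1L],
                   atoms = ligand_atoms)
  }
  structure(
    list(unit_id = unit_id, atoms = atoms, ligand = ligand, waters = waters,
         disordered_count = 0L, span = as.integer(span)),
    class = "structure_unit")
}

# Apply a rigid motion to every coordinate of a unit.
transform_unit <- function(unit, rot, trans) {
  mv <- function(df) {
    if (nrow(df) == 0L) return(df)
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot) +
      matrix(trans, nrow(df), 3L, byrow = TRUE)
    df$x <- m[, 1L]; df$y <- m[, 2L]; df$z <- m[, 3L]
    df
  }
  unit$atoms <- mv(unit$atoms)
  if (!is.null(unit$ligand)) unit$ligand$atoms <- mv(unit$ligand$atoms)
  unit$waters <- mv(unit$waters)
  unit
}

rotation_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3L, 3L)
  diag(3L) + sin(a) * k + (1 - cos(a)) * (k %*% k)
}

euler_rotation <- function(ang) {
  rotation_about(c(0, 0, 1), ang[1L]) %*%
    rotation_about(c(0, 1, 0), ang[2L]) %*%
    rotation_about(c(0, 0, 1), ang[3L])
}

# Independent superposition oracle: minimize the RMSD of Eq.-style
# least-squares over rotations by Euler-angle grid scan plus Nelder-Mead
# polish, with the optimal translation fixed at the centroids. Never uses
# the SVD path.
oracle_rmsd <- function(moving, fixed, step = 20) {
  p <- sweep(moving, 2L, colMeans(moving))
  q <- sweep(fixed, 2L, colMeans(fixed))
  f <- function(ang) {
    r <- euler_rotation(ang)
    sqrt(mean(rowSums((q - p %*% t(r))^2)))
  }
  best <- c(0, 0, 0)
  best_v <- f(best)
  for (a in seq(0, 360 - step, by = step)) {
    for (b in seq(0, 180, by = step)) {
      for (g in seq(0, 360 - step, by = step)) {
        v <- f(c(a, b, g))
        if (v < best_v) {
          best_v <- v
          best <- c(a, b, g)
        }
      }
    }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  opt <- stats::optim(opt$par, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  opt$value
}

# Exhaustive all-pairs contact scan (oracle for binding-area fractions).
oracle_contact_residues <- function(unit, cutoff) {
  lig <- unit$ligand$atoms
  hit <- integer(0L)
  for (i in seq_len(nrow(unit$atoms))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt(sum((c(unit$atoms$x[i], unit$atoms$y[i], unit$atoms$z[i]) -
                       c(lig$x[j], lig$y[j], lig$z[j]))^2))
      if (d < cutoff) hit <- c(hit, unit$atoms$resno[i])
    }
  }
  sort(unique(hit))
}

# Analytic accessible area of two intersecting solvent-expanded spheres
# (radii R1, R2, centre distance d): each sphere loses a spherical cap.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

# Fixed-width PDB record line for parser tests.
pdb_line <- function(rectype, serial, name, resname, chain, resno,
                     x, y, z, occ = 1, b = 20, element = "",
                     altloc = " ") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial, nm, altloc, resname, chain, resno,
          x, y, z, occ, b, element)
}

# Small toy protein: residues 1..n along x with slight (deterministic,
# non-collinear) C-alpha displacements; CB atoms on a fixed line y = -1.5 so
# ligand/water toy distances are easy to place by hand.
toy_protein <- function(n = 6L, spacing = 4) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    dy <- 0.3 * (i %% 2L)
    dz <- 0.15 * ((i * 7L) %% 3L)
    make_atoms(c("N", "CA", "C", "CB"),
               rbind(c(spacing * i - 1.2, 0.9 + dy, dz),
                     c(spacing * i, dy, dz),
                     c(spacing * i + 1.2, 0.9 + dy, 0.4 + dz),
                     c(spacing * i, -1.5, 0.3)),
               resno = i, resname = "ALA")
  }))
}
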