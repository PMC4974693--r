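#' Specification for a synthetic cocrystal ensemble
#'
#' Describes a generative model with the statistical structure assumed by
#' the analysis: near-identical protein copies with per-residue isotropic
#' Gaussian displacement, random per-unit rigid poses, a bound ligand whose
#' amine nitrogen is placed at set distances from designated role residues,
#' planted conserved water sites (present in a chosen fraction of units,
#' low B-factor) over a background of uniform random waters (high B-factor),
#' and occasional missing ("disordered") residues.
#'
#' @param n_units Number of units.
#' @param n_residues Protein length (at least 20).
#' @param first_resno First author residue number; default 41, giving the
#'   span 41-764 at the default length of 724.
#' @param sigma Per-residue displacement standard deviation in Angstrom;
#'   scalar or length-`n_residues` vector.
#' @param rot_deg,trans_A Rigid-pose ranges: rotation angle drawn uniformly
#'   in `[0, rot_deg]` about a uniform random axis, translation components
#'   uniform in `[-trans_A, trans_A]`.
#' @param missing_residue_rate Per-residue probability of being unresolved
#'   in a unit.
#' @param with_ligand Place the synthetic inhibitor.
#' @param amine_distances Target distances (Angstrom) from the ligand amine
#'   N to the Glu205-role OE1, Glu206-role OE1 and Tyr662-role OH atoms.
#' @param ser_contact_dist Distance from the ligand warhead carbon to the
#'   Ser630-role OG atom; below 3 it reads as a covalent nitrile.
#' @param anchor_dist Distance from a ligand O atom to the Arg125-role NH1
#'   atom (the polar anchor); `NA` omits the anchor atom.
#' @param n_decoy_atoms Additional inert ligand carbons.
#' @param n_planted_sites Number of conserved water sites planted.
#' @param planted_presence_fraction Fraction of units carrying each planted
#'   water.
#' @param planted_jitter Positional jitter s.d. of planted waters (Angstrom).
#' @param n_random_waters Uniform random waters drawn per unit (in the
#'   protein bounding box plus `water_box_margin`, at least 2.4 Angstrom
#'   from any atom; only those within 4 Angstrom of the protein are
#'   retained in the unit, mirroring the unit-definition rule).
#' @param water_box_margin Box margin in Angstrom.
#' @param planted_b,random_b,protein_b B-factors assigned to planted waters,
#'   random waters and protein atoms.
#' @param seed Integer seed; identical specs generate identical ensembles.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_units = 10L,
                          n_residues = 724L,
                          first_resno = 41L,
                          sigma = 0.2,
                          rot_deg = 180,
                          trans_A = 10,
                          missing_residue_rate = 0,
                          with_ligand = TRUE,
                          amine_distances = c(3.0, 3.2, 4.2),
                          ser_contact_dist = 3.4,
                          anchor_dist = 3.2,
                          n_decoy_atoms = 6L,
                          n_planted_sites = 5L,
                          planted_presence_fraction = 0.8,
                          planted_jitter = 0.2,
                          n_random_waters = 50L,
                          water_box_margin = 6,
                          planted_b = 10,
                          random_b = 40,
                          protein_b = 25,
                          seed = 1L) {
  stopifnot(n_units >= 1L, n_residues >= 20L,
            all(sigma >= 0), missing_residue_rate >= 0,
            missing_residue_rate <= 1,
            planted_presence_fraction >= 0, planted_presence_fraction <= 1,
            planted_jitter >= 0, length(amine_distances) == 3L)
  if (length(sigma) == 1L) sigma <- rep(sigma, n_residues)
  if (length(sigma) != n_residues) {
    stop("sigma must be scalar or length n_residues")
  }
  structure(
    list(n_units = as.integer(n_units),
         n_residues = as.integer(n_residues),
         first_resno = as.integer(first_resno),
         sigma = sigma,
         rot_deg = rot_deg, trans_A = trans_A,
         missing_residue_rate = missing_residue_rate,
         with_ligand = isTRUE(with_ligand),
         amine_distances = amine_distances,
         ser_contact_dist = ser_contact_dist,
         anchor_dist = anchor_dist,
         n_decoy_atoms = as.integer(n_decoy_atoms),
         n_planted_sites = as.integer(n_planted_sites),
         planted_presence_fraction = planted_presence_fraction,
         planted_jitter = planted_jitter,
         n_random_waters = as.integer(n_random_waters),
         water_box_margin = water_box_margin,
         planted_b = planted_b, random_b = random_b, protein_b = protein_b,
         seed = as.integer(seed)),
    class = "ensemble_spec")
}

# Side-chain pseudo-atom layout per residue type (radial/tangential offsets
# from CA in the local helix frame, in Angstrom).
synthetic_sidechains <- function() {
  list(
    SER = list(OG  = c(2.4,  0.0)),
    VAL = list(CB  = c(1.5,  0.0), CG1 = c(2.8,  0.75), CG2 = c(2.8, -0.75)),
    ARG = list(NH1 = c(3.2,  0.75), NH2 = c(3.2, -0.75)),
    TYR = list(OH  = c(3.4,  0.0)),
    GLU = list(OE1 = c(3.0,  0.75), OE2 = c(3.0, -0.75)),
    ASN = list(ND2 = c(2.6,  0.7), OD1 = c(2.6, -0.7)),
    HIS = list(NE2 = c(2.9,  0.0)),
    PHE = list(CZ  = c(3.1,  0.0)),
    TRP = list(CH2 = c(3.3,  0.4)),
    ALA = list(CB  = c(1.5,  0.0))
  )
}

# Idealized alpha-helical template: CA on a helix (radius 2.3 A, rise 1.5 A,
# 100 degrees per residue), N/C offsets in the local frame, side-chain
# pseudo-atoms pointing radially outward. Returns atoms data frame plus the
# per-residue local frame (for water placement) and the role site_map.
synthetic_template <- function(spec) {
  n <- spec$n_residues
  resnos <- spec$first_resno + seq_len(n) - 1L

  s <- spec$first_resno + n %/% 2L
  site_map <- list(ser630 = s, glu205 = s + 1L, glu206 = s + 2L,
                   tyr662 = s + 3L, arg125 = s - 2L, asn710 = s - 1L)
  palette <- c("SER", "VAL", "ARG", "TYR", "GLU", "ASN", "HIS", "PHE",
               "TRP", "ALA")
  resname <- palette[(seq_len(n) - 1L) %% length(palette) + 1L]
  role_type <- c(ser630 = "SER", glu205 = "GLU", glu206 = "GLU",
                 tyr662 = "TYR", arg125 = "ARG", asn710 = "ASN")
  for (role in names(site_map)) {
    resname[match(site_map[[role]], resnos)] <- role_type[[role]]
  }

  theta <- (seq_len(n) - 1L) * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (seq_len(n) - 1L))
  rhat <- cbind(cos(theta), sin(theta), 0)
  that <- cbind(-sin(theta), cos(theta), 0)
  axial <- matrix(rep(c(0, 0, 1), each = n), n, 3L)

  sc <- synthetic_sidechains()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C")
    pos <- rbind(ca[i, ] - 0.53 * rhat[i, ] - 0.84 * that[i, ] - 0.95 * axial[i, ],
                 ca[i, ],
                 ca[i, ] - 0.53 * rhat[i, ] + 0.84 * that[i, ] + 0.95 * axial[i, ])
    side <- sc[[resname[i]]]
    for (an in names(side)) {
      off <- side[[an]]
      nm <- c(nm, an)
      pos <- rbind(pos, ca[i, ] + off[1L] * rhat[i, ] + off[2L] * that[i, ])
    }
    rows[[i]] <- data.frame(
      rectype = "ATOM", eleno = 0L, name = nm, altloc = "",
      resname = resname[i], chain = "A", resno = resnos[i],
      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
      occ = 1, b = spec$protein_b,
      element = derive_element(nm),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)

  # Active-site pocket: the six role residues' functional side-chain atoms
  # converge on a common pocket centre outside the helix barrel, emulating
  # the binding cavity a folded protein presents (a straight helix would
  # splay them apart).
  role_idx <- match(unlist(site_map), resnos)
  e1 <- colMeans(rhat[role_idx, , drop = FALSE])
  e1 <- c(e1[1:2] / sqrt(sum(e1[1:2]^2)), 0)
  e3 <- c(0, 0, 1)
  e2 <- c(-e1[2L], e1[1L], 0)
  pocket <- colMeans(ca[role_idx, , drop = FALSE]) + 4.5 * e1
  at_p <- function(off) pocket + off[1L] * e1 + off[2L] * e2 + off[3L] * e3
  pocket_layout <- list(
    glu205 = list(OE1 = c(-2.0,  0.8,  0.0), OE2 = c(-2.0, -0.7,  0.0)),
    glu206 = list(OE1 = c(-1.2,  2.2,  0.3), OE2 = c(-2.4,  2.0,  0.3)),
    tyr662 = list(OH  = c( 0.5,  3.0, -0.5)),
    ser630 = list(OG  = c( 2.5,  0.0,  0.5)),
    arg125 = list(NH1 = c( 0.0, -2.8,  0.5), NH2 = c( 1.2, -2.6,  0.0)),
    asn710 = list(ND2 = c( 2.2, -1.8, -0.5), OD1 = c( 3.0, -1.0, -0.5)))
  for (role in names(pocket_layout)) {
    resno <- site_map[[role]]
    for (an in names(pocket_layout[[role]])) {
      sel <- atoms$resno == resno & atoms$name == an
      atoms[sel, c("x", "y", "z")] <- as.list(at_p(pocket_layout[[role]][[an]]))
    }
  }

  atoms$eleno <- seq_len(nrow(atoms))
  atoms$is_water <- FALSE
  atoms$is_hetero <- FALSE
  list(atoms = atoms, ca = ca, rhat = rhat, that = that,
       resnos = resnos, site_map = site_map, pocket = pocket)
}

# Place the synthetic ligand in the template frame: amine N at the target
# distances from the role anchors (least-squares trilateration), a bonded
# carbon, a warhead carbon near the Ser630-role OG, an optional polar-anchor
# O near the Arg125-role NH1, and inert decoy carbons.
synthetic_ligand <- function(tmpl, spec) {
  atom_xyz <- function(resno, name) {
    a <- tmpl$atoms
    unlist(a[a$resno == resno & a$name == name, c("x", "y", "z")],
           use.names = FALSE)
  }
  a1 <- atom_xyz(tmpl$site_map$glu205, "OE1")
  a2 <- atom_xyz(tmpl$site_map$glu206, "OE1")
  a3 <- atom_xyz(tmpl$site_map$tyr662, "OH")
  og <- atom_xyz(tmpl$site_map$ser630, "OG")
  d <- spec$amine_distances

  obj <- function(x) {
    (sqrt(sum((x - a1)^2)) - d[1L])^2 +
      (sqrt(sum((x - a2)^2)) - d[2L])^2 +
      (sqrt(sum((x - a3)^2)) - d[3L])^2
  }
  n_pos <- stats::optim(tmpl$pocket, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))$par

  udir <- function(v) v / sqrt(sum(v^2))
  to_og <- udir(og - n_pos)
  c1 <- n_pos + 1.45 * to_og
  warhead <- og - spec$ser_contact_dist * to_og

  nm <- c("N1", "C1", "C2")
  pos <- rbind(n_pos, c1, warhead)
  if (!is.na(spec$anchor_dist)) {
    nh1 <- atom_xyz(tmpl$site_map$arg125, "NH1")
    radial <- udir(c(nh1[1L], nh1[2L], 0))
    nm <- c(nm, "O1")
    pos <- rbind(pos, nh1 + spec$anchor_dist * radial)
  }
  if (spec$n_decoy_atoms > 0L) {
    # Inert tail growing away from the amine so its valence stays primary.
    away <- udir(n_pos - og)
    perp <- udir(c(-away[2L], away[1L], 0.2))
    for (k in seq_len(spec$n_decoy_atoms)) {
      nm <- c(nm, paste0("C", k + 2L))
      pos <- rbind(pos, n_pos + (2.0 + 0.9 * k) * away + 0.5 * (k %% 2L) * perp)
    }
  }
  lig_resno <- max(tmpl$resnos) + 10L
  data.frame(
    rectype = "HETATM", eleno = 0L, name = nm, altloc = "",
    resname = "LIG", chain = "A", resno = lig_resno,
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    occ = 1, b = spec$protein_b,
    element = derive_element(nm),
    is_water = FALSE, is_hetero = TRUE,
    stringsAsFactors = FALSE)
}

# Planted conserved-water positions in the template frame: 2.8 A beyond the
# side-chain tip of evenly spaced residues, i.e. hydration-shell distance
# from the protein (well inside the 4 A water-retention rule even under
# jitter and coordinate noise). Role residues are skipped because their side
# chains point into the pocket rather than radially.
planted_water_positions <- function(tmpl, spec) {
  k <- spec$n_planted_sites
  if (k == 0L) return(matrix(numeric(0L), 0L, 3L))
  n <- length(tmpl$resnos)
  roles <- match(unlist(tmpl$site_map), tmpl$resnos)
  sc <- synthetic_sidechains()
  idx <- as.integer(round(seq(0.15, 0.85, length.out = k) * n))
  idx <- vapply(idx, function(i) {
    while (i %in% roles) i <- i + 4L
    min(i, n)
  }, numeric(1L))
  t(vapply(idx, function(i) {
    rn <- tmpl$atoms$resname[match(tmpl$resnos[i], tmpl$atoms$resno)]
    tip <- max(vapply(sc[[rn]], `[`, numeric(1L), 1L))  # radial tip offset
    tmpl$ca[i, ] + (tip + 2.8) * tmpl$rhat[i, ]
  }, numeric(3L)))
}

random_rotation <- function(max_deg) {
  ax <- stats::rnorm(3L)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1L, 0, max_deg) * pi / 180
  k <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L], ax[2L], -ax[1L], 0),
              3L, 3L)
  diag(3L) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

#' Generate a synthetic cocrystal ensemble with known ground truth
#'
#' Builds the idealized template of [ensemble_spec()], then derives each
#' unit by adding per-residue isotropic Gaussian noise, dropping residues at
#' the missing-residue rate, planting conserved waters (with jitter) in the
#' configured fraction of units over uniform random background waters, and
#' applying a random rigid pose to everything. The random draw order per
#' unit is fixed (pose, protein noise, missing residues, planted-water
#' presence and jitter, random waters) so ensembles are stable across
#' releases; the caller's RNG state is untouched.
#'
#' @param spec An `ensemble_spec`.
#' @return List with `units` (list of `structure_unit`) and `truth`: the
#'   generative record (`sigma` named by residue number, `site_map`,
#'   `water_sites` template-frame matrix, `water_presence` units x sites
#'   logical matrix, `water_support`, `missing` residue numbers per unit,
#'   `poses`, `ligand` geometry summary, `template` atoms).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  tmpl <- synthetic_template(spec)
  if (nrow(tmpl$atoms) < 3L) stop("spec produces fewer than 3 atoms per unit")
  lig <- if (spec$with_ligand) synthetic_ligand(tmpl, spec)
  wpos <- planted_water_positions(tmpl, spec)

  prot_xyz <- xyz_mat(tmpl$atoms)
  all_fixed <- rbind(prot_xyz, if (!is.null(lig)) xyz_mat(lig))
  bb_lo <- apply(all_fixed, 2L, min) - spec$water_box_margin
  bb_hi <- apply(all_fixed, 2L, max) + spec$water_box_margin
  sigma_atom <- spec$sigma[match(tmpl$atoms$resno, tmpl$resnos)]

  units <- vector("list", spec$n_units)
  presence <- matrix(FALSE, spec$n_units, max(spec$n_planted_sites, 0L))
  missing <- vector("list", spec$n_units)
  poses <- vector("list", spec$n_units)

  with_private_seed(spec$seed, {
    for (u in seq_len(spec$n_units)) {
      rot <- random_rotation(spec$rot_deg)
      trans <- stats::runif(3L, -spec$trans_A, spec$trans_A)
      poses[[u]] <- list(rotation = rot, translation = trans)

      at <- tmpl$atoms
      noise <- matrix(stats::rnorm(3L * nrow(at), sd = rep(sigma_atom, 3L)),
                      ncol = 3L)
      pxyz <- prot_xyz + noise

      drop_res <- tmpl$resnos[stats::runif(length(tmpl$resnos)) <
                                spec$missing_residue_rate]
      missing[[u]] <- drop_res

      wat_xyz <- matrix(numeric(0L), 0L, 3L)
      wat_b <- numeric(0L)
      if (spec$n_planted_sites > 0L) {
        pres <- stats::runif(spec$n_planted_sites) < spec$planted_presence_fraction
        presence[u, ] <- pres
        for (s in which(pres)) {
          jit <- stats::rnorm(3L, sd = spec$planted_jitter)
          wat_xyz <- rbind(wat_xyz, wpos[s, ] + jit)
          wat_b <- c(wat_b, spec$planted_b)
        }
      }
      if (spec$n_random_waters > 0L) {
        cand <- matrix(stats::runif(3L * spec$n_random_waters), ncol = 3L)
        cand <- sweep(sweep(cand, 2L, bb_hi - bb_lo, "*"), 2L, bb_lo, "+")
        dmin <- min_dist_to(cand, all_fixed)
        cand <- cand[dmin >= 2.4, , drop = FALSE]
        wat_xyz <- rbind(wat_xyz, cand)
        wat_b <- c(wat_b, rep(spec$random_b, nrow(cand)))
      }

      pose <- function(m) {
        if (nrow(m) == 0L) return(m)
        tcrossprod(m, rot) + matrix(trans, nrow(m), 3L, byrow = TRUE)
      }
      # Coordinates are rounded to the PDB format's 3-decimal precision so
      # that units written to file and re-parsed are bit-identical.
      pxyz_p <- round(pose(pxyz), 3L)
      at$x <- pxyz_p[, 1L]; at$y <- pxyz_p[, 2L]; at$z <- pxyz_p[, 3L]
      keep <- !(at$resno %in% drop_res)
      at <- at[keep, , drop = FALSE]

      ligand <- NULL
      if (!is.null(lig)) {
        lx <- round(pose(xyz_mat(lig)), 3L)
        la <- lig
        la$x <- lx[, 1L]; la$y <- lx[, 2L]; la$z <- lx[, 3L]
        ligand <- list(id = paste(la$resname[1L], la$chain[1L], la$resno[1L],
                                  sep = "_"),
                       comp_id = la$resname[1L],
                       atoms = la)
      }

      waters <- data.frame(
        rectype = character(0L), eleno = integer(0L), name = character(0L),
        altloc = character(0L), resname = character(0L), chain = character(0L),
        resno = integer(0L), x = numeric(0L), y = numeric(0L), z = numeric(0L),
        occ = numeric(0L), b = numeric(0L), element = character(0L),
        is_water = logical(0L), is_hetero = logical(0L),
        stringsAsFactors = FALSE)
      if (nrow(wat_xyz) > 0L) {
        # Retain the waters a crystallographer would assign to this unit.
        near <- min_dist_to(wat_xyz, pxyz[tmpl$atoms$resno %in% at$resno, ,
                                          drop = FALSE]) < 4
        wk <- round(pose(wat_xyz[near, , drop = FALSE]), 3L)
        if (nrow(wk) > 0L) {
          waters <- data.frame(
            rectype = "HETATM",
            eleno = max(at$eleno) + seq_len(nrow(wk)),
            name = "O", altloc = "", resname = "HOH", chain = "A",
            resno = max(tmpl$resnos) + 20L + seq_len(nrow(wk)),
            x = wk[, 1L], y = wk[, 2L], z = wk[, 3L],
            occ = 1, b = wat_b[near],
            element = "O", is_water = TRUE, is_hetero = FALSE,
            stringsAsFactors = FALSE)
        }
      }

      units[[u]] <- structure(
        list(unit_id = sprintf("SYN%02d_A", u),
             atoms = at,
             ligand = ligand,
             waters = waters,
             disordered_count = length(drop_res),
             span = c(spec$first_resno,
                      spec$first_resno + spec$n_residues - 1L)),
        class = "structure_unit")
    }
  })

  truth <- list(
    sigma = stats::setNames(spec$sigma, tmpl$resnos),
    site_map = tmpl$site_map,
    water_sites = wpos,
    water_presence = presence,
    water_support = if (ncol(presence)) colSums(presence) else integer(0L),
    missing = missing,
    poses = poses,
    ligand = if (!is.null(lig)) list(
      amine_distances = spec$amine_distances,
      ser_contact_dist = spec$ser_contact_dist,
      covalent = spec$ser_contact_dist < 3,
      anchor_dist = spec$anchor_dist),
    template = tmpl$atoms,
    seed = spec$seed)
  list(units = units, truth = truth)
}

#' Write a synthetic ensemble to PDB files
#'
#' One legal PDB file per unit, so the analysis pipeline can be exercised
#' through its real I/O path.
#'
#' @param units List of `structure_unit` objects.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_ensemble_pdbs <- function(units, dir) {
  check_units(units, min_n = 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(units, function(u) {
    f <- file.path(dir, paste0(sub("_[^_]*$", "", u$unit_id), ".pdb"))
    write_unit_pdb(u, f)
    f
  }, character(1L))
  invisible(paths)
}
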