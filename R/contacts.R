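#' Contact-frequency definition of the inhibitor binding area
#'
#' A residue contacts an inhibitor when any protein heavy atom of the
#' residue lies within `cutoff` of any ligand heavy atom. Contact fractions
#' are tallied over distinct inhibitors (deduplicated by chemical-component
#' identifier, so an inhibitor appearing in several units counts once;
#' DPP-4 convention: 68 inhibitors across 147 units) and, for
#' cross-checking, over units. Residues with fraction strictly above
#' `high_fraction` form the core set, above `low_fraction` the extended set
#' (the DPP-4 binding area: 13 residues above 70 %, 16 above 30 %).
#'
#' @param units List of `structure_unit` objects, at least one with a ligand.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @param high_fraction,low_fraction Strict membership thresholds.
#' @param per_ligand If `TRUE` fractions use distinct inhibitors as
#'   denominator; if `FALSE`, units.
#' @return Object of class `binding_area`: list with `fraction` (named by
#'   residue number), `unit_fraction`, `core_set`, `extended_set`,
#'   `n_ligands`, `n_units`, and the thresholds used.
#' @export
binding_area_from_contacts <- function(units, cutoff = 4.0,
                                       high_fraction = 0.70,
                                       low_fraction = 0.30,
                                       per_ligand = TRUE) {
  check_units(units, min_n = 1L)
  with_lig <- Filter(function(u) !is.null(u$ligand), units)
  if (length(with_lig) == 0L) stop("no units carry a ligand")
  check_ligand_identifiers(with_lig)

  unit_contacts <- lapply(with_lig, function(u) contact_residues(u, cutoff))
  comp <- vapply(with_lig, function(u) u$ligand$comp_id, character(1L))

  all_res <- sort(unique(unlist(lapply(with_lig, function(u) unique(u$atoms$resno)))))
  key <- as.character(all_res)

  # Distinct-inhibitor tally: an inhibitor contacts a residue if any of its
  # units does.
  lig_ids <- sort(unique(comp))
  lig_hits <- stats::setNames(integer(length(all_res)), key)
  for (lg in lig_ids) {
    res_union <- unique(unlist(unit_contacts[comp == lg]))
    lig_hits[as.character(res_union)] <- lig_hits[as.character(res_union)] + 1L
  }
  unit_hits <- stats::setNames(integer(length(all_res)), key)
  for (ct in unit_contacts) {
    unit_hits[as.character(ct)] <- unit_hits[as.character(ct)] + 1L
  }

  lig_frac <- lig_hits / length(lig_ids)
  unit_frac <- unit_hits / length(with_lig)
  frac <- if (per_ligand) lig_frac else unit_frac

  structure(
    list(fraction = frac,
         unit_fraction = unit_frac,
         core_set = all_res[frac > high_fraction],
         extended_set = all_res[frac > low_fraction],
         n_ligands = length(lig_ids),
         n_units = length(with_lig),
         cutoff = cutoff,
         high_fraction = high_fraction,
         low_fraction = low_fraction),
    class = "binding_area")
}

#' @export
print.binding_area <- function(x, ...) {
  cat("<binding_area> cutoff ", x$cutoff, " A over ", x$n_ligands,
      " inhibitors (", x$n_units, " units)\n",
      "  core (>", 100 * x$high_fraction, "%):     ",
      paste(x$core_set, collapse = " "), "\n",
      "  extended (>", 100 * x$low_fraction, "%): ",
      paste(x$extended_set, collapse = " "), "\n", sep = "")
  invisible(x)
}

contact_residues <- function(unit, cutoff) {
  lig <- xyz_mat(unit$ligand$atoms)
  d <- min_dist_to(xyz_mat(unit$atoms), lig)
  sort(unique(unit$atoms$resno[d < cutoff]))
}

check_ligand_identifiers <- function(units) {
  sig <- list()
  for (u in units) {
    id <- u$ligand$comp_id
    s <- paste(sort(u$ligand$atoms$name), collapse = ",")
    if (!is.null(sig[[id]]) && !identical(sig[[id]], s)) {
      stop("ligand identifier '", id,
           "' is shared by chemically different ligands (atom sets differ)")
    }
    sig[[id]] <- s
  }
  invisible(TRUE)
}

default_site_map <- function() {
  list(glu205 = 205L, glu206 = 206L, tyr662 = 662L,
       arg125 = 125L, asn710 = 710L, ser630 = 630L)
}

#' Classify the common electrostatic binding modes of one unit
#'
#' Tests the three recurring inhibitor binding modes of DPP-4-style
#' ensembles, with residue roles supplied by `site_map` so synthetic or
#' renumbered systems can be analysed:
#' \describe{
#'   \item{amine network}{one primary or secondary amine nitrogen of the
#'     inhibitor simultaneously < 4 Angstrom from a Glu205 OE atom, < 4 from
#'     a Glu206 OE atom and < 5 from the Tyr662 OH atom. Amine nitrogens are
#'     detected by valence: a ligand N with 1 or 2 heavy-atom neighbours
#'     within bond distance (1.8 Angstrom).}
#'   \item{polar anchor}{an inhibitor O, N or halogen atom < 4 Angstrom from
#'     an Arg125 NH atom or from the Asn710 ND2/OD1 atom (both tested, since
#'     the amide N/O assignment swaps between deposits); per-partner flags
#'     are also reported.}
#'   \item{covalent Ser630}{the Ser630 OG atom < 3 Angstrom from an
#'     inhibitor carbon, as for nitrile warheads.}
#' }
#'
#' @param unit A `structure_unit` with a ligand.
#' @param site_map Named list of role -> residue number with entries
#'   `glu205`, `glu206`, `tyr662`, `arg125`, `asn710`, `ser630`.
#' @return Object of class `binding_mode_record` (list of flags, qualifying
#'   atoms and minimal distances).
#' @export
classify_binding_modes <- function(unit, site_map = default_site_map()) {
  stopifnot(inherits(unit, "structure_unit"))
  if (is.null(unit$ligand)) stop("unit ", unit$unit_id, " has no ligand")
  lig <- unit$ligand$atoms

  role_xyz <- function(role, names) {
    resno <- site_map[[role]]
    if (is.null(resno)) stop("site_map lacks role '", role, "'")
    at <- residue_atoms(unit, resno)
    if (nrow(at) == 0L) {
      stop("site_map role '", role, "' points at residue ", resno,
           ", absent from unit ", unit$unit_id)
    }
    sel <- at[at$name %in% names, , drop = FALSE]
    xyz_mat(sel)
  }

  glu205 <- role_xyz("glu205", c("OE1", "OE2"))
  glu206 <- role_xyz("glu206", c("OE1", "OE2"))
  tyr662 <- role_xyz("tyr662", "OH")
  arg125 <- role_xyz("arg125", c("NH1", "NH2"))
  asn710 <- role_xyz("asn710", c("ND2", "OD1"))
  ser630 <- role_xyz("ser630", "OG")

  lxyz <- xyz_mat(lig)

  # Primary/secondary amine N: 1-2 heavy neighbours within bond distance.
  is_n <- lig$element == "N"
  amine <- logical(nrow(lig))
  if (any(is_n) && nrow(lig) > 1L) {
    d2 <- dist2_cross(lxyz, lxyz)
    nb <- rowSums(d2 < 1.8^2) - 1L
    amine <- is_n & nb >= 1L & nb <= 2L
  }

  amine_network <- FALSE
  amine_atom <- NA_character_
  amine_dists <- c(glu205 = NA_real_, glu206 = NA_real_, tyr662 = NA_real_)
  if (any(amine) && nrow(glu205) && nrow(glu206) && nrow(tyr662)) {
    axyz <- lxyz[amine, , drop = FALSE]
    d205 <- min_dist_to(axyz, glu205)
    d206 <- min_dist_to(axyz, glu206)
    d662 <- min_dist_to(axyz, tyr662)
    hit <- which(d205 < 4 & d206 < 4 & d662 < 5)
    if (length(hit)) {
      best <- hit[which.min(d205[hit] + d206[hit] + d662[hit])]
      amine_network <- TRUE
      amine_atom <- lig$name[amine][best]
      amine_dists <- c(glu205 = d205[best], glu206 = d206[best],
                       tyr662 = d662[best])
    }
  }

  polar <- lig$element %in% c("O", "N", "F", "CL", "BR", "I")
  arg_flag <- FALSE; asn_flag <- FALSE
  anchor_atom <- NA_character_; anchor_partner <- NA_character_
  anchor_dist <- NA_real_
  if (any(polar)) {
    pxyz <- lxyz[polar, , drop = FALSE]
    darg <- if (nrow(arg125)) min_dist_to(pxyz, arg125) else rep(Inf, nrow(pxyz))
    dasn <- if (nrow(asn710)) min_dist_to(pxyz, asn710) else rep(Inf, nrow(pxyz))
    arg_flag <- any(darg < 4)
    asn_flag <- any(dasn < 4)
    dmin <- pmin(darg, dasn)
    if (any(dmin < 4)) {
      best <- which.min(dmin)
      anchor_atom <- lig$name[polar][best]
      anchor_partner <- if (darg[best] <= dasn[best]) "arg125" else "asn710"
      anchor_dist <- dmin[best]
    }
  }

  cov_dist <- NA_real_
  covalent <- FALSE
  is_c <- lig$element == "C"
  if (any(is_c) && nrow(ser630)) {
    dcv <- min_dist_to(lxyz[is_c, , drop = FALSE], ser630)
    cov_dist <- min(dcv)
    covalent <- cov_dist < 3
  }

  structure(
    list(unit_id = unit$unit_id,
         amine_network = amine_network,
         amine_atom = amine_atom,
         amine_distances = amine_dists,
         polar_anchor = arg_flag || asn_flag,
         polar_anchor_arg125 = arg_flag,
         polar_anchor_asn710 = asn_flag,
         anchor_atom = anchor_atom,
         anchor_partner = anchor_partner,
         anchor_distance = anchor_dist,
         covalent_ser630 = covalent,
         covalent_distance = cov_dist),
    class = "binding_mode_record")
}

#' @export
print.binding_mode_record <- function(x, ...) {
  yn <- function(f) if (f) "yes" else "no"
  cat("<binding_mode_record> ", x$unit_id, "\n",
      "  amine network:  ", yn(x$amine_network),
      if (x$amine_network) paste0(" (", x$amine_atom, ")") else "", "\n",
      "  polar anchor:   ", yn(x$polar_anchor),
      if (x$polar_anchor) paste0(" (", x$anchor_atom, " -> ", x$anchor_partner,
                                 ", ", format(x$anchor_distance, digits = 3), " A)") else "",
      "\n",
      "  covalent Ser630:", yn(x$covalent_ser630), "\n", sep = "")
  invisible(x)
}

#' Tabulate binding modes over an ensemble
#'
#' @param units List of `structure_unit` objects with ligands.
#' @param site_map See [classify_binding_modes()].
#' @return Data frame with one row per unit and logical/na columns for each
#'   mode, plus per-inhibitor prevalence attributes `"amine_prevalence"`,
#'   `"anchor_prevalence"` (fractions over distinct inhibitors).
#' @export
binding_mode_table <- function(units, site_map = default_site_map()) {
  check_units(units, min_n = 1L)
  with_lig <- Filter(function(u) !is.null(u$ligand), units)
  if (length(with_lig) == 0L) stop("no units carry a ligand")
  recs <- lapply(with_lig, classify_binding_modes, site_map = site_map)
  out <- data.frame(
    unit_id = vapply(recs, `[[`, character(1L), "unit_id"),
    ligand = vapply(with_lig, function(u) u$ligand$comp_id, character(1L)),
    amine_network = vapply(recs, `[[`, logical(1L), "amine_network"),
    polar_anchor = vapply(recs, `[[`, logical(1L), "polar_anchor"),
    covalent_ser630 = vapply(recs, `[[`, logical(1L), "covalent_ser630"),
    stringsAsFactors = FALSE
  )
  by_lig <- function(flag) {
    mean(vapply(split(out[[flag]], out$ligand), any, logical(1L)))
  }
  attr(out, "amine_prevalence") <- by_lig("amine_network")
  attr(out, "anchor_prevalence") <- by_lig("polar_anchor")
  rownames(out) <- NULL
  out
}
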