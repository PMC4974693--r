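#' Detect water sites conserved across units
#'
#' Waters of every unit are mapped into a common reference frame via the
#' global shared-C-alpha superposition of each unit onto the reference unit;
#' water oxygens within `identity_radius` (1 Angstrom by convention) of one
#' another are treated as the same structural water. Consensus sites are
#' formed by greedy centroid clustering: the pooled point with the most
#' in-radius neighbours seeds a site, one water per unit (the nearest) is
#' assigned, the centroid is recomputed once and membership finalized within
#' the radius, then the procedure repeats on the remaining pool. The result
#' is deterministic given the input; ties are broken by lowest unit id, then
#' lowest atom serial.
#'
#' Units without any deposited water are excluded from the support
#' denominator (DPP-4 convention: 238 sites supported by at least 61 of 143
#' water-bearing units).
#'
#' @param units List of `structure_unit` objects.
#' @param reference_unit `unit_id` of the frame-defining unit; default the
#'   first unit in the list.
#' @param identity_radius Clustering radius in Angstrom (> 0).
#' @param min_support_frac Minimum support as a fraction of water-bearing
#'   units; default 61/143.
#' @param min_support Optional absolute support threshold overriding the
#'   fraction.
#' @return Object of class `water_sites`: list with `sites` (data frame
#'   `site_id`, `x`, `y`, `z` (reference frame), `support`, `mean_b`),
#'   `members` (list of data frames keyed by `site_id`, holding `unit_id`,
#'   `eleno`, `dist` to centroid, `b` and original-frame coordinates),
#'   `n_units` (water-bearing), `identity_radius`, `reference_unit` and the
#'   support threshold applied.
#' @export
consensus_water_sites <- function(units, reference_unit = NULL,
                                  identity_radius = 1.0,
                                  min_support_frac = 61 / 143,
                                  min_support = NULL) {
  check_units(units, min_n = 1L)
  if (identity_radius <= 0) stop("identity_radius must be > 0")
  ids <- vapply(units, function(u) u$unit_id, character(1L))
  if (is.null(reference_unit)) reference_unit <- ids[1L]
  ref_idx <- match(reference_unit, ids)
  if (is.na(ref_idx)) stop("reference unit '", reference_unit, "' not in ensemble")
  ref_ca <- unit_ca(units[[ref_idx]])

  has_water <- vapply(units, function(u) nrow(u$waters) > 0L, logical(1L))
  contrib <- which(has_water)
  if (length(contrib) == 0L) stop("no unit carries any water")

  pool <- do.call(rbind, lapply(contrib, function(i) {
    u <- units[[i]]
    w <- xyz_mat(u$waters)
    if (i != ref_idx) {
      shared <- intersect(rownames(unit_ca(u)), rownames(ref_ca))
      if (length(shared) < 3L) {
        stop("unit ", u$unit_id, " shares fewer than 3 C-alpha atoms with the reference")
      }
      ca <- unit_ca(u)
      sup <- superpose_kabsch(ca[shared, , drop = FALSE],
                              ref_ca[shared, , drop = FALSE])
      w <- apply_superposition(sup, w)
    }
    data.frame(unit_id = u$unit_id, eleno = u$waters$eleno,
               x = w[, 1L], y = w[, 2L], z = w[, 3L],
               ox = u$waters$x, oy = u$waters$y, oz = u$waters$z,
               b = u$waters$b, stringsAsFactors = FALSE)
  }))
  pool <- pool[order(pool$unit_id, pool$eleno), , drop = FALSE]
  rownames(pool) <- NULL

  cl <- greedy_cluster(as.matrix(pool[, c("x", "y", "z")]), pool$unit_id,
                       identity_radius)

  n_contrib <- length(contrib)
  thr <- if (!is.null(min_support)) min_support else
    ceiling(min_support_frac * n_contrib - 1e-9)

  support <- vapply(cl, function(s) length(s$members), integer(1L))
  ord <- order(-support, seq_along(cl))
  cl <- cl[ord]
  support <- support[ord]
  keep <- support >= thr
  cl <- cl[keep]
  support <- support[keep]

  sites <- data.frame(
    site_id = if (length(cl)) paste0("S", seq_along(cl)) else character(0L),
    x = vapply(cl, function(s) s$centroid[1L], numeric(1L)),
    y = vapply(cl, function(s) s$centroid[2L], numeric(1L)),
    z = vapply(cl, function(s) s$centroid[3L], numeric(1L)),
    support = support,
    mean_b = vapply(cl, function(s) mean(pool$b[s$members]), numeric(1L)),
    stringsAsFactors = FALSE
  )
  members <- lapply(cl, function(s) {
    m <- pool[s$members, c("unit_id", "eleno", "ox", "oy", "oz", "b"), drop = FALSE]
    pt <- as.matrix(pool[s$members, c("x", "y", "z"), drop = FALSE])
    m$dist <- sqrt(rowSums(sweep(pt, 2L, s$centroid)^2))
    rownames(m) <- NULL
    m
  })
  names(members) <- sites$site_id

  structure(
    list(sites = sites, members = members,
         n_units = n_contrib,
         identity_radius = identity_radius,
         reference_unit = reference_unit,
         min_support = thr),
    class = "water_sites")
}

# Greedy centroid clustering of 3-D points with a one-member-per-unit rule.
# Points must be supplied in deterministic (unit_id, serial) order.
greedy_cluster <- function(xyz, unit_id, radius) {
  n <- nrow(xyz)
  if (n == 0L) return(list())
  r2 <- radius^2
  nbr <- dist2_cross(xyz, xyz) <= r2
  alive <- rep(TRUE, n)
  counts <- rowSums(nbr)
  out <- list()
  while (any(alive)) {
    cand <- counts
    cand[!alive] <- -1L
    seed <- which.max(cand)  # ties -> first in (unit_id, serial) order

    first <- which(alive & nbr[seed, ])
    first <- pick_per_unit(first, unit_id,
                           rowSums(sweep(xyz[first, , drop = FALSE], 2L,
                                         xyz[seed, ])^2))
    centroid <- colMeans(xyz[first, , drop = FALSE])

    d2c <- rowSums(sweep(xyz, 2L, centroid)^2)
    mem <- which(alive & d2c <= r2)
    if (length(mem) == 0L) {
      mem <- seed
      centroid <- xyz[seed, ]
    } else {
      mem <- pick_per_unit(mem, unit_id, d2c[mem])
    }

    out[[length(out) + 1L]] <- list(centroid = centroid, members = mem)
    alive[mem] <- FALSE
    counts <- counts - rowSums(nbr[, mem, drop = FALSE])
  }
  out
}

# Among candidate point indices, keep the nearest per unit (ties -> first,
# i.e. lowest serial given the pool ordering).
pick_per_unit <- function(idx, unit_id, d2) {
  sel <- idx[order(unit_id[idx], d2, idx)]
  sel[!duplicated(unit_id[sel])]
}

#' @export
print.water_sites <- function(x, ...) {
  cat("<water_sites> ", nrow(x$sites), " sites with support >= ", x$min_support,
      " (of ", x$n_units, " water-bearing units)\n",
      "  reference frame: ", x$reference_unit,
      ", identity radius ", x$identity_radius, " A\n", sep = "")
  if (nrow(x$sites)) print(utils::head(x$sites, 10L))
  invisible(x)
}

#' Annotate conserved water sites
#'
#' Adds, per site: whether any member water lies within 4 Angstrom of a heavy
#' atom of a binding-area (extended-set) residue in that member's own unit;
#' the number of member units whose ligand has a heavy atom within
#' 5 Angstrom of the member water; and B-factor comparisons, i.e. the
#' fraction of member waters whose B is lower than the mean B of all water
#' oxygens of their unit, and than the mean B of all protein heavy atoms of
#' their unit (hydrated-versus-incidental crystal water diagnostic). The
#' site is flagged `low_b` when both fractions exceed 0.5.
#'
#' @param sites A `water_sites` object.
#' @param binding_area A `binding_area` object (or `NULL` to skip the
#'   proximity flag).
#' @param units The units the sites were computed from.
#' @return `sites` with columns `near_binding_area`, `near_ligand_count`,
#'   `frac_b_below_water`, `frac_b_below_protein`, `low_b` appended to
#'   `$sites`.
#' @export
annotate_water_sites <- function(sites, binding_area, units) {
  stopifnot(inherits(sites, "water_sites"))
  check_units(units, min_n = 1L)
  umap <- stats::setNames(units, vapply(units, function(u) u$unit_id, character(1L)))

  area_res <- if (!is.null(binding_area)) binding_area$extended_set else integer(0L)
  unit_water_b <- vapply(umap, function(u) {
    if (nrow(u$waters)) mean(u$waters$b) else NA_real_
  }, numeric(1L))
  unit_prot_b <- vapply(umap, function(u) mean(u$atoms$b), numeric(1L))

  n_sites <- nrow(sites$sites)
  near_area <- logical(n_sites)
  near_lig <- integer(n_sites)
  f_bw <- numeric(n_sites)
  f_bp <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    m <- sites$members[[s]]
    wxyz <- as.matrix(m[, c("ox", "oy", "oz")])
    hit_area <- FALSE
    nlig <- 0L
    for (r in seq_len(nrow(m))) {
      u <- umap[[m$unit_id[r]]]
      if (is.null(u)) next
      w <- wxyz[r, , drop = FALSE]
      if (!hit_area && length(area_res)) {
        pa <- u$atoms[u$atoms$resno %in% area_res, , drop = FALSE]
        if (nrow(pa) && min_dist_to(w, xyz_mat(pa)) < 4) hit_area <- TRUE
      }
      if (!is.null(u$ligand) &&
          min_dist_to(w, xyz_mat(u$ligand$atoms)) < 5) {
        nlig <- nlig + 1L
      }
    }
    near_area[s] <- hit_area
    near_lig[s] <- nlig
    f_bw[s] <- mean(m$b < unit_water_b[m$unit_id], na.rm = TRUE)
    f_bp[s] <- mean(m$b < unit_prot_b[m$unit_id], na.rm = TRUE)
  }
  sites$sites$near_binding_area <- near_area
  sites$sites$near_ligand_count <- near_lig
  sites$sites$frac_b_below_water <- f_bw
  sites$sites$frac_b_below_protein <- f_bp
  sites$sites$low_b <- f_bw > 0.5 & f_bp > 0.5
  sites
}
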