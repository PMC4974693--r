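no_noise_spec <- function(n_units = 3L, ...) {
  ensemble_spec(n_units = n_units, n_residues = 40L, sigma = 0,
                n_planted_sites = 0L, n_random_waters = 0L, ...)
}

test_that("identical units give zero RMSD and zero variation everywhere", {
  e <- generate_ensemble(no_noise_spec(rot_deg = 0, trans_A = 0, seed = 1L))
  rs <- rmsd_summary(e$units)
  expect_equal(rs$pairs$rmsd, rep(0, 3L), tolerance = 1e-9)
  expect_equal(rs$mean, 0, tolerance = 1e-9)
  expect_equal(rs$max, 0, tolerance = 1e-9)
  cv <- calpha_variation(e$units)
  expect_equal(cv$variation, rep(0, nrow(cv)), tolerance = 1e-9)
  sv <- sidechain_variation(e$units)
  expect_equal(sv$variation, rep(0, nrow(sv)), tolerance = 1e-8)
})

test_that("a pure rigid motion between units is fully removed", {
  e <- generate_ensemble(no_noise_spec(n_units = 2L, rot_deg = 180,
                                       trans_A = 10, seed = 2L))
  rs <- rmsd_summary(e$units)
  # Residual bounded by the generator's 3-decimal coordinate precision.
  expect_lt(rs$pairs$rmsd, 1e-3)
})

test_that("Gaussian displacement reproduces the Maxwell-mean and RMSD laws", {
  # Difference of two sigma-noised copies: per-coordinate variance 2 sigma^2,
  # so E[RMSD^2] = 6 sigma^2 and E|delta| = 4 sigma / sqrt(pi).
  sigma <- 0.15
  e <- generate_ensemble(ensemble_spec(n_units = 10L, n_residues = 300L,
                                       sigma = sigma, with_ligand = FALSE,
                                       n_planted_sites = 0L,
                                       n_random_waters = 0L, seed = 3L))
  rs <- rmsd_summary(e$units)
  expect_equal(rs$mean, sigma * sqrt(6), tolerance = 0.05)
  cv <- calpha_variation(e$units)
  expect_equal(attr(cv, "mean_variation"), 4 * sigma / sqrt(pi),
               tolerance = 0.05)
  # Scale recovery: sigma-hat = variation * sqrt(pi) / 4.
  expect_equal(attr(cv, "mean_variation") * sqrt(pi) / 4, sigma,
               tolerance = 0.05)
})

test_that("planted high-mobility residues rank top in C-alpha variation", {
  n_res <- 200L
  sigma <- rep(0.1, n_res)
  planted <- c(12L, 30L, 55L, 78L, 90L, 120L, 141L, 160L, 185L, 198L)
  sigma[planted] <- 0.5
  e <- generate_ensemble(ensemble_spec(n_units = 10L, n_residues = n_res,
                                       sigma = sigma, with_ligand = FALSE,
                                       n_planted_sites = 0L,
                                       n_random_waters = 0L, seed = 4L))
  cv <- calpha_variation(e$units)
  top10 <- cv$resno[order(-cv$variation)][1:10]
  expect_setequal(top10, as.integer(names(e$truth$sigma))[planted])
})

test_that("variation recomputed from stored pair distances is exact", {
  e <- generate_ensemble(ensemble_spec(n_units = 5L, n_residues = 30L,
                                       sigma = 0.2, with_ligand = FALSE,
                                       n_planted_sites = 0L,
                                       n_random_waters = 0L,
                                       missing_residue_rate = 0.05, seed = 5L))
  cv <- calpha_variation(e$units, keep_pairs = TRUE)
  pd <- attr(cv, "pair_distances")
  for (i in seq_len(nrow(cv))) {
    d <- pd[[as.character(cv$resno[i])]]
    expect_equal(length(d), cv$n_pairs[i])
    # Equal up to floating-point summation order.
    if (cv$n_pairs[i] > 0L) {
      expect_equal(cv$variation[i], mean(d), tolerance = 1e-12)
    }
  }
})

test_that("pairs missing a residue are dropped from that residue's M", {
  e <- generate_ensemble(no_noise_spec(n_units = 3L, rot_deg = 0,
                                       trans_A = 0, seed = 6L))
  u <- e$units
  drop_res <- u[[3L]]$atoms$resno[1L]
  u[[3L]]$atoms <- u[[3L]]$atoms[u[[3L]]$atoms$resno != drop_res, ]
  cv <- calpha_variation(u)
  expect_equal(cv$n_pairs[cv$resno == drop_res], 1L)
  expect_equal(unique(cv$n_pairs[cv$resno != drop_res]), 3L)
})

test_that("side-chain variation equals the chord of a pure chi1-type rotation", {
  base <- make_atoms(c("N", "CA", "C", "OG"),
                     rbind(c(-1.2, 0.9, 0), c(0, 0, 0), c(1.2, 0.9, 0.4),
                           c(0.8, -1.6, 0.9)),
                     resno = 1L, resname = "SER")
  axis <- c(0.3, -1, 0.2)
  ang <- 120
  rot <- rotation_about(axis, ang)
  rotated <- base
  og <- as.numeric(base[base$name == "OG", c("x", "y", "z")])
  og2 <- as.numeric(rot %*% og)
  rotated[rotated$name == "OG", c("x", "y", "z")] <- as.list(og2)

  u1 <- make_unit(base, unit_id = "U1_A")
  u2 <- make_unit(rotated, unit_id = "U2_A")
  sv <- sidechain_variation(list(u1, u2), residues = 1L)

  # Chord length of the reporter about the rotation axis (through the origin).
  ax <- axis / sqrt(sum(axis^2))
  r_perp <- sqrt(sum(og^2) - sum(og * ax)^2)
  chord <- 2 * r_perp * sin(ang / 2 * pi / 180)
  expect_equal(sv$variation, chord, tolerance = 1e-9)
})

test_that("a resampled rotamer circle shows up as elevated variation", {
  mk <- function(theta, id) {
    at <- rbind(
      make_atoms(c("N", "CA", "C", "OG"),
                 rbind(c(-1.2, 0.9, 0), c(0, 0, 0), c(1.2, 0.9, 0.4),
                       c(1.2 * cos(theta), -1.4, 1.2 * sin(theta))),
                 resno = 1L, resname = "SER"),
      make_atoms(c("N", "CA", "C", "OG"),
                 rbind(c(8.8, 0.9, 0), c(10, 0, 0), c(11.2, 0.9, 0.4),
                       c(10.8, -1.6, 0.9)),
                 resno = 2L, resname = "SER"))
    make_unit(at, unit_id = id)
  }
  set.seed(8)
  units <- lapply(1:6, function(i) mk(runif(1L, 0, 2 * pi),
                                      sprintf("U%d_A", i)))
  sv <- sidechain_variation(units)
  expect_gt(sv$variation[sv$resno == 1L], sv$variation[sv$resno == 2L])
  expect_equal(sv$variation[sv$resno == 2L], 0, tolerance = 1e-9)
})

test_that("multi-atom reporters are averaged with fixed correspondence", {
  base <- make_atoms(c("N", "CA", "C", "CB", "CG1", "CG2"),
                     rbind(c(-1.2, 0.9, 0), c(0, 0, 0), c(1.2, 0.9, 0.4),
                           c(0, -1.5, 0.3), c(0.8, -2.6, 0.3),
                           c(-0.8, -2.6, 0.3)),
                     resno = 1L, resname = "VAL")
  moved <- base
  moved[moved$name == "CG1", "x"] <- moved[moved$name == "CG1", "x"] + 0.4
  moved[moved$name == "CG2", "x"] <- moved[moved$name == "CG2", "x"] + 0.8
  sv <- sidechain_variation(list(make_unit(base, unit_id = "U1_A"),
                                 make_unit(moved, unit_id = "U2_A")),
                            residues = 1L)
  expect_equal(sv$variation, (0.4 + 0.8) / 2, tolerance = 1e-9)
  expect_equal(sv$atom_role, "CG1+CG2")
})

test_that("side-chain variation is invariant to whole-unit rigid motion", {
  e <- generate_ensemble(ensemble_spec(n_units = 3L, n_residues = 30L,
                                       sigma = 0.2, with_ligand = FALSE,
                                       n_planted_sites = 0L,
                                       n_random_waters = 0L, seed = 9L))
  sv1 <- sidechain_variation(e$units)
  moved <- e$units
  moved[[2L]] <- transform_unit(moved[[2L]], rotation_about(c(1, 2, 3), 71),
                                c(30, -12, 5))
  sv2 <- sidechain_variation(moved)
  expect_equal(sv2$variation, sv1$variation, tolerance = 1e-8)

  # C-alpha variation, by contrast, responds to internal deformation.
  cv1 <- calpha_variation(e$units)
  deformed <- e$units
  idx <- deformed[[2L]]$atoms$resno == deformed[[2L]]$atoms$resno[1L]
  deformed[[2L]]$atoms$x[idx] <- deformed[[2L]]$atoms$x[idx] + 3
  cv2 <- calpha_variation(deformed)
  expect_false(isTRUE(all.equal(cv1$variation, cv2$variation,
                                tolerance = 1e-6)))
})

test_that("an amino acid without a reporter entry errors in strict mode", {
  at <- make_atoms(c("N", "CA", "C"),
                   rbind(c(-1.2, 0.9, 0), c(0, 0, 0), c(1.2, 0.9, 0.4)),
                   resno = 1L, resname = "GLY")
  units <- list(make_unit(at, unit_id = "U1_A"),
                make_unit(at, unit_id = "U2_A"))
  expect_error(sidechain_variation(units, residues = 1L), "no reporter atom")
  expect_equal(nrow(sidechain_variation(units)), 0L)  # skipped silently
})
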