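test_that("parse_pdb separates protein, ligand and water records", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 41, 11, 6, -6.5, element = "C"),
    pdb_line("HETATM", 2, "C1", "LIG", "A", 900, 1, 2, 3, element = "C"),
    pdb_line("HETATM", 3, "O", "HOH", "A", 901, 2, 2, 3, element = "O"),
    "END")
  m <- parse_pdb(lines, id = "TOY")
  expect_s3_class(m, "pdb_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(sum(m$atoms$rectype == "ATOM"), 1L)
  expect_equal(sum(m$atoms$is_hetero), 1L)
  expect_equal(sum(m$atoms$is_water), 1L)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 41, 1, 0, 0, occ = 0.6, altloc = "A",
             element = "C"),
    pdb_line("ATOM", 2, "CA", "SER", "A", 41, 2, 0, 0, occ = 0.4, altloc = "B",
             element = "C"),
    "END")
  m <- parse_pdb(lines)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$altloc, "A")
  expect_equal(m$atoms$x, 1)

  # Occupancy tie: lexicographically first altloc wins.
  tie <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 41, 1, 0, 0, occ = 0.5, altloc = "B",
             element = "C"),
    pdb_line("ATOM", 2, "CA", "SER", "A", 41, 2, 0, 0, occ = 0.5, altloc = "A",
             element = "C"),
    "END")
  expect_equal(parse_pdb(tie)$atoms$altloc, "A")
})

test_that("hydrogens are dropped and hydrogen-only input errors", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 41, 1, 0, 0, element = "C"),
    pdb_line("ATOM", 2, "H", "SER", "A", 41, 1.5, 0, 0, element = "H"),
    "END")
  expect_equal(nrow(parse_pdb(lines)$atoms), 1L)
  only_h <- c(pdb_line("ATOM", 1, "H", "SER", "A", 41, 1, 0, 0, element = "H"),
              "END")
  expect_error(parse_pdb(only_h), "no heavy atoms")
})

test_that("malformed and empty input give informative parse errors", {
  bad <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 41, 1, 0, 0, element = "C"),
    "ATOM      2  CA  SER A  42      xx.xxx   6.000  -5.400  1.00 10.00           C",
    "END")
  expect_error(parse_pdb(bad), "line 2.*malformed coordinate")
  expect_error(parse_pdb(c("HEADER", "END")), "empty model")
  ins <- c(pdb_line("ATOM", 1, "CA", "SER", "A", 41, 1, 0, 0, element = "C"))
  ins <- sub("^(.{26}).", "\\1A", ins)  # set insertion-code column
  expect_error(parse_pdb(c(ins, "END")), "insertion codes")
})

make_toy_model <- function(ligand_xyz = c(4 * 3, -3.0, 0.3),
                           water_xyz = NULL, drop_resno = integer(0L),
                           second_ligand_xyz = NULL) {
  prot <- toy_protein(10L)
  prot <- prot[!prot$resno %in% drop_resno, , drop = FALSE]
  lines <- character(0L)
  k <- 0L
  for (i in seq_len(nrow(prot))) {
    k <- k + 1L
    lines <- c(lines, pdb_line("ATOM", k, prot$name[i], "ALA", "A",
                               prot$resno[i], prot$x[i], prot$y[i], prot$z[i],
                               element = prot$element[i]))
  }
  if (!is.null(ligand_xyz)) {
    lig <- matrix(ligand_xyz, ncol = 3L)
    for (i in seq_len(nrow(lig))) {
      k <- k + 1L
      lines <- c(lines, pdb_line("HETATM", k, paste0("C", i), "LIG", "A", 900,
                                 lig[i, 1], lig[i, 2], lig[i, 3], element = "C"))
    }
  }
  if (!is.null(second_ligand_xyz)) {
    k <- k + 1L
    lines <- c(lines, pdb_line("HETATM", k, "C1", "XYZ", "A", 910,
                               second_ligand_xyz[1], second_ligand_xyz[2],
                               second_ligand_xyz[3], element = "C"))
  }
  if (!is.null(water_xyz)) {
    w <- matrix(water_xyz, ncol = 3L)
    for (i in seq_len(nrow(w))) {
      k <- k + 1L
      lines <- c(lines, pdb_line("HETATM", k, "O", "HOH", "A", 950 + i,
                                 w[i, 1], w[i, 2], w[i, 3], element = "O"))
    }
  }
  parse_pdb(c(lines, "END"), id = "TOY")
}

test_that("build_unit accepts a complete chain with a bound ligand", {
  # Ligand carbon 3.0 A below residue 3's CB -> bound at the active centre.
  m <- make_toy_model(ligand_xyz = c(12, -4.5, 0.3))
  u <- build_unit(m, "A", span = c(1L, 10L), active_site_residue = 3L)
  expect_s3_class(u, "structure_unit")
  expect_equal(u$disordered_count, 0L)
  expect_equal(u$ligand$comp_id, "LIG")
  expect_equal(length(unique(u$atoms$resno)), 10L)
})

test_that("build_unit rejects at the disorder threshold and missing ligand", {
  m <- make_toy_model(ligand_xyz = c(12, -4.5, 0.3), drop_resno = 5:10)
  r <- build_unit(m, "A", span = c(1L, 10L), active_site_residue = 3L)
  expect_s3_class(r, "unit_rejection")
  expect_match(r$reason, "disordered residues >= 6")

  # 5 missing residues still passes the default threshold of 6.
  m5 <- make_toy_model(ligand_xyz = c(12, -4.5, 0.3), drop_resno = 5:9)
  expect_s3_class(build_unit(m5, "A", span = c(1L, 10L),
                             active_site_residue = 3L), "structure_unit")

  far <- make_toy_model(ligand_xyz = c(12, -30, 0))
  r2 <- build_unit(far, "A", span = c(1L, 10L), active_site_residue = 3L)
  expect_s3_class(r2, "unit_rejection")
  expect_match(r2$reason, "no ligand")
})

test_that("build_unit errors on missing chains and ambiguous ligands", {
  m <- make_toy_model()
  expect_error(build_unit(m, "Z", span = c(1L, 10L)), "chain 'Z' not found")
  amb <- make_toy_model(ligand_xyz = c(12, -4.5, 0.3),
                        second_ligand_xyz = c(12, -4.0, -0.5))
  expect_error(build_unit(amb, "A", span = c(1L, 10L), active_site_residue = 3L),
               "multiple candidate ligands.*LIG_A_900.*XYZ_A_910")
  # Disambiguation by ligand_id succeeds.
  u <- build_unit(amb, "A", span = c(1L, 10L), active_site_residue = 3L,
                  ligand_id = "LIG_A_900")
  expect_equal(u$ligand$comp_id, "LIG")
})

test_that("water retention respects the 4 A rule at the boundary", {
  # Nearest protein heavy atom to both waters is residue 5's CB at (20,-1.5,0.3).
  m <- make_toy_model(ligand_xyz = c(12, -4.5, 0.3),
                      water_xyz = rbind(c(20, -5.4, 0.3),   # 3.9 A
                                        c(20, -5.6, 0.3)))  # 4.1 A
  u <- build_unit(m, "A", span = c(1L, 10L), active_site_residue = 3L)
  expect_equal(nrow(u$waters), 1L)
  expect_equal(u$waters$y, -5.4)
})

test_that("enlarging the water cutoff never decreases retained waters", {
  set.seed(42)
  w <- cbind(runif(40, 0, 45), runif(40, -12, 10), runif(40, -6, 6))
  m <- make_toy_model(ligand_xyz = c(12, -4.5, 0.3), water_xyz = w)
  counts <- vapply(c(2, 3, 4, 5, 6, 8), function(cut) {
    nrow(build_unit(m, "A", span = c(1L, 10L), active_site_residue = 3L,
                    water_cutoff = cut)$waters)
  }, numeric(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("units round-trip through PDB files", {
  e <- generate_ensemble(ensemble_spec(n_units = 2L, n_residues = 40L,
                                       sigma = 0.1, seed = 5L))
  u <- e$units[[1L]]
  f <- tempfile(fileext = ".pdb")
  write_unit_pdb(u, f)
  m <- parse_pdb(f, id = "SYN01")
  u2 <- build_unit(m, "A", span = u$span,
                   active_site_residue = e$truth$site_map$ser630)
  expect_s3_class(u2, "structure_unit")
  expect_equal(nrow(u2$atoms), nrow(u$atoms))
  expect_equal(nrow(u2$waters), nrow(u$waters))
  expect_equal(nrow(u2$ligand$atoms), nrow(u$ligand$atoms))
  ord <- function(df) df[order(df$resno, df$name), c("x", "y", "z")]
  expect_equal(unname(as.matrix(ord(u2$atoms))),
               unname(as.matrix(ord(u$atoms))), tolerance = 1e-9)
})

test_that("a gap-free span 41-764 yields exactly 724 residues", {
  e <- generate_ensemble(ensemble_spec(n_units = 1L, n_residues = 724L,
                                       sigma = 0, rot_deg = 0, trans_A = 0,
                                       with_ligand = FALSE,
                                       n_planted_sites = 0L,
                                       n_random_waters = 0L, seed = 1L))
  u <- e$units[[1L]]
  expect_equal(u$span, c(41L, 764L))
  expect_equal(length(unique(u$atoms$resno)), 724L)
})
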