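# Contact/binding-mode toy systems shared between test files.

# Two-residue toy: residue 1 heavy atom at origin, residue 2 at (8,0,0).
two_res_unit <- function(lig_x, comp = "LIG", id = "TOY_A") {
  at <- make_atoms(c("CA", "CA"), rbind(c(0, 0, 0), c(8, 0, 0)),
                   resno = c(1L, 2L))
  lig <- make_atoms("C1", c(lig_x, 0, 0), resno = 900L, resname = comp,
                    rectype = "HETATM")
  make_unit(at, ligand_atoms = lig, unit_id = id)
}

# Amine position: exactly 3.2 A from Glu205 OE1 at the origin and 3.5 A
# from Glu206 OE1 at (3,0,0); the Tyr662 OH of mode_unit sits 4.6 A above it.
n1 <- c(1.165, sqrt(3.2^2 - 1.165^2), 0)

# Role-residue toy for binding-mode classification. Each role residue holds
# just its functional atoms at hand-placed positions.
mode_unit <- function(lig, id = "TOY_A") {
  role <- function(name, resname, resno, xyz) {
    make_atoms(name, xyz, resno = resno, resname = resname)
  }
  at <- rbind(
    role(c("OE1", "OE2"), "GLU", 205L, rbind(c(0, 0, 0), c(0.5, -1.2, 0))),
    role(c("OE1", "OE2"), "GLU", 206L, rbind(c(3, 0, 0), c(3.5, -1.2, 0))),
    role("OH", "TYR", 662L, n1 + c(0, 0, 4.6)),
    role(c("NH1", "NH2"), "ARG", 125L, rbind(c(8, 8, 0), c(9, 8, 0))),
    role(c("ND2", "OD1"), "ASN", 710L, rbind(c(8, -8, 0), c(9, -8, 0))),
    role("OG", "SER", 630L, c(-4, 2, 0)))
  at$eleno <- seq_len(nrow(at))
  make_unit(at, ligand_atoms = lig, unit_id = id)
}

lig_atoms <- function(name, xyz) {
  la <- make_atoms(name, xyz, resno = 900L, resname = "LIG",
                   rectype = "HETATM")
  la$eleno <- seq_len(nrow(la))
  la
}
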