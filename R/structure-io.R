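#' Parse a PDB file into an atom model
#'
#' Reads ATOM/HETATM records (via \pkg{bio3d}), drops hydrogens, and resolves
#' alternate locations by keeping, for each atom, the altloc with the highest
#' occupancy (ties broken by the lexicographically first altloc label).
#' All downstream distance analysis is between heavy atoms only.
#'
#' @param x Path to a PDB file, or a character vector of PDB-format lines
#'   (a single string containing newlines is also accepted).
#' @param id Entry identifier used to form unit ids (e.g. `"1X70"`). Defaults
#'   to the file name without extension, or `"MODEL"` for in-memory text.
#' @return An object of class `pdb_model`: a list with `id` and `atoms`, a
#'   data frame with one row per heavy atom (columns `rectype`, `eleno`,
#'   `name`, `altloc`, `resname`, `chain`, `resno`, `x`, `y`, `z`, `occ`,
#'   `b`, `element`, `is_hetero`, `is_water`).
#' @examples
#' lines <- c(
#'   "ATOM      1  CA  SER A  41      11.000   6.000  -6.500  1.00 10.00           C",
#'   "HETATM    2  C1  LIG A 900       1.000   2.000   3.000  1.00 20.00           C",
#'   "HETATM    3  O   HOH A 901       2.000   2.000   3.000  1.00 30.00           O",
#'   "END")
#' m <- parse_pdb(lines, id = "TOY")
#' nrow(m$atoms)
#' @export
parse_pdb <- function(x, id = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    path <- x
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(x), "\n", fixed = TRUE))
    if (is.null(id)) id <- "MODEL"
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  }
  validate_pdb_lines(lines)
  if (!any(grepl("^(ATOM  |HETATM)", lines))) {
    stop("empty model: no ATOM/HETATM records found")
  }

  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$element <- ifelse(is.na(at$elesy) | at$elesy == "",
                       derive_element(at$elety), toupper(at$elesy))
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms in model")
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported; found on residue(s) ",
         paste(unique(at$resno[!is.na(at$insert)]), collapse = ", "))
  }

  at$occ <- ifelse(is.na(at$o), 1, at$o)
  at$altloc <- ifelse(is.na(at$alt), "", at$alt)
  at <- resolve_altlocs(at)

  atoms <- data.frame(
    rectype  = at$type,
    eleno    = at$eleno,
    name     = at$elety,
    altloc   = at$altloc,
    resname  = at$resid,
    chain    = at$chain,
    resno    = at$resno,
    x = at$x, y = at$y, z = at$z,
    occ = at$occ,
    b   = ifelse(is.na(at$b), 0, at$b),
    element = at$element,
    stringsAsFactors = FALSE
  )
  atoms$is_water  <- atoms$resname %in% c("HOH", "WAT")
  atoms$is_hetero <- atoms$rectype == "HETATM" & !atoms$is_water
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in model")
  }
  structure(list(id = id, atoms = atoms), class = "pdb_model")
}

validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      stop("parse error at line ", i, ": coordinate record too short")
    }
    for (fld in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1L], fld[2L])))
      if (is.na(v)) {
        stop("parse error at line ", i, ": malformed coordinate field")
      }
    }
  }
  invisible(TRUE)
}

# Element symbol from the atom-name column when columns 77-78 are absent.
derive_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1L, 2L)
  one <- substr(nm, 1L, 1L)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"), two, one)
}

resolve_altlocs <- function(at) {
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "\r")
  ord <- order(key, -at$occ, at$altloc)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

#' Build an analysis unit from a parsed model
#'
#' Applies the unit-selection rules of comparative cocrystal analysis: one
#' protein chain restricted to a residue span (DPP-4 convention: residues
#' 41-764, i.e. 724 residues), fewer than `max_disordered` disordered (fully
#' unresolved) residues, one inhibitor bound at the active centre (at least
#' one ligand heavy atom within `ligand_cutoff` of a heavy atom of the
#' active-site residue, Ser630 in DPP-4), and the water oxygens within
#' `water_cutoff` of any protein heavy atom of the unit.
#'
#' @param model A `pdb_model` from [parse_pdb()].
#' @param chain_id Chain to extract.
#' @param span Length-2 integer vector, inclusive residue-number interval.
#' @param active_site_residue Residue number defining the active centre.
#' @param ligand_cutoff,water_cutoff Distances in Angstrom.
#' @param max_disordered Units with this many or more missing span residues
#'   are rejected.
#' @param require_ligand If `FALSE` (inhibitor-free mode) no ligand is
#'   sought and its absence is not a rejection.
#' @param ligand_id Optional `resname_chain_resno` key disambiguating between
#'   several hetero molecules at the active site.
#' @return A `structure_unit` (list with `unit_id`, `atoms`, `ligand`,
#'   `waters`, `disordered_count`, `span`), or a `unit_rejection` (list with
#'   `unit_id`, `reason`) when the chain fails a selection rule.
#' @export
build_unit <- function(model, chain_id,
                       span = c(41L, 764L),
                       active_site_residue = 630L,
                       ligand_cutoff = 4.0,
                       water_cutoff = 4.0,
                       max_disordered = 6L,
                       require_ligand = TRUE,
                       ligand_id = NULL) {
  stopifnot(inherits(model, "pdb_model"), length(span) == 2L, span[1] <= span[2])
  at <- model$atoms
  if (!chain_id %in% at$chain) {
    stop("chain '", chain_id, "' not found in model '", model$id, "'")
  }
  unit_id <- paste0(model$id, "_", chain_id)

  prot <- at[at$rectype == "ATOM" & at$chain == chain_id & !at$is_water &
               at$resno >= span[1] & at$resno <= span[2], , drop = FALSE]
  n_expected <- span[2] - span[1] + 1L
  disordered <- n_expected - length(unique(prot$resno))
  if (disordered >= max_disordered) {
    return(structure(
      list(unit_id = unit_id,
           reason = sprintf("disordered residues >= %d (found %d)",
                            max_disordered, disordered)),
      class = "unit_rejection"))
  }
  if (nrow(prot) == 0L) {
    return(structure(list(unit_id = unit_id, reason = "no protein atoms in span"),
                     class = "unit_rejection"))
  }

  ligand <- NULL
  if (require_ligand) {
    site <- prot[prot$resno == active_site_residue, , drop = FALSE]
    if (nrow(site) == 0L) {
      return(structure(
        list(unit_id = unit_id,
             reason = sprintf("active-site residue %d unresolved", active_site_residue)),
        class = "unit_rejection"))
    }
    het <- at[at$is_hetero, , drop = FALSE]
    if (nrow(het) > 0L) {
      key <- paste(het$resname, het$chain, het$resno, sep = "_")
      cand <- unique(key[min_dist_to(xyz_mat(het), xyz_mat(site)) < ligand_cutoff])
      if (!is.null(ligand_id)) cand <- intersect(cand, ligand_id)
      if (length(cand) > 1L) {
        stop("multiple candidate ligands at the active site of ", unit_id, ": ",
             paste(cand, collapse = ", "),
             "; disambiguate with ligand_id")
      }
      if (length(cand) == 1L) {
        lat <- het[key == cand, , drop = FALSE]
        ligand <- list(id = cand,
                       comp_id = lat$resname[1L],
                       atoms = lat)
      }
    }
    if (is.null(ligand)) {
      return(structure(
        list(unit_id = unit_id, reason = "no ligand bound at the active centre"),
        class = "unit_rejection"))
    }
  }

  wat <- at[at$is_water & at$element == "O", , drop = FALSE]
  if (nrow(wat) > 0L) {
    keep <- min_dist_to(xyz_mat(wat), xyz_mat(prot)) < water_cutoff
    wat <- wat[keep, , drop = FALSE]
  }

  structure(
    list(unit_id = unit_id,
         atoms = prot,
         ligand = ligand,
         waters = wat,
         disordered_count = disordered,
         span = as.integer(span)),
    class = "structure_unit")
}

#' @export
print.structure_unit <- function(x, ...) {
  cat("<structure_unit> ", x$unit_id, "\n",
      "  residues: ", length(unique(x$atoms$resno)),
      " (span ", x$span[1], "-", x$span[2],
      ", disordered ", x$disordered_count, ")\n",
      "  ligand:   ", if (is.null(x$ligand)) "none" else
        paste0(x$ligand$id, " (", nrow(x$ligand$atoms), " heavy atoms)"), "\n",
      "  waters:   ", nrow(x$waters), "\n", sep = "")
  invisible(x)
}

#' @export
print.unit_rejection <- function(x, ...) {
  cat("<unit_rejection> ", x$unit_id, ": ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Write a unit back to PDB format
#'
#' Protein atoms are emitted as ATOM records, the ligand and waters as
#' HETATM records. Coordinates are written at the format's 3-decimal
#' precision, so a write/parse round trip preserves them to 0.001 Angstrom.
#'
#' @param unit A `structure_unit`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_unit_pdb <- function(unit, file) {
  stopifnot(inherits(unit, "structure_unit"))
  parts <- list(unit$atoms)
  if (!is.null(unit$ligand)) parts <- c(parts, list(unit$ligand$atoms))
  if (nrow(unit$waters) > 0L) parts <- c(parts, list(unit$waters))
  at <- do.call(rbind, parts)
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(xyz_mat(at))),
    type = at$rectype,
    resno = at$resno,
    resid = at$resname,
    eleno = seq_len(nrow(at)),
    elety = at$name,
    chain = at$chain,
    o = at$occ,
    b = at$b,
    elesy = at$element
  )
  invisible(file)
}

#' Extract all qualifying units from a directory of PDB files
#'
#' Convenience wrapper applying [build_unit()] to every chain of every
#' `*.pdb` file, keeping, per entry, either all qualifying chains or only
#' the first in file order.
#'
#' @inheritParams build_unit
#' @param dir Directory containing `.pdb` files.
#' @param one_per_entry Keep only the first qualifying chain per file
#'   (the convention when several copies of the protein share an entry).
#' @param ... Passed to [build_unit()].
#' @return List with `units` (accepted `structure_unit`s) and `rejections`.
#' @export
extract_units <- function(dir, one_per_entry = FALSE, ...) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  units <- list()
  rejections <- list()
  for (f in files) {
    model <- parse_pdb(f)
    chains <- unique(model$atoms$chain[model$atoms$rectype == "ATOM"])
    for (ch in chains) {
      res <- build_unit(model, ch, ...)
      if (inherits(res, "structure_unit")) {
        units[[res$unit_id]] <- res
        if (one_per_entry) break
      } else {
        rejections[[res$unit_id]] <- res
      }
    }
  }
  list(units = units, rejections = rejections)
}

# Shared heavy-atom coordinate helpers ---------------------------------------

# C-alpha coordinates of a unit, rownames = residue numbers.
unit_ca <- function(unit) {
  ca <- unit$atoms[unit$atoms$name == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  m <- xyz_mat(ca)
  rownames(m) <- ca$resno
  m
}

residue_atoms <- function(unit, resno) {
  unit$atoms[unit$atoms$resno == resno, , drop = FALSE]
}
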