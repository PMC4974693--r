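#' Pipeline configuration
#'
#' @param input Either a directory of PDB files or a list of
#'   `structure_unit` objects.
#' @param span,active_site_residue,ligand_cutoff,water_cutoff,max_disordered
#'   Unit-selection rules, see [build_unit()].
#' @param contact_cutoff,high_fraction,low_fraction Binding-area thresholds,
#'   see [binding_area_from_contacts()].
#' @param identity_radius,min_support_frac Conserved-water parameters, see
#'   [consensus_water_sites()].
#' @param site_map Binding-mode role map, see [classify_binding_modes()].
#' @param reference_unit Reference frame for water clustering (default:
#'   first unit).
#' @param probe_radius,sasa_points Surface-area parameters.
#' @param with_ligand `FALSE` runs inhibitor-free mode: the contact,
#'   binding-mode and water-ligand-proximity stages are skipped.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a `report.json`.
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(input,
                       span = c(41L, 764L),
                       active_site_residue = 630L,
                       ligand_cutoff = 4.0,
                       water_cutoff = 4.0,
                       max_disordered = 6L,
                       contact_cutoff = 4.0,
                       high_fraction = 0.70,
                       low_fraction = 0.30,
                       identity_radius = 1.0,
                       min_support_frac = 61 / 143,
                       site_map = default_site_map(),
                       reference_unit = NULL,
                       probe_radius = 1.4,
                       sasa_points = 960L,
                       with_ligand = TRUE,
                       out_dir = NULL) {
  thr <- c(ligand_cutoff, water_cutoff, contact_cutoff, identity_radius,
           probe_radius)
  if (any(thr <= 0)) stop("all distance thresholds must be positive")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full cocrystal-ensemble analysis
#'
#' Orchestrates unit extraction, all-pairs superposition, C-alpha and
#' side-chain variation, binding-area and binding-mode analysis, conserved
#' water detection with annotation, and ensemble surface-area profiling.
#' All stages are deterministic, so a rerun on the same inputs reproduces
#' the report byte for byte.
#'
#' @param config A `run_config`.
#' @return Object of class `xtalvar_report`: list with `units`,
#'   `rejections`, `rmsd`, `calpha`, `sidechain`, `binding_area`, `modes`,
#'   `waters`, `sasa`, `config` and `headline` (the aggregate numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(config$input)) {
    ex <- extract_units(config$input,
                        span = config$span,
                        active_site_residue = config$active_site_residue,
                        ligand_cutoff = config$ligand_cutoff,
                        water_cutoff = config$water_cutoff,
                        max_disordered = config$max_disordered,
                        require_ligand = config$with_ligand)
    units <- ex$units
    rejections <- ex$rejections
  } else {
    units <- config$input
    rejections <- Filter(function(u) inherits(u, "unit_rejection"), units)
    units <- Filter(function(u) inherits(u, "structure_unit"), units)
  }
  if (length(units) < 2L) {
    stop("pipeline needs at least 2 accepted units (got ", length(units), ")")
  }
  for (r in rejections) {
    message("rejected ", r$unit_id, ": ", r$reason)
  }

  rmsd <- rmsd_summary(units)
  calpha <- calpha_variation(units)
  sidechain <- sidechain_variation(units)

  area <- NULL
  modes <- NULL
  if (config$with_ligand) {
    area <- binding_area_from_contacts(units,
                                       cutoff = config$contact_cutoff,
                                       high_fraction = config$high_fraction,
                                       low_fraction = config$low_fraction)
    modes <- binding_mode_table(units, site_map = config$site_map)
  }

  waters <- NULL
  n_water_units <- sum(vapply(units, function(u) nrow(u$waters) > 0L, logical(1L)))
  if (n_water_units >= 1L) {
    waters <- consensus_water_sites(units,
                                    reference_unit = config$reference_unit,
                                    identity_radius = config$identity_radius,
                                    min_support_frac = config$min_support_frac)
    waters <- annotate_water_sites(waters, area, units)
  }

  sasa <- ensemble_sasa(units, probe_radius = config$probe_radius,
                        n_points = config$sasa_points)

  headline <- list(
    n_units = length(units),
    n_rejections = length(rejections),
    n_pairs = pair_combinations(length(units)),
    mean_rmsd = rmsd$mean,
    max_rmsd = rmsd$max,
    mean_calpha_variation = attr(calpha, "mean_variation"),
    binding_area_core = if (!is.null(area)) area$core_set,
    binding_area_extended = if (!is.null(area)) area$extended_set,
    amine_network_prevalence = if (!is.null(modes)) attr(modes, "amine_prevalence"),
    polar_anchor_prevalence = if (!is.null(modes)) attr(modes, "anchor_prevalence"),
    n_conserved_water_sites = if (!is.null(waters)) nrow(waters$sites) else 0L,
    water_min_support = if (!is.null(waters)) waters$min_support
  )

  report <- structure(
    list(units = units, rejections = rejections,
         rmsd = rmsd, calpha = calpha, sidechain = sidechain,
         binding_area = area, modes = modes, waters = waters, sasa = sasa,
         config = config, headline = headline),
    class = "xtalvar_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(report$rmsd$pairs, "rmsd_summary.tsv")
  tsv(report$calpha, "calpha_variation.tsv")
  tsv(report$sidechain, "sidechain_variation.tsv")
  if (!is.null(report$binding_area)) {
    ba <- report$binding_area
    tsv(data.frame(resno = as.integer(names(ba$fraction)),
                   contact_fraction = unname(ba$fraction),
                   unit_fraction = unname(ba$unit_fraction),
                   core = as.integer(names(ba$fraction)) %in% ba$core_set,
                   extended = as.integer(names(ba$fraction)) %in% ba$extended_set),
        "area.tsv")
  }
  if (!is.null(report$modes)) tsv(report$modes, "modes.tsv")
  if (!is.null(report$waters)) tsv(report$waters$sites, "waters.tsv")
  tsv(report$sasa, "sasa.tsv")

  cfg <- report$config
  cfg$input <- if (is.character(cfg$input)) cfg$input else "<in-memory units>"
  cfg$out_dir <- NULL
  manifest <- lapply(report$units, function(u) {
    list(unit_id = u$unit_id,
         disordered_count = u$disordered_count,
         ligand = if (!is.null(u$ligand)) u$ligand$id else NA,
         n_waters = nrow(u$waters))
  })
  jsonlite::write_json(
    list(headline = report$headline,
         config = unclass(cfg),
         units = manifest,
         rejections = lapply(report$rejections, function(r) {
           list(unit_id = r$unit_id, reason = r$reason)
         })),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.xtalvar_report <- function(x, ...) {
  h <- x$headline
  cat("<xtalvar_report> ", h$n_units, " units (", h$n_rejections,
      " rejected), ", h$n_pairs, " pairs\n",
      "  mean/max C-alpha RMSD: ",
      format(h$mean_rmsd, digits = 3), " / ",
      format(h$max_rmsd, digits = 3), " A\n",
      "  mean C-alpha variation: ",
      format(h$mean_calpha_variation, digits = 3), " A\n", sep = "")
  if (!is.null(h$binding_area_core)) {
    cat("  binding area: ", length(h$binding_area_core), " core / ",
        length(h$binding_area_extended), " extended residues\n",
        "  amine network prevalence: ",
        format(h$amine_network_prevalence, digits = 3), "\n", sep = "")
  }
  cat("  conserved water sites (support >= ",
      h$water_min_support %||% NA, "): ", h$n_conserved_water_sites,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.xtalvar_report <- function(object, ...) {
  object$headline
}
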