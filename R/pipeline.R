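#' Pipeline configuration
#'
#' All tunable parameters of the phantom-to-MI pipeline in one serialisable
#' list. Two bundled profiles: `"paper"` (1 mm voxels, 0.23 cm mesh edge,
#' ~1.2e5 tets — the full-scale experiment) and `"desk"` (3 mm voxels, 0.5 cm
#' edge, ~1.2e4 tets — a scaled-down run for a single CPU).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param seed integer noise seed.
#' @param targets dense-tissue percentages of the aging series.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(profile = c("desk", "paper"), seed = 42L,
                           targets = c(9, 27, 43, 53, 56)) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  structure(list(
    profile = profile,
    seed = as.integer(seed),
    noise = list(octaves = 4L, persistence = 0.5, base_cell_size = 2.5),
    shape = list(semi_posterior = c(8.5, 3.75, 3.7),
                 semi_anterior = c(8.5, 3.75, 3.7)),
    phantom = list(voxel_spacing = if (desk) 0.3 else 0.1,
                   tissue_levels = seq(1, 0.40, by = -0.05),
                   density_targets = targets,
                   calibration_tol = 0.25),
    mesh = list(target_edge = if (desk) 0.5 else 0.23,
                plate_band = 0.8, quadrature_order = 5L),
    materials = list(E_adipose = 20, E_gland = 80, nu = 0.49),
    compression = list(displacement = 3.76, n_steps = if (desk) 20L else 40L,
                       tol = 1e-6, penalty = 2000,
                       plate_extent_x = c(-10, 10),
                       plate_extent_z = c(0, 7.5)),
    mi = list(patch = 1, contact_floor = 0.1, retention = 0.27)),
    class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#' @param config a `pipeline_config`; @param path YAML path.
#' @return `save_config`: `path` invisibly; `load_config`: the config.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$noise$octaves <- as.integer(cfg$noise$octaves)
  cfg$mesh$quadrature_order <- as.integer(cfg$mesh$quadrature_order)
  cfg$compression$n_steps <- as.integer(cfg$compression$n_steps)
  for (nm in c("semi_posterior", "semi_anterior"))
    cfg$shape[[nm]] <- as.numeric(cfg$shape[[nm]])
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full virtual MI pipeline
#'
#' For every density target: threshold-calibrate the shared noise field,
#' assign element moduli to the (shared) mesh, solve plate compression, bin
#' the sensor-side MI map and summarise. The mesh, noise field and thresholds
#' are deterministic functions of the configuration.
#'
#' @param config a [default_config()]-style `pipeline_config`.
#' @param outdir optional directory for artifacts (phantoms, VTK meshes, MI
#'   CSV maps, JSON summaries, PNG figures); nothing is written when NULL.
#' @param verbose print stage progress?
#' @return list: `results` data frame (one row per density: dense %, reaction
#'   force N, contact area cm^2, mean stress kPa, retention-adjusted kPa,
#'   plus integer-rounded presentation columns), `maps`, `states`,
#'   `phantoms`, `mesh`, `config_hash`.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- .config_hash(config)

  shape <- breast_shape(config$shape$semi_posterior, config$shape$semi_anterior)
  maskinfo <- shape_mask(shape, config$phantom$voxel_spacing)
  say("phantom grid %s voxels (%d in mask)",
      paste(maskinfo$dims, collapse = "x"), sum(maskinfo$mask))

  lattice <- perlin_lattice(config$seed, config$noise$base_cell_size)
  spec <- octave_spec(config$noise$octaves, config$noise$persistence,
                      config$noise$base_cell_size)
  field <- sample_field(lattice, spec, maskinfo$dims,
                        config$phantom$voxel_spacing, maskinfo$origin)
  table <- tissue_table(config$phantom$tissue_levels)

  mesh <- tetrahedralize(shape, config$mesh$target_edge,
                         config$mesh$plate_band)
  say("mesh: %d nodes, %d tets", nrow(mesh$nodes), nrow(mesh$tets))
  materials <- material_map(config$materials$E_adipose,
                            config$materials$E_gland, config$materials$nu)
  b <- shape$semi_posterior[2]
  plate <- plate_model(fixed_plane = -b, moving_plane = b,
                       displacement = config$compression$displacement,
                       extent_x = config$compression$plate_extent_x,
                       extent_z = config$compression$plate_extent_z,
                       penalty = config$compression$penalty)

  targets <- config$phantom$density_targets
  rows <- vector("list", length(targets))
  maps <- states <- phantoms <- vector("list", length(targets))
  names(maps) <- names(states) <- names(phantoms) <- as.character(targets)
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    say("density target %g%%: calibrating threshold", tg)
    cal <- calibrate_threshold(field, maskinfo, table, tg,
                               tol = config$phantom$calibration_tol)
    phantom <- cal$phantom
    emesh <- assign_materials(mesh, phantom, materials,
                              config$mesh$quadrature_order)
    say("  moduli %.1f-%.1f kPa; solving compression",
        min(emesh$element_modulus), max(emesh$element_modulus))
    law <- neo_hookean_law(emesh, materials)
    state <- solve_compression(emesh, law, plate,
                               n_steps = config$compression$n_steps,
                               tol = config$compression$tol,
                               verbose = verbose)
    map <- bin_patch_pressures(state, plate, which = "fixed",
                               patch = config$mi$patch)
    s <- summarize_mi(map, config$mi$contact_floor)
    rows[[ti]] <- data.frame(
      density_target = tg,
      dense_percent = cal$achieved,
      threshold = cal$threshold,
      reaction_force_N = abs(reaction_forces(state)$F_moving),
      contact_area_cm2 = s$contact_area_cm2,
      mean_stress_kPa = s$mean_stress_kPa,
      retention_adjusted_kPa = retention_adjust(s$mean_stress_kPa,
                                                config$mi$retention))
    maps[[ti]] <- map; states[[ti]] <- state; phantoms[[ti]] <- phantom
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      stem <- file.path(outdir, sprintf("density_%02d", round(tg)))
      save_phantom(phantom, paste0(stem, "_phantom.bin"))
      write_vtk(emesh, paste0(stem, "_mesh.vtk"),
                point_data = list(
                  displacement = matrix(state$u, ncol = 3, byrow = TRUE)),
                cell_data = list(E_kPa = emesh$element_modulus))
      write_mi_csv(map, paste0(stem, "_mi.csv"))
      plot_mi_map(map, paste0(stem, "_mi.png"))
      plot_phantom_projection(phantom, paste0(stem, "_phantom.png"))
      jsonlite::write_json(
        c(list(config_hash = hash, seed = config$seed,
               package_version = as.character(utils::packageVersion("mivct"))),
          as.list(rows[[ti]])),
        paste0(stem, "_summary.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  results <- do.call(rbind, rows)
  # integer presentation mirroring the reported table; full precision kept
  results$reaction_force_N_rounded <- round(results$reaction_force_N)
  results$mean_stress_kPa_rounded <- round(results$mean_stress_kPa)
  say("pipeline done in %.1f min",
      as.numeric(difftime(Sys.time(), t0, units = "mins")))
  list(results = results, maps = maps, states = states, phantoms = phantoms,
       mesh = mesh, config_hash = hash)
}
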