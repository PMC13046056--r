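#' Bin nodal plate forces into the simulated MI pressure map
#'
#' Emulates the grid pressure sensor: each contacting node's y-force is added
#' to the 1 cm x 1 cm patch containing its deformed (x, z) position on the
#' chosen plate, and each patch sum is divided by the patch area
#' (1 N/cm^2 = 10 kPa). The patch grid is anchored at the plate's minimum
#' (x, z) corner.
#'
#' @param state a `compression_state` from [solve_compression()].
#' @param plate a [plate_model()] (extent and patch origin).
#' @param which `"fixed"` (stationary, sensor side; includes the anchor-node
#'   reaction) or `"moving"`.
#' @param patch patch edge length (cm).
#' @return object of class `mi_map`: `pressures` (kPa matrix, x by z),
#'   `patch`, `origin`, `plate_side`.
#' @export
bin_patch_pressures <- function(state, plate, which = c("fixed", "moving"),
                                patch = 1) {
  which <- match.arg(which)
  mesh <- state$mesh
  n <- nrow(mesh$nodes)
  u <- state$u
  fy <- if (which == "fixed") {
    f <- state$contact$node_force_fixed
    # constraint reaction at the anchor belongs to the stationary plate
    f[mesh$node_sets$anchor_node] <- f[mesh$node_sets$anchor_node] +
      state$anchor_reaction_y
    f
  } else {
    state$contact$node_force_moving
  }
  .bin_forces(abs(fy),
              x = mesh$nodes[, 1] + u[3 * seq_len(n) - 2],
              z = mesh$nodes[, 3] + u[3 * seq_len(n)],
              plate = plate, patch = patch, side = which)
}

.bin_forces <- function(force_N, x, z, plate, patch, side = "fixed") {
  act <- force_N != 0
  if (any(act & (x < plate$extent_x[1] | x > plate$extent_x[2] |
                 z < plate$extent_z[1] | z > plate$extent_z[2])))
    stop("contacting node outside the plate extent: plate too small",
         call. = FALSE)
  nx <- ceiling(diff(plate$extent_x) / patch - 1e-9)
  nz <- ceiling(diff(plate$extent_z) / patch - 1e-9)
  press <- matrix(0, nx, nz)
  if (any(act)) {
    ix <- pmin(floor((x[act] - plate$extent_x[1]) / patch) + 1L, nx)
    iz <- pmin(floor((z[act] - plate$extent_z[1]) / patch) + 1L, nz)
    for (q in seq_along(ix))
      press[ix[q], iz[q]] <- press[ix[q], iz[q]] + force_N[act][q]
  }
  # N per patch -> kPa: divide by patch area (cm^2), x10
  press <- press / (patch * patch) * 10
  structure(list(pressures = press, patch = patch,
                 origin = c(plate$extent_x[1], plate$extent_z[1]),
                 plate_side = side),
            class = "mi_map")
}

#' Scalar MI summaries: total force, contact area, mean stress
#'
#' `total_force` is the sum of the patch forces (N); `contact_area` counts
#' patches above the contact floor (cm^2); `mean_stress` is total force over
#' contact area, converted to kPa.
#'
#' @param map an `mi_map`.
#' @param contact_floor pressure floor (kPa) for a patch to count as contact.
#' @return list `total_force_N`, `contact_area_cm2`, `mean_stress_kPa`.
#' @export
summarize_mi <- function(map, contact_floor = 0.1) {
  patch_area <- map$patch^2
  total_force <- sum(map$pressures) / 10 * patch_area     # kPa -> N cm^-2
  n_contact <- sum(map$pressures > contact_floor)
  if (n_contact == 0)
    stop("no contact patches above the floor: mean stress undefined",
         call. = FALSE)
  area <- n_contact * patch_area
  list(total_force_N = total_force, contact_area_cm2 = area,
       mean_stress_kPa = total_force / area * 10)
}

#' Chest-wall force-retention adjustment
#'
#' In vivo, only a fraction (~27% in the craniocaudal view) of the applied
#' compression force is transmitted through the central breast area — the
#' rest is absorbed by the chest wall. Scaling the simulated mean stress by
#' that retention fraction makes it comparable, in order of magnitude, to the
#' reported in-vivo average of 2.5 kPa.
#'
#' @param mean_stress simulated mean stress (kPa).
#' @param retention_fraction fraction retained, in (0, 1].
#' @return adjusted stress (kPa).
#' @export
retention_adjust <- function(mean_stress, retention_fraction = 0.27) {
  stopifnot(retention_fraction > 0, retention_fraction <= 1)
  retention_fraction * mean_stress
}

#' Write an MI map as a CSV grid (kPa)
#' @param map an `mi_map`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_mi_csv <- function(map, path) {
  utils::write.table(map$pressures, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' PNG heat map of an MI pressure map
#' @param map an `mi_map`; @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_mi_map <- function(map, path) {
  grDevices::png(path, width = 700, height = 380)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 4))
  graphics::image(seq_len(nrow(map$pressures)), seq_len(ncol(map$pressures)),
                  map$pressures,
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "", ylab = "", asp = 1,
                  main = sprintf("max %.1f kPa", max(map$pressures)))
  invisible(path)
}
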