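#' Write a tet mesh as a legacy ASCII VTK unstructured grid
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node vectors (length n) or 3-column
#'   matrices (written as VECTORS).
#' @param cell_data named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("tet mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("CELLS %d %d", m, 5L * m)
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  w("CELL_TYPES %d", m)
  writeLines(as.character(rep(10L, m)), con)
  if (length(point_data)) {
    w("POINT_DATA %d", n)
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      if (is.matrix(d) && ncol(d) == 3) {
        w("VECTORS %s double", nm)
        writeLines(paste(d[, 1], d[, 2], d[, 3]), con)
      } else {
        w("SCALARS %s double 1", nm)
        w("LOOKUP_TABLE default")
        writeLines(as.character(d), con)
      }
    }
  }
  if (length(cell_data)) {
    w("CELL_DATA %d", m)
    for (nm in names(cell_data)) {
      w("SCALARS %s double 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(as.character(cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Export geometry, materials and boundary conditions as FEBio XML
#'
#' Writes a `febio_spec` 3.0 document with the tet mesh, a neo-Hookean
#' material (per-element modulus carried as ElementData `E_kPa`), the fixed
#' back-surface / plate-band / anchor boundary conditions, two rigid-body
#' plates with a sliding contact stanza and the prescribed -y displacement —
#' a hook for cross-validating the internal solver against the reference
#' solver.
#'
#' @param mesh a `tet_mesh` with element moduli assigned.
#' @param materials a [material_map()].
#' @param plate a [plate_model()].
#' @param path output `.feb` path.
#' @return `path`, invisibly.
#' @export
export_feb <- function(mesh, materials, plate, path) {
  if (is.null(mesh$element_modulus))
    stop("mesh has no element moduli; run assign_materials()", call. = FALSE)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="ISO-8859-1"?>')
  w('<febio_spec version="3.0">')
  w('  <Module type="solid"/>')
  w('  <Material>')
  w('    <material id="1" name="tissue" type="neo-Hookean">')
  w('      <E>%.6g</E>', mean(mesh$element_modulus) * 1000)  # kPa -> Pa scale note
  w('      <v>%.4f</v>', materials$nu)
  w('    </material>')
  w('  </Material>')
  w('  <Mesh>')
  w('    <Nodes name="breast">')
  writeLines(sprintf('      <node id="%d">%.9g,%.9g,%.9g</node>',
                     seq_len(n), mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  w('    </Nodes>')
  w('    <Elements type="tet4" name="Part1">')
  writeLines(sprintf('      <elem id="%d">%d,%d,%d,%d</elem>',
                     seq_len(m), mesh$tets[, 1], mesh$tets[, 2],
                     mesh$tets[, 3], mesh$tets[, 4]), con)
  w('    </Elements>')
  for (nm in c("back_surface", "near_fixed_plate", "near_moving_plate",
               "anchor_node")) {
    w('    <NodeSet name="%s">', nm)
    writeLines(sprintf('      <n id="%d"/>', mesh$node_sets[[nm]]), con)
    w('    </NodeSet>')
  }
  w('  </Mesh>')
  w('  <MeshDomains>')
  w('    <SolidDomain name="Part1" mat="tissue"/>')
  w('  </MeshDomains>')
  w('  <MeshData>')
  w('    <ElementData name="E_kPa" elem_set="Part1">')
  writeLines(sprintf('      <e lid="%d">%.6g</e>', seq_len(m),
                     mesh$element_modulus), con)
  w('    </ElementData>')
  w('  </MeshData>')
  w('  <Boundary>')
  w('    <bc type="fix" node_set="back_surface"><dofs>z</dofs></bc>')
  w('    <bc type="fix" node_set="near_fixed_plate"><dofs>x</dofs></bc>')
  w('    <bc type="fix" node_set="near_moving_plate"><dofs>x</dofs></bc>')
  w('    <bc type="fix" node_set="anchor_node"><dofs>x,y,z</dofs></bc>')
  w('  </Boundary>')
  w('  <Rigid>')
  w('    <rigid_constraint name="fixed_plate" type="fix">')
  w('      <rb>2</rb><dofs>Rx,Ry,Rz,Ru,Rv,Rw</dofs>')
  w('    </rigid_constraint>')
  w('    <rigid_constraint name="moving_plate" type="prescribe">')
  w('      <rb>3</rb><dof>Ry</dof><value lc="1">%.6g</value>',
    -plate$displacement)
  w('    </rigid_constraint>')
  w('  </Rigid>')
  w('  <Contact>')
  w('    <contact type="facet-to-facet sliding" name="plate_contact">')
  w('      <laugon>0</laugon><penalty>%.6g</penalty>', plate$penalty)
  w('    </contact>')
  w('  </Contact>')
  w('  <LoadData>')
  w('    <load_controller id="1" type="loadcurve">')
  w('      <points><point>0,0</point><point>1,1</point></points>')
  w('    </load_controller>')
  w('  </LoadData>')
  w('</febio_spec>')
  invisible(path)
}

#' Write deformed configurations of a compression run as a VTK time series
#'
#' One `.vtk` file per stored step (requires `store_history = TRUE` in
#' [solve_compression()]), plus the final state.
#'
#' @param state a `compression_state`.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return character vector of written paths, invisibly.
#' @export
write_vtk_series <- function(state, dir, basename = "compression") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- state$mesh
  n <- nrow(mesh$nodes)
  snaps <- state$history
  if (is.null(snaps)) snaps <- list()
  snaps <- c(snaps, list(state$u))
  paths <- character(0)
  for (s in seq_along(snaps)) {
    u <- matrix(snaps[[s]], ncol = 3, byrow = TRUE)
    p <- file.path(dir, sprintf("%s_%03d.vtk", basename, s))
    write_vtk(mesh, p,
              point_data = list(displacement = u),
              cell_data = list(E_kPa = mesh$element_modulus %||% rep(0, nrow(mesh$tets))))
    paths <- c(paths, p)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
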