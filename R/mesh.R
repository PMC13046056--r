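#' Tissue material map
#'
#' Stiffness moduli for the two tissue end-members and the Poisson ratio used
#' for every element. The paper-derived defaults are 20 kPa (adipose) and
#' 80 kPa (fibroglandular); nu defaults to 0.49 (near-incompressible soft
#' tissue) and is configurable downward when element locking is a concern.
#'
#' @param E_adipose,E_gland moduli in kPa.
#' @param nu Poisson ratio in (0, 0.5).
#' @return object of class `material_map`.
#' @export
material_map <- function(E_adipose = 20, E_gland = 80, nu = 0.49) {
  stopifnot(E_adipose > 0, E_adipose <= E_gland, nu > 0, nu < 0.5)
  structure(list(E_adipose = E_adipose, E_gland = E_gland, nu = nu),
            class = "material_map")
}

#' Lame parameters from modulus and Poisson ratio
#' @param E modulus (any unit); @param nu Poisson ratio.
#' @return list `mu`, `lambda` in the unit of `E`.
#' @export
lame_parameters <- function(E, nu) {
  list(mu = E / (2 * (1 + nu)),
       lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

# Freudenthal/Kuhn 6-tet split of a hex, local corner ids in
# (x-fastest) binary order c000,c100,c010,c110,c001,c101,c011,c111 = 1..8.
# All tets share the main diagonal c000-c111, so faces of adjacent hexes are
# split along the same diagonals and the mesh is conforming.
.kuhn_tets <- matrix(c(
  1, 2, 4, 8,
  1, 4, 3, 8,
  1, 3, 7, 8,
  1, 7, 5, 8,
  1, 5, 6, 8,
  1, 6, 2, 8), ncol = 4, byrow = TRUE)

.hex_grid_tets <- function(xs, ys, zs, keep) {
  # keep: logical over hex cells, array (nx-1, ny-1, nz-1)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  idx <- which(keep, arr.ind = TRUE)
  m <- nrow(idx)
  corners <- matrix(0L, m, 8)
  for (c in 1:8) {
    di <- bitwAnd(c - 1L, 1L)
    dj <- bitwAnd(bitwShiftR(c - 1L, 1L), 1L)
    dk <- bitwAnd(bitwShiftR(c - 1L, 2L), 1L)
    corners[, c] <- nid(idx[, 1] + di, idx[, 2] + dj, idx[, 3] + dk)
  }
  tets <- matrix(0L, 6L * m, 4)
  for (t in 1:6)
    tets[seq.int(t, by = 6L, length.out = m), ] <-
      corners[, .kuhn_tets[t, ], drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  renum <- integer(nx * ny * nz)
  renum[used] <- seq_along(used)
  tets[] <- renum[tets]
  kk <- ((used - 1L) %/% (nx * ny)) + 1L
  rem <- (used - 1L) %% (nx * ny)
  jj <- (rem %/% nx) + 1L
  ii <- (rem %% nx) + 1L
  nodes <- cbind(xs[ii], ys[jj], zs[kk])
  list(nodes = nodes, tets = tets)
}

.orient_tets <- function(nodes, tets) {
  v1 <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  v2 <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  v3 <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  det6 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  flip <- det6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tets
}

.boundary_faces <- function(tets) {
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c3
  key <- paste(a, b, c3)
  cnt <- table(key)
  faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

# tributary plate areas: 1/3 of each boundary-face area projected on the
# plane normal to y, accumulated at the face's nodes
.tributary_areas <- function(nodes, faces, n_nodes) {
  e1 <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  e2 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]  # y-component of cross product
  aproj <- 0.5 * abs(ny)
  areas <- numeric(n_nodes)
  for (c in 1:3) {
    acc <- tapply(aproj, faces[, c], sum)
    areas[as.integer(names(acc))] <- areas[as.integer(names(acc))] + acc / 3
  }
  areas
}

.finish_mesh <- function(nodes, tets, plate_planes, plate_band, anchor_ref) {
  tets <- .orient_tets(nodes, tets)
  faces <- .boundary_faces(tets)
  surface <- sort(unique(as.vector(faces)))
  areas <- .tributary_areas(nodes, faces, nrow(nodes))
  tolz <- 1e-8
  back <- which(abs(nodes[, 3]) < tolz)
  near_fixed <- surface[abs(nodes[surface, 2] - plate_planes[1]) <= plate_band]
  near_moving <- surface[abs(nodes[surface, 2] - plate_planes[2]) <= plate_band]
  # anchor: node of the lowest-y layer (touching the fixed plate side),
  # closest to the reference point in (x, z); ties -> lowest index
  ymin <- min(nodes[surface, 2])
  cand <- surface[nodes[surface, 2] <= ymin + 1e-8]
  d2 <- (nodes[cand, 1] - anchor_ref[1])^2 + (nodes[cand, 3] - anchor_ref[2])^2
  anchor <- cand[which.min(d2)]
  structure(list(
    nodes = nodes, tets = tets, boundary_faces = faces,
    tributary_area = areas, element_modulus = NULL,
    node_sets = list(back_surface = back, near_fixed_plate = near_fixed,
                     near_moving_plate = near_moving, anchor_node = anchor),
    plate_planes = plate_planes), class = "tet_mesh")
}

#' Tetrahedralise a breast shape
#'
#' Structured hex grid clipped to the solid (a hex is kept when its centre is
#' inside), each hex split into 6 conforming, positively oriented tetrahedra.
#' The grid is anchored so that `z = 0` (the chest wall) is a node layer.
#' Node sets: `back_surface` (z = 0, later fixed in z), `near_fixed_plate` /
#' `near_moving_plate` (surface nodes within `plate_band` of the plate planes
#' along y, later fixed in x), and `anchor_node` (the plate-contacting node
#' closest to the shape centroid in (x, z), fixed in all directions).
#'
#' @param shape a [breast_shape()].
#' @param target_edge hex edge length (cm); 0.5 gives ~1.2e4 tets, 0.23
#'   ~1.2e5 (the full-scale mesh size).
#' @param plate_band proximity band to each plate plane (cm), default 0.8
#'   (8 mm).
#' @return object of class `tet_mesh`.
#' @export
tetrahedralize <- function(shape, target_edge = 0.5, plate_band = 0.8) {
  bb <- shape_bbox(shape)
  ns <- pmax(1L, as.integer(ceiling((bb[, 2] - bb[, 1]) / target_edge - 1e-9)))
  xs <- seq(bb[1, 1], by = target_edge, length.out = ns[1] + 1L)
  ys <- seq(bb[2, 1], by = target_edge, length.out = ns[2] + 1L)
  zs <- seq(0, by = target_edge, length.out = ns[3] + 1L)
  cx <- xs[-1] - target_edge / 2
  cy <- ys[-1] - target_edge / 2
  cz <- zs[-1] - target_edge / 2
  centres <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  keep <- array(in_shape(shape, centres), dim = ns)
  if (!any(keep)) stop("edge length too large: no hex centre inside the shape",
                       call. = FALSE)
  g <- .hex_grid_tets(xs, ys, zs, keep)
  b <- shape$semi_posterior[2]
  zc <- 3 * shape$semi_posterior[3] / 8  # centroid height of a half ellipsoid
  .finish_mesh(g$nodes, g$tets, plate_planes = c(-b, b),
               plate_band = plate_band, anchor_ref = c(0, zc))
}

#' Tetrahedral mesh of a rectangular block (for verification problems)
#'
#' Block spans `[0, dims]` with plates normal to y at `y = 0` (fixed) and
#' `y = dims[2]` (moving).
#'
#' @param dims block edge lengths (cm), length 3.
#' @param edge hex edge length (cm).
#' @param plate_band proximity band (cm).
#' @return a `tet_mesh`.
#' @export
block_mesh <- function(dims, edge, plate_band = 0.8) {
  ns <- pmax(1L, as.integer(round(dims / edge)))
  xs <- seq(0, dims[1], length.out = ns[1] + 1L)
  ys <- seq(0, dims[2], length.out = ns[2] + 1L)
  zs <- seq(0, dims[3], length.out = ns[3] + 1L)
  keep <- array(TRUE, dim = ns)
  g <- .hex_grid_tets(xs, ys, zs, keep)
  .finish_mesh(g$nodes, g$tets, plate_planes = c(0, dims[2]),
               plate_band = plate_band, anchor_ref = c(dims[1] / 2, dims[3] / 2))
}

#' Signed tet volumes of a mesh
#' @param mesh a `tet_mesh`.
#' @return numeric vector (cm^3), positive for a well-oriented mesh.
#' @export
tet_volumes <- function(mesh) {
  pre <- cpp_tet_precompute(mesh$nodes, mesh$tets)
  pre$vol
}

# equal-weight barycentric quadrature points for piecewise-constant averaging;
# order 2 is the classic 4-point rule, higher orders use the interior
# barycentric lattice (i + 1/4)/n over compositions i1+..+i4 = n - 1
.tet_quadrature <- function(order = 2L) {
  if (order <= 1L) return(matrix(0.25, 1, 4))
  if (order == 2L) {
    a <- 0.5854101966249685; b <- 0.1381966011250105
    return(rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)))
  }
  n <- order
  comp <- expand.grid(i1 = 0:(n - 1), i2 = 0:(n - 1), i3 = 0:(n - 1))
  comp <- comp[rowSums(comp) <= n - 1, , drop = FALSE]
  i4 <- (n - 1) - rowSums(comp)
  qp <- (as.matrix(cbind(comp, i4)) + 0.25) / n
  unname(qp)
}

#' Assign per-element stiffness from a voxel phantom
#'
#' For each tetrahedron the mean adipose fraction `vbar` is estimated by a
#' fixed-order quadrature rule with nearest-voxel lookup (no interpolation,
#' honouring the discrete tissue table); the element modulus is the linear
#' mixture `E = vbar * E_adipose + (1 - vbar) * E_gland`. Samples falling on
#' out-of-mask voxels take the nearest in-mask voxel; their count is recorded
#' in `attr(, "n_outside_samples")`.
#'
#' @param mesh a `tet_mesh`.
#' @param phantom a `phantom_volume` covering the mesh bounding box.
#' @param materials a [material_map()].
#' @param quadrature_order 1 = centroid, 2 = classic 4-point,
#'   n >= 3 = dense interior lattice with `choose(n+2, 3)` points. The
#'   default (5, 35 points) keeps every element modulus within 1 kPa of a
#'   much finer rule at the default grid resolutions; the integrand is
#'   piecewise constant, so dense equal-weight coverage beats low-order
#'   polynomial rules.
#' @return the mesh with `element_modulus` (kPa) and `element_vbar` filled in.
#' @export
assign_materials <- function(mesh, phantom, materials, quadrature_order = 5L) {
  dims <- dim(phantom$voxels)
  lo <- phantom$origin
  hi <- phantom$origin + dims * phantom$spacing
  bbn <- apply(mesh$nodes, 2, range)
  if (any(bbn[1, ] < lo - phantom$spacing) || any(bbn[2, ] > hi + phantom$spacing))
    stop("phantom grid does not cover the mesh bounding box", call. = FALSE)
  vox <- phantom$voxels
  vox[!phantom$mask] <- 0  # never read: masked lookups are redirected
  res <- cpp_element_mean_voxel(mesh$nodes, mesh$tets, as.numeric(vox),
                                as.logical(phantom$mask), dims,
                                as.numeric(phantom$origin), phantom$spacing,
                                .tet_quadrature(quadrature_order))
  if (isTRUE(res$unresolved))
    stop("quadrature sample could not be matched to any in-mask voxel",
         call. = FALSE)
  vbar <- res$vbar
  E <- vbar * materials$E_adipose + (1 - vbar) * materials$E_gland
  mesh$element_modulus <- E
  mesh$element_vbar <- vbar
  attr(mesh$element_modulus, "n_outside_samples") <- res$n_outside
  mesh
}
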