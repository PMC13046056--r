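# Independent scalar oracles used across the suite. These re-derive expected
# values by direct loops / closed forms and must stay independent of the
# vectorised implementation paths they check.

# scalar corner-loop Perlin oracle: quintic fade + corner dot products,
# gradients taken from the lattice (octave 0)
oracle_perlin <- function(lattice, point, octave = 0L, cell = NULL) {
  if (is.null(cell)) cell <- lattice$cell_size / 2^octave
  p <- point / cell
  i0 <- floor(p)
  d <- p - i0
  fade <- function(t) 6 * t^5 - 15 * t^4 + 10 * t^3
  val <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    g <- lattice_gradients(lattice, matrix(i0 + c(cx, cy, cz), 1), octave)
    dist <- d - c(cx, cy, cz)
    w <- (if (cx) fade(d[1]) else 1 - fade(d[1])) *
         (if (cy) fade(d[2]) else 1 - fade(d[2])) *
         (if (cz) fade(d[3]) else 1 - fade(d[3]))
    val <- val + w * sum(g * dist)
  }
  val
}

# term-wise fractal oracle: explicit octave sum with halved cells
oracle_fractal <- function(lattice, spec, point) {
  amps <- spec$persistence^(0:(spec$n_octaves - 1))
  cells <- spec$base_cell_size / 2^(0:(spec$n_octaves - 1))
  terms <- vapply(seq_len(spec$n_octaves), function(i) {
    oracle_perlin(lattice, point, octave = i - 1L, cell = cells[i])
  }, numeric(1))
  sum(amps * terms) / sum(amps)
}

# linear-elastic nodal forces of a single tet under a small displacement
# field: sigma = lambda tr(eps) I + 2 mu eps ; f_a = V sigma gradN_a
oracle_hooke_tet_forces <- function(nodes, u_mat, E, nu) {
  Dm <- t(nodes[2:4, ] - matrix(nodes[1, ], 3, 3, byrow = TRUE))
  vol <- det(Dm) / 6
  gradN <- rbind(-colSums(solve(Dm)), solve(Dm))  # rows: grad N_a
  gradu <- t(u_mat) %*% gradN  # 3x3 displacement gradient (du_i/dx_j)
  eps <- 0.5 * (gradu + t(gradu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  sigma <- lam * sum(diag(eps)) * diag(3) + 2 * mu * eps
  t(vol * sigma %*% t(gradN))  # 4x3 nodal forces
}

# closed-form uniaxial neo-Hookean: given axial stretch ly, solve the lateral
# stretch lt from zero lateral first-Piola stress, return the axial nominal
# stress P_yy (force per undeformed area)
oracle_uniaxial_nh <- function(E, nu, ly) {
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  Pxx <- function(lt) {
    J <- lt^2 * ly
    mu * (lt - 1 / lt) + lam * log(J) / lt
  }
  lt <- stats::uniroot(Pxx, c(1 + 1e-9, 5), tol = 1e-12)$root
  J <- lt^2 * ly
  list(lateral_stretch = lt,
       P_axial = mu * (ly - 1 / ly) + lam * log(J) / ly)
}

# uniform random points inside a tet via sorted-uniform barycentric sampling
oracle_points_in_tet <- function(nodes, n) {
  u <- matrix(stats::runif(3 * n), n, 3)
  u <- t(apply(u, 1, sort))
  b <- cbind(u[, 1], u[, 2] - u[, 1], u[, 3] - u[, 2], 1 - u[, 3])
  b %*% nodes
}

# nearest-voxel lookup matching the material-assignment convention
oracle_voxel_lookup <- function(pts, phantom) {
  dims <- dim(phantom$voxels)
  idx <- floor(sweep(sweep(pts, 2, phantom$origin), 2,
                     rep(phantom$spacing, 3), "/"))
  idx <- pmin(pmax(idx, 0), matrix(dims - 1L, nrow(idx), 3, byrow = TRUE))
  phantom$voxels[idx + 1]
}

# build a constant-valued phantom_volume over a mask (synthetic fixture)
make_uniform_phantom <- function(maskinfo, value) {
  voxels <- array(NA_real_, dim = dim(maskinfo$mask))
  voxels[maskinfo$mask] <- value
  structure(list(voxels = voxels, mask = maskinfo$mask,
                 spacing = maskinfo$spacing, origin = maskinfo$origin,
                 threshold_used = NA_real_,
                 dense_fraction = 100 * (1 - value)),
            class = "phantom_volume")
}

# minimal compression_state carrying fabricated nodal plate forces, for
# exercising the MI binning in isolation
make_fake_state <- function(nodes, force_fixed, u = NULL) {
  n <- nrow(nodes)
  if (is.null(u)) u <- numeric(3 * n)
  mesh <- list(nodes = nodes, node_sets = list(anchor_node = integer(0)))
  structure(list(u = u, mesh = mesh,
                 contact = list(node_force_fixed = force_fixed,
                                node_force_moving = -force_fixed),
                 anchor_reaction_y = 0),
            class = "compression_state")
}

# desk-profile pipeline run shared by the acceptance tests (computed once)
.desk_cache <- new.env(parent = emptyenv())
get_desk_run <- function() {
  if (is.null(.desk_cache$run)) {
    cfg <- default_config("desk", seed = 42)
    .desk_cache$run <- run_pipeline(cfg)
  }
  .desk_cache$run
}
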