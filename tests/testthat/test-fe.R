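test_that("the reference configuration is stress-free", {
  mesh <- block_mesh(c(2, 1, 1), 0.5)
  law <- neo_hookean_law(mesh, material_map(), E_uniform = 20)
  res <- internal_forces(mesh, law, numeric(3 * nrow(mesh$nodes)))
  expect_identical(res$f, numeric(3 * nrow(mesh$nodes)))
  expect_equal(res$energy, 0)
  expect_equal(res$minJ, 1)
})

test_that("small-strain tet forces match linear elasticity", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- list(nodes = nodes, tets = matrix(1:4, 1))
  E <- 30; nu <- 0.3
  law <- neo_hookean_law(mesh, material_map(nu = nu), E_uniform = E)
  eps <- 1e-3  # 0.1% uniaxial strain along y
  u_mat <- cbind(0, eps * nodes[, 2], 0)
  u <- as.vector(t(u_mat))
  got <- matrix(internal_forces(mesh, law, u, want_K = FALSE)$f,
                ncol = 3, byrow = TRUE)
  want <- oracle_hooke_tet_forces(nodes, u_mat, E * 0.1, nu)  # kPa -> N/cm^2
  expect_equal(got, want, tolerance = 0.01)
})

test_that("the tangent is the exact derivative of the internal forces", {
  mesh <- block_mesh(c(1, 1, 1), 0.5)
  n <- nrow(mesh$nodes)
  law <- neo_hookean_law(mesh, material_map(nu = 0.45), E_uniform = 25)
  set.seed(30)
  u <- stats::rnorm(3 * n, sd = 5e-3)
  v <- stats::rnorm(3 * n); v <- v / sqrt(sum(v^2))
  K <- internal_forces(mesh, law, u)$K
  h <- 1e-6
  fp <- internal_forces(mesh, law, u + h * v, want_K = FALSE)$f
  fm <- internal_forces(mesh, law, u - h * v, want_K = FALSE)$f
  fd <- (fp - fm) / (2 * h)
  Kv <- as.numeric(K %*% v)
  expect_lt(sqrt(sum((Kv - fd)^2)) / sqrt(sum(fd^2)), 1e-6)
})

test_that("penalty contact forces follow their definition", {
  mesh <- block_mesh(c(2, 2, 2), 1)
  plate <- plate_model(fixed_plane = 0, moving_plane = 2, displacement = 1,
                       penalty = 500)
  n <- nrow(mesh$nodes)
  # undeformed, plates at the faces: no penetration anywhere
  fc0 <- contact_forces(mesh, plate, numeric(3 * n))
  expect_identical(unname(fc0$f), numeric(3 * n))
  expect_equal(fc0$F_fixed, 0)
  # push one top-surface node 0.01 cm beyond the moving plate
  top <- which(mesh$nodes[, 2] == 2 & mesh$tributary_area > 0)[1]
  u <- numeric(3 * n)
  u[3 * top - 1] <- 0.01
  fc <- contact_forces(mesh, plate, u)
  a <- mesh$tributary_area[top]
  expect_equal(fc$f[3 * top - 1], -500 * 0.01 * a)
  expect_equal(sum(fc$f != 0), 1L)
  expect_equal(fc$F_moving, -500 * 0.01 * a)
})

test_that("uniaxial block compression matches the closed-form solution", {
  dims <- c(4, 3, 4)
  mesh <- block_mesh(dims, 0.5, plate_band = 0.01)
  # symmetry-style constraints for a homogeneous state: x fixed on x = 0,
  # z fixed on z = 0, anchor at the origin
  mesh$node_sets$back_surface <- which(abs(mesh$nodes[, 3]) < 1e-9)
  mesh$node_sets$near_fixed_plate <- which(abs(mesh$nodes[, 1]) < 1e-9)
  mesh$node_sets$near_moving_plate <- integer(0)
  mesh$node_sets$anchor_node <-
    which(rowSums(abs(mesh$nodes)) < 1e-9)
  E <- 20; nu <- 0.49
  law <- neo_hookean_law(mesh, material_map(nu = nu), E_uniform = E)
  plate <- plate_model(fixed_plane = 0, moving_plane = dims[2],
                       displacement = 0.3 * dims[2],
                       extent_x = c(-1, 20), extent_z = c(-1, 20),
                       penalty = 4000)
  st <- solve_compression(mesh, law, plate, n_steps = 10)
  F_num <- abs(reaction_forces(st)$F_moving)
  oracle <- oracle_uniaxial_nh(E * 0.1, nu, 0.7)  # N/cm^2 units
  F_ref <- abs(oracle$P_axial) * dims[1] * dims[3]
  expect_equal(F_num, F_ref, tolerance = 0.03)
  # moving and fixed plate y-forces balance
  rf <- reaction_forces(st)
  expect_lt(abs(rf$F_moving + rf$F_fixed), 0.005 * abs(rf$F_moving))
  # strain energy grows monotonically along the monotone ramp
  expect_true(all(diff(st$steps$energy) > 0))
})

test_that("doubling the contact penalty barely changes the reaction", {
  dims <- c(2, 2, 2)
  mesh <- block_mesh(dims, 0.5, plate_band = 0.01)
  mesh$node_sets$back_surface <- which(abs(mesh$nodes[, 3]) < 1e-9)
  mesh$node_sets$near_fixed_plate <- which(abs(mesh$nodes[, 1]) < 1e-9)
  mesh$node_sets$near_moving_plate <- integer(0)
  mesh$node_sets$anchor_node <- which(rowSums(abs(mesh$nodes)) < 1e-9)
  law <- neo_hookean_law(mesh, material_map(), E_uniform = 20)
  run <- function(k) {
    plate <- plate_model(fixed_plane = 0, moving_plane = 2, displacement = 0.5,
                         extent_x = c(-1, 10), extent_z = c(-1, 10),
                         penalty = k)
    abs(reaction_forces(solve_compression(mesh, law, plate,
                                          n_steps = 5))$F_moving)
  }
  F1 <- run(2000); F2 <- run(4000)
  expect_lt(abs(F2 - F1) / F1, 0.01)
})

test_that("reaction force is stable under mesh refinement", {
  # homogeneous phantom at the default resolution vs a mesh with twice the
  # elements: total reaction within 10%
  shape <- breast_shape()
  mats <- material_map()
  run <- function(edge) {
    mesh <- tetrahedralize(shape, edge)
    law <- neo_hookean_law(mesh, mats, E_uniform = 25)
    st <- solve_compression(mesh, law, plate_model(), n_steps = 15)
    abs(reaction_forces(st)$F_moving)
  }
  F_default <- run(0.5)
  F_fine <- run(0.4)
  expect_lt(abs(F_default - F_fine) / F_fine, 0.10)
})

test_that("zero prescribed displacement returns the identity solution", {
  mesh <- block_mesh(c(2, 2, 2), 1)
  law <- neo_hookean_law(mesh, material_map(), E_uniform = 20)
  plate <- plate_model(fixed_plane = 0, moving_plane = 2, displacement = 0,
                       extent_x = c(-1, 10), extent_z = c(-1, 10))
  st <- solve_compression(mesh, law, plate, n_steps = 2)
  expect_identical(st$u, numeric(3 * nrow(mesh$nodes)))
  expect_equal(abs(reaction_forces(st)$F_moving), 0)
})
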