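test_that("a single hex splits into 6 tets conserving volume exactly", {
  mesh <- block_mesh(c(1, 1, 1), 1)
  expect_equal(nrow(mesh$tets), 6L)
  vols <- tet_volumes(mesh)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 1, tolerance = 1e-14)
})

test_that("hex-split meshes are conforming and positively oriented", {
  shape <- breast_shape()
  mesh <- tetrahedralize(shape, 1.2)
  expect_true(all(tet_volumes(mesh) > 0))
  # outward-oriented faces of each positively oriented tet
  faces <- rbind(mesh$tets[, c(1, 3, 2)], mesh$tets[, c(1, 2, 4)],
                 mesh$tets[, c(1, 4, 3)], mesh$tets[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  counts <- table(key)
  expect_true(all(counts %in% c(1L, 2L)))
  # shared faces appear with opposite orientation: orientation parity of the
  # vertex permutation differs between the two occurrences
  dup <- names(counts)[counts == 2L]
  parity <- function(f) {
    o <- order(f)
    s <- 0L
    for (i in 1:2) for (j in (i + 1):3) if (o[i] > o[j]) s <- s + 1L
    s %% 2L
  }
  sel <- key %in% dup[seq_len(min(200, length(dup)))]
  par_by_key <- tapply(apply(faces[sel, , drop = FALSE], 1, parity), key[sel],
                       function(p) length(unique(p)))
  expect_true(all(par_by_key == 2L))
})

test_that("mesh volume converges to the analytic shape volume", {
  shape <- breast_shape()
  mesh <- tetrahedralize(shape, 0.5)
  expect_equal(sum(tet_volumes(mesh)), shape_volume(shape), tolerance = 0.03)
})

test_that("full-scale meshing lands at the order of 1e5 elements", {
  shape <- breast_shape()
  mesh <- tetrahedralize(shape, 0.23)
  expect_gt(nrow(mesh$tets), 4e4)
  expect_lt(nrow(mesh$tets), 4e5)
})

test_that("node sets capture back surface, plate bands and anchor", {
  shape <- breast_shape()
  mesh <- tetrahedralize(shape, 0.5)
  ns <- mesh$node_sets
  expect_true(all(abs(mesh$nodes[ns$back_surface, 3]) < 1e-8))
  expect_true(all(mesh$nodes[ns$near_fixed_plate, 2] <= -3.75 + 0.8 + 1e-9))
  expect_true(all(mesh$nodes[ns$near_moving_plate, 2] >= 3.75 - 0.8 - 1e-9))
  expect_length(ns$anchor_node, 1L)
  expect_equal(mesh$nodes[ns$anchor_node, 2], min(mesh$nodes[, 2]))
  # empty mesh when the edge is absurdly large
  expect_error(tetrahedralize(shape, 30), "no hex centre")
})

test_that("uniform phantoms map to the end-member and mixture moduli", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.4)
  mesh <- tetrahedralize(shape, 0.8)
  mats <- material_map()
  m1 <- assign_materials(mesh, make_uniform_phantom(mi, 1), mats)
  expect_true(all(abs(m1$element_modulus - 20) < 1e-12))
  # 40% adipose / 60% gland mixture: 0.4*20 + 0.6*80 = 56 kPa
  m2 <- assign_materials(mesh, make_uniform_phantom(mi, 0.40), mats)
  expect_true(all(abs(m2$element_modulus - 56) < 1e-12))
})

test_that("element modulus matches brute-force integration on a split field", {
  # single tet across a two-valued voxel field
  nodes <- rbind(c(0.1, 0.1, 0.1), c(3.9, 0.2, 0.15),
                 c(0.2, 3.9, 0.1), c(0.15, 0.2, 3.9))
  mesh <- list(nodes = nodes, tets = matrix(1:4, 1))
  dims <- c(8L, 8L, 8L)  # spacing 0.5 over [0,4]^3
  vox <- array(1, dim = dims)
  vox[1:4, , ] <- 0.40  # x < 2: dense mixture
  phantom <- structure(list(voxels = vox, mask = array(TRUE, dims),
                            spacing = 0.5, origin = c(0, 0, 0)),
                       class = "phantom_volume")
  mats <- material_map()
  got <- as.numeric(assign_materials(mesh, phantom, mats,
                                     quadrature_order = 18)$element_modulus)
  set.seed(20)
  pts <- oracle_points_in_tet(nodes, 4e4)
  vbar_mc <- mean(oracle_voxel_lookup(pts, phantom))
  want <- vbar_mc * 20 + (1 - vbar_mc) * 80
  expect_equal(got, want, tolerance = 0.02)
})

test_that("quadrature refinement leaves moduli essentially unchanged", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.3)
  lat <- perlin_lattice(42, 2.5)
  sp <- octave_spec(4, 0.5, 2.5)
  field <- sample_field(lat, sp, mi$dims, 0.3, mi$origin)
  ph <- calibrate_threshold(field, mi, tissue_table(), 43)$phantom
  mesh <- tetrahedralize(shape, 0.5)
  mats <- material_map()
  e5 <- assign_materials(mesh, ph, mats, quadrature_order = 5)$element_modulus
  e16 <- assign_materials(mesh, ph, mats, quadrature_order = 16)$element_modulus
  expect_lt(max(abs(e5 - e16)), 1)
})

test_that("denser phantoms yield element-wise stiffer meshes", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.4)
  lat <- perlin_lattice(42, 2.5)
  sp <- octave_spec(4, 0.5, 2.5)
  field <- sample_field(lat, sp, mi$dims, 0.4, mi$origin)
  tab <- tissue_table()
  mesh <- tetrahedralize(shape, 0.8)
  mats <- material_map()
  series <- aging_series(field, mi, tab, c(9, 43, 56))
  E <- sapply(series, function(p)
    assign_materials(mesh, p, mats)$element_modulus)
  expect_true(all(E[, 2] >= E[, 1] - 1e-12))
  expect_true(all(E[, 3] >= E[, 2] - 1e-12))
  expect_true(all(E >= 20 - 1e-12 & E <= 80 + 1e-12))
})
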