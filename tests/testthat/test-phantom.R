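test_that("default breast shape spans 17 x 7.5 x 3.7 cm", {
  shape <- breast_shape()
  bb <- shape_bbox(shape)
  expect_equal(unname(bb[, 2] - bb[, 1]), c(17, 7.5, 3.7), tolerance = 1e-9)
  expect_error(breast_shape(c(8.5, 3.75, 3.7), c(8.5, 3, 3.7)), "semi-axes")
})

test_that("equal quarters give a reflection-symmetric membership test", {
  shape <- breast_shape()
  set.seed(10)
  pts <- cbind(stats::runif(500, -9, 9), stats::runif(500, -4, 4),
               stats::runif(500, 0, 4))
  expect_identical(in_shape(shape, pts),
                   in_shape(shape, pts * matrix(c(-1, 1, 1), 500, 3, TRUE)))
  expect_identical(in_shape(shape, pts),
                   in_shape(shape, pts * matrix(c(1, -1, 1), 500, 3, TRUE)))
  expect_false(any(in_shape(shape, cbind(pts[, 1:2], -abs(pts[, 3]) - 0.01))))
})

test_that("Monte-Carlo volume matches the analytic quarter-ellipsoid sum", {
  shape <- breast_shape(c(9, 3.75, 3.7), c(8, 3.75, 3.7))
  bb <- shape_bbox(shape)
  set.seed(11)
  n <- 2e5
  pts <- cbind(stats::runif(n, bb[1, 1], bb[1, 2]),
               stats::runif(n, bb[2, 1], bb[2, 2]),
               stats::runif(n, bb[3, 1], bb[3, 2]))
  vol_box <- prod(bb[, 2] - bb[, 1])
  mc <- mean(in_shape(shape, pts)) * vol_box
  expect_equal(mc, shape_volume(shape), tolerance = 0.01)
})

test_that("voxel mask volume approximates the analytic volume", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.1)
  expect_equal(sum(mi$mask) * 0.1^3, shape_volume(shape), tolerance = 0.02)
})

test_that("tissue table is validated", {
  expect_silent(tissue_table())
  expect_error(tissue_table(c(1, 0.5, 0.45)), "0.40")
  expect_error(tissue_table(c(1, 0.5, 0.5, 0.40)), "decreasing")
})

test_that("thresholding handles degenerate cases", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.5)
  tab <- tissue_table()
  field <- array(0.2, dim = mi$dims)
  # threshold above the maximum: all adipose, warning not error
  expect_warning(ph <- apply_threshold(field, mi, tab, 1), "all-adipose")
  expect_equal(ph$dense_fraction, 0)
  expect_true(all(ph$voxels[mi$mask] == 1))
  expect_true(all(is.na(ph$voxels[!mi$mask])))
  # -Inf threshold on a constant field: everything snaps to the densest level
  ph2 <- apply_threshold(field, mi, tab, -Inf)
  expect_true(all(ph2$voxels[mi$mask] == 0.40))
  expect_equal(ph2$dense_fraction, 60)
})

test_that("dense fraction matches a per-voxel loop recomputation", {
  mi <- list(mask = array(TRUE, c(16, 16, 16)), dims = c(16L, 16L, 16L),
             origin = c(0, 0, 0), spacing = 0.1)
  set.seed(12)
  field <- array(stats::rnorm(16^3), c(16, 16, 16))
  tab <- tissue_table()
  thr <- stats::median(field)
  ph <- apply_threshold(field, mi, tab, thr)
  # independent loop: rescale then snap to nearest level by direct search
  lv <- as.numeric(tab)
  fmax <- max(field)
  vals <- numeric(length(field))
  for (i in seq_along(field)) {
    f <- field[i]
    if (f < thr) vals[i] <- 1 else {
      target <- 1 - 0.6 * (f - thr) / (fmax - thr)
      vals[i] <- lv[which.min(abs(lv - target))]
    }
  }
  expect_equal(as.vector(ph$voxels), vals)
  expect_equal(ph$dense_fraction, 100 * mean(1 - vals))
  expect_equal(dense_fraction(ph), ph$dense_fraction, tolerance = 1e-9)
})

test_that("dense fraction is monotone non-increasing in the threshold", {
  mi <- list(mask = array(TRUE, c(12, 12, 12)), dims = c(12L, 12L, 12L),
             origin = c(0, 0, 0), spacing = 0.1)
  set.seed(13)
  field <- array(stats::rnorm(12^3), c(12, 12, 12))
  tab <- tissue_table()
  thrs <- seq(min(field) - 3, max(field), length.out = 50)
  dens <- vapply(thrs, function(t)
    apply_threshold(field, mi, tab, t)$dense_fraction, numeric(1))
  expect_true(all(diff(dens) <= 1e-12))
})

test_that("threshold calibration reaches its target and refines stably", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.4)
  lat <- perlin_lattice(42, 2.5)
  sp <- octave_spec(4, 0.5, 2.5)
  field <- sample_field(lat, sp, mi$dims, 0.4, mi$origin)
  tab <- tissue_table()
  cal <- calibrate_threshold(field, mi, tab, 9)
  expect_lte(abs(cal$achieved - 9), 0.25)
  expect_equal(cal$achieved, cal$phantom$dense_fraction)
  # target 0: all-adipose phantom
  cal0 <- calibrate_threshold(field, mi, tab, 0)
  expect_equal(cal0$achieved, 0)
  # unreachable target
  expect_error(calibrate_threshold(field, mi, tab, 70), "dense percentage")
  # re-measuring on a 2x finer resampling of the same continuous field
  mi2 <- shape_mask(shape, 0.2)
  field2 <- sample_field(lat, sp, mi2$dims, 0.2, mi2$origin)
  ph2 <- apply_threshold(field2, mi2, tab, cal$threshold)
  expect_lt(abs(ph2$dense_fraction - cal$achieved), 1)
})

test_that("the aging series shares anatomy and nests in glandularity", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.4)
  lat <- perlin_lattice(42, 2.5)
  sp <- octave_spec(4, 0.5, 2.5)
  field <- sample_field(lat, sp, mi$dims, 0.4, mi$origin)
  tab <- tissue_table()
  targets <- c(9, 27, 43, 53, 56)
  series <- aging_series(field, mi, tab, targets)
  achieved <- vapply(series, dense_fraction, numeric(1))
  expect_true(all(abs(achieved - targets) <= 0.25))
  thrs <- vapply(series, function(p) p$threshold_used, numeric(1))
  expect_true(all(diff(thrs) < 0))  # denser <- lower threshold
  # nesting: voxel values only decrease (more glandular) as the target rises
  for (i in seq_len(length(series) - 1)) {
    lo <- series[[i]]$voxels[mi$mask]
    hi <- series[[i + 1]]$voxels[mi$mask]
    expect_true(all(hi <= lo + 1e-12))
  }
  # identical targets give identical phantoms
  twice <- aging_series(field, mi, tab, c(27, 27))
  expect_identical(twice[[1]]$voxels, twice[[2]]$voxels)
})

test_that("phantom save/load round-trips", {
  shape <- breast_shape()
  mi <- shape_mask(shape, 0.5)
  ph <- make_uniform_phantom(mi, 0.85)
  path <- tempfile(fileext = ".bin")
  save_phantom(ph, path)
  ph2 <- load_phantom(path)
  expect_equal(ph2$voxels, ph$voxels)
  expect_equal(ph2$dense_fraction, ph$dense_fraction)
  expect_equal(ph2$spacing, ph$spacing)
  unlink(c(path, paste0(path, ".json")))
})
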