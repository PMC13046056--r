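#' Seeded 3D Perlin gradient-noise lattice
#'
#' A lattice of pseudo-random unit gradient vectors at integer multiples of
#' `cell_size`. Gradients are a pure function of `(seed, lattice coordinates)`
#' via a counter-based hash: the same seed and cell size always regenerate
#' identical gradients, independently of evaluation order. Gradient directions
#' are drawn uniformly on the unit sphere by rejection sampling from the unit
#' cube followed by normalisation.
#'
#' @param seed integer seed (< 2^31).
#' @param cell_size distance (cm) between lattice intersection points.
#' @param extent numeric length-2, lower/upper bound (cm) of the lattice's
#'   defined extent on every axis; evaluating outside is an error.
#' @return an object of class `perlin_lattice`.
#' @export
perlin_lattice <- function(seed = 42L, cell_size = 2.5, extent = c(-1000, 1000)) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed),
            abs(seed) < 2^31, cell_size > 0,
            length(extent) == 2L, extent[1] < extent[2])
  structure(list(seed = as.integer(seed), cell_size = cell_size,
                 extent = as.numeric(extent)),
            class = "perlin_lattice")
}

#' Octave composition for fractal noise
#'
#' Octave `i` (0-based) uses cell size `base_cell_size / 2^i` and amplitude
#' `persistence^i`; the octave sum is normalised by the total amplitude so the
#' output range is independent of the octave count.
#'
#' @param n_octaves number of superimposed octaves (>= 1).
#' @param persistence amplitude ratio per octave, in (0, 1].
#' @param base_cell_size cell size (cm) of the base octave.
#' @return an object of class `octave_spec`.
#' @export
octave_spec <- function(n_octaves = 4L, persistence = 0.5, base_cell_size = 2.5) {
  stopifnot(n_octaves >= 1, n_octaves == round(n_octaves),
            persistence > 0, persistence <= 1, base_cell_size > 0)
  structure(list(n_octaves = as.integer(n_octaves), persistence = persistence,
                 base_cell_size = base_cell_size),
            class = "octave_spec")
}

#' Gradient vectors at lattice points
#'
#' Mainly for verification: returns the stored unit gradients at integer
#' lattice coordinates for a given octave (0 = base).
#'
#' @param lattice a [perlin_lattice()].
#' @param ijk integer matrix (n x 3) of lattice coordinates.
#' @param octave 0-based octave index.
#' @return n x 3 matrix of unit vectors.
#' @export
lattice_gradients <- function(lattice, ijk, octave = 0L) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  cpp_perlin_gradients(lattice$seed, ijk, as.integer(octave))
}

.check_extent <- function(lattice, pts) {
  if (any(pts < lattice$extent[1]) || any(pts > lattice$extent[2]))
    stop("point outside the lattice extent [", lattice$extent[1], ", ",
         lattice$extent[2], "] cm", call. = FALSE)
}

#' Single-octave Perlin noise value
#'
#' Smoothly interpolated dot-product noise: for the eight lattice corners
#' enclosing the point, the dot product of the corner gradient with the
#' distance vector to the point is blended with the quintic fade
#' \eqn{6t^5 - 15t^4 + 10t^3}. Exactly zero at lattice intersection points.
#'
#' @inheritParams lattice_gradients
#' @param point numeric length-3 (cm), or an n x 3 matrix of points.
#' @return scalar in \[-1, 1\] (or vector of length n).
#' @export
noise_value <- function(lattice, point) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  .check_extent(lattice, pts)
  v <- cpp_perlin_noise(lattice$seed, lattice$cell_size, pts, 0L)
  if (is.matrix(point)) v else v[1]
}

#' Multi-octave (fractal) Perlin noise
#'
#' Normalised sum over octaves: \eqn{\sum_i p^i n_i(x) / \sum_i p^i}, where
#' octave i halves the base cell size i times.
#'
#' @inheritParams noise_value
#' @param spec an [octave_spec()].
#' @return scalar (or vector) in \[-1, 1\].
#' @export
fractal_noise <- function(lattice, spec, point) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  .check_extent(lattice, pts)
  v <- cpp_fractal_noise(lattice$seed, spec$base_cell_size, spec$n_octaves,
                         spec$persistence, pts)
  if (is.matrix(point)) v else v[1]
}

#' Sample a fractal noise field on a voxel grid
#'
#' Evaluates [fractal_noise()] at every voxel centre
#' `origin + (index - 0.5) * spacing`.
#'
#' @inheritParams fractal_noise
#' @param grid_shape integer length-3 voxel counts.
#' @param grid_spacing voxel edge length (cm).
#' @param origin grid corner (cm), default the origin.
#' @return 3D numeric array with attributes `spacing` and `origin`.
#' @export
sample_field <- function(lattice, spec, grid_shape, grid_spacing,
                         origin = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L), grid_spacing > 0)
  lo <- origin + 0.5 * grid_spacing
  hi <- origin + (grid_shape - 0.5) * grid_spacing
  .check_extent(lattice, rbind(lo, hi))
  arr <- cpp_sample_field(lattice$seed, spec$base_cell_size, spec$n_octaves,
                          spec$persistence, grid_shape, grid_spacing,
                          as.numeric(origin))
  attr(arr, "spacing") <- grid_spacing
  attr(arr, "origin") <- as.numeric(origin)
  arr
}

#' Save / load a sampled field as a raw array with JSON sidecar
#'
#' The array is written as flat little-endian float64 (`.bin`); grid and
#' generator metadata go to `<path>.json`.
#'
#' @param field array from [sample_field()].
#' @param path file path for the binary payload.
#' @param meta named list of metadata to record (seed, octaves, ...).
#' @return `path`, invisibly.
#' @export
save_field <- function(field, path, meta = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(field), con, size = 8, endian = "little")
  meta$dim <- dim(field)
  meta$spacing <- attr(field, "spacing")
  meta$origin <- attr(field, "origin")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_field
#' @export
load_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  arr <- array(readBin(con, "double", n = n, size = 8, endian = "little"),
               dim = meta$dim)
  attr(arr, "spacing") <- meta$spacing
  attr(arr, "origin") <- meta$origin
  attr(arr, "meta") <- meta
  arr
}
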