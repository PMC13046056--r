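#' Breast-shaped solid from two ellipsoid quarters
#'
#' The solid is the union of two quarter ellipsoids joined at the `x = 0`
#' plane (craniocaudal axis), clipped to `z >= 0` (the chest wall). With the
#' default semi-axes the bounding box spans 17 cm (x) by 7.5 cm (y, the
#' compression direction) by 3.7 cm (z), roughly a cup size A.
#'
#' @param semi_posterior,semi_anterior numeric length-3 semi-axes (cm) of the
#'   x < 0 and x >= 0 quarters. The y and z semi-axes must agree so the two
#'   quarters meet smoothly on the join plane.
#' @return object of class `breast_shape`.
#' @export
breast_shape <- function(semi_posterior = c(8.5, 3.75, 3.7),
                         semi_anterior = c(8.5, 3.75, 3.7)) {
  stopifnot(length(semi_posterior) == 3L, length(semi_anterior) == 3L,
            all(semi_posterior > 0), all(semi_anterior > 0))
  if (any(abs(semi_posterior[2:3] - semi_anterior[2:3]) > 1e-9))
    stop("the two quarters must share y and z semi-axes on the join plane",
         call. = FALSE)
  structure(list(semi_posterior = as.numeric(semi_posterior),
                 semi_anterior = as.numeric(semi_anterior)),
            class = "breast_shape")
}

#' Bounding box of a breast shape
#' @param shape a [breast_shape()].
#' @return 3 x 2 matrix of lower/upper bounds (cm).
#' @export
shape_bbox <- function(shape) {
  a1 <- shape$semi_posterior; a2 <- shape$semi_anterior
  rbind(x = c(-a1[1], a2[1]), y = c(-a1[2], a1[2]), z = c(0, a1[3]))
}

#' Membership test for a breast shape
#' @param shape a [breast_shape()].
#' @param pts n x 3 matrix of points (cm).
#' @return logical vector, TRUE for points inside the solid.
#' @export
in_shape <- function(shape, pts) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = 3)
  a <- ifelse(pts[, 1] < 0, shape$semi_posterior[1], shape$semi_anterior[1])
  b <- shape$semi_posterior[2]; cc <- shape$semi_posterior[3]
  (pts[, 3] >= 0) &
    ((pts[, 1] / a)^2 + (pts[, 2] / b)^2 + (pts[, 3] / cc)^2 <= 1)
}

#' Analytic volume of a breast shape
#'
#' Sum of the two quarter-ellipsoid volumes (each an upper half in z, one half
#' in x): \eqn{\pi a b c / 3} per quarter.
#' @param shape a [breast_shape()].
#' @return volume in cm^3.
#' @export
shape_volume <- function(shape) {
  q <- function(s) pi * s[1] * s[2] * s[3] / 3
  q(shape$semi_posterior) + q(shape$semi_anterior)
}

#' Voxelise a breast shape
#'
#' Builds the boolean in-breast mask on a regular grid covering the bounding
#' box, with voxel centres at `origin + (index - 0.5) * spacing`.
#'
#' @param shape a [breast_shape()].
#' @param spacing voxel edge length (cm); 0.1 for the full-resolution phantom,
#'   0.3 for the scaled-down profile.
#' @return list with `mask` (3D logical), `dims`, `origin`, `spacing`.
#' @export
shape_mask <- function(shape, spacing = 0.1) {
  bb <- shape_bbox(shape)
  dims <- as.integer(ceiling((bb[, 2] - bb[, 1]) / spacing - 1e-9))
  origin <- as.numeric(bb[, 1])
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing
  pts <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  mask <- array(in_shape(shape, pts), dim = dims)
  list(mask = mask, dims = dims, origin = origin, spacing = spacing)
}

#' Discrete adipose-fraction table
#'
#' Ordered voxel values from 1.00 (100% adipose) down to 0.40 (40% adipose /
#' 60% fibroglandular), the mixture semantics of the anatomical model.
#'
#' @param levels strictly decreasing values, first 1.00, last 0.40.
#' @return numeric vector of class `tissue_table`.
#' @export
tissue_table <- function(levels = seq(1, 0.40, by = -0.05)) {
  levels <- as.numeric(levels)
  if (abs(levels[1] - 1) > 1e-12 || abs(levels[length(levels)] - 0.40) > 1e-12)
    stop("tissue table must run from 1.00 down to 0.40", call. = FALSE)
  if (any(diff(levels) >= 0))
    stop("tissue table values must be strictly decreasing", call. = FALSE)
  structure(levels, class = "tissue_table")
}

.snap_levels <- function(v, table) {
  lv <- sort(as.numeric(table))  # ascending for findInterval
  mids <- (lv[-1] + lv[-length(lv)]) / 2
  lv[findInterval(v, mids) + 1L]
}

#' Threshold a noise field into a tissue phantom
#'
#' In-mask voxels with field value below `threshold` become pure adipose
#' (1.00). Voxels at or above it are linearly rescaled from
#' `[threshold, max(field)]` onto `[1.00, 0.40]` and snapped to the nearest
#' tissue-table level, preserving the graded glandular structure. The dense
#' fraction is the volume-weighted mean fibroglandular fraction,
#' `100 * mean(1 - value)` over in-mask voxels.
#'
#' @param field 3D noise array (from [sample_field()]).
#' @param maskinfo list from [shape_mask()] (congruent with `field`).
#' @param table a [tissue_table()].
#' @param threshold scalar threshold on the noise values; `-Inf` maps every
#'   voxel to the densest level.
#' @return object of class `phantom_volume`: `voxels` (NA outside the mask),
#'   `mask`, `spacing`, `origin`, `threshold_used`, `dense_fraction` (%).
#' @export
apply_threshold <- function(field, maskinfo, table, threshold) {
  mask <- maskinfo$mask
  stopifnot(identical(dim(field), dim(mask)))
  f <- field[mask]
  fmax <- max(f)
  v <- rep(1, length(f))
  if (threshold > fmax) {
    warning("threshold above the field maximum: all-adipose phantom")
  } else {
    above <- f >= threshold
    denom <- fmax - threshold
    ratio <- if (!is.finite(threshold) || denom < .Machine$double.eps) {
      rep(1, sum(above))
    } else {
      (f[above] - threshold) / denom
    }
    v[above] <- .snap_levels(1 - 0.6 * ratio, table)
  }
  voxels <- array(NA_real_, dim = dim(mask))
  voxels[mask] <- v
  structure(list(voxels = voxels, mask = mask, spacing = maskinfo$spacing,
                 origin = maskinfo$origin, threshold_used = threshold,
                 dense_fraction = 100 * mean(1 - v)),
            class = "phantom_volume")
}

#' Recompute the dense-tissue percentage of a phantom
#' @param phantom a `phantom_volume`.
#' @return volume-weighted percent fibroglandular tissue.
#' @export
dense_fraction <- function(phantom) {
  100 * mean(1 - phantom$voxels[phantom$mask])
}

#' Calibrate the threshold to a target dense-tissue percentage
#'
#' Bisection on the threshold: the dense fraction is monotonically
#' non-increasing in the threshold, so the bracket
#' `[min(field) - large, max(field) + eps]` always contains the target.
#' Converges when the achieved percentage is within `tol` points of the
#' target.
#'
#' @inheritParams apply_threshold
#' @param target_dense_percent target percent fibroglandular tissue; must be
#'   below the table's maximum (60% for the default table).
#' @param tol convergence tolerance in percentage points.
#' @param max_iter bisection iteration cap.
#' @return list `threshold`, `phantom`, `achieved`, `iterations`.
#' @export
calibrate_threshold <- function(field, maskinfo, table, target_dense_percent,
                                tol = 0.25, max_iter = 60L) {
  max_dense <- 100 * (1 - min(as.numeric(table)))
  if (target_dense_percent < 0 || target_dense_percent >= max_dense)
    stop("target dense percentage must lie in [0, ", max_dense,
         ") for this tissue table", call. = FALSE)
  f <- field[maskinfo$mask]
  fmin <- min(f); fmax <- max(f); rng <- max(fmax - fmin, 1e-12)
  lo <- fmin - 1e6 * rng   # dense -> max_dense
  hi <- fmax + 1e-9 * rng  # dense -> 0
  if (target_dense_percent == 0) {
    ph <- suppressWarnings(apply_threshold(field, maskinfo, table, hi))
    return(list(threshold = hi, phantom = ph, achieved = 0, iterations = 0L))
  }
  ph <- NULL; mid <- NA_real_; achieved <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    ph <- apply_threshold(field, maskinfo, table, mid)
    achieved <- ph$dense_fraction
    if (abs(achieved - target_dense_percent) <= tol)
      return(list(threshold = mid, phantom = ph, achieved = achieved,
                  iterations = it))
    if (achieved > target_dense_percent) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "threshold calibration did not reach %.2f%% (best %.3f%%) in %d iterations",
    target_dense_percent, achieved, max_iter), call. = FALSE)
}

#' Aging series: one anatomy, several densities
#'
#' Thresholds the same underlying noise field at calibrated values to produce
#' phantoms of increasing dense-tissue percentage — progressive involution of
#' the same simulated breast, denser phantoms representing younger tissue.
#'
#' @inheritParams calibrate_threshold
#' @param targets dense-tissue percentages, e.g. `c(9, 27, 43, 53, 56)`.
#' @return named list of `phantom_volume` objects (names = targets).
#' @export
aging_series <- function(field, maskinfo, table, targets,
                         tol = 0.25, max_iter = 60L) {
  out <- lapply(targets, function(tg) {
    calibrate_threshold(field, maskinfo, table, tg, tol, max_iter)$phantom
  })
  names(out) <- as.character(targets)
  out
}

#' Save / load a phantom volume (raw array + JSON sidecar)
#'
#' Voxels are written as flat little-endian float64 with NaN outside the mask;
#' grid metadata, threshold and dense fraction go to `<path>.json`.
#'
#' @param phantom a `phantom_volume`.
#' @param path binary payload path.
#' @return `path` invisibly; `load_phantom` returns the `phantom_volume`.
#' @export
save_phantom <- function(phantom, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(phantom$voxels), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(dim = dim(phantom$voxels), spacing = phantom$spacing,
         origin = phantom$origin, threshold_used = phantom$threshold_used,
         dense_fraction = phantom$dense_fraction),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  voxels <- array(readBin(con, "double", n = n, size = 8, endian = "little"),
                  dim = meta$dim)
  structure(list(voxels = voxels, mask = !is.na(voxels),
                 spacing = meta$spacing, origin = meta$origin,
                 threshold_used = meta$threshold_used,
                 dense_fraction = meta$dense_fraction),
            class = "phantom_volume")
}

#' Mean-projection image of a phantom
#'
#' Writes a PNG of the through-thickness mean percent-dense map (projection
#' along z) with a percent colour scale.
#'
#' @param phantom a `phantom_volume`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_phantom_projection <- function(phantom, path) {
  dense <- 1 - phantom$voxels
  proj <- apply(dense, c(1, 2), mean, na.rm = TRUE) * 100
  proj[is.nan(proj)] <- NA
  grDevices::png(path, width = 800, height = 420)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 4))
  graphics::image(seq_len(nrow(proj)), seq_len(ncol(proj)), proj,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "", asp = 1,
                  main = sprintf("dense tissue %.1f%%", phantom$dense_fraction))
  invisible(path)
}
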