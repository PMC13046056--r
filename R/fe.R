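# Quasi-static large-deformation neo-Hookean solve of plate compression.
# Internal mechanical units: cm, N, N/cm^2 (1 N/cm^2 = 10 kPa); the API takes
# moduli in kPa and converts.

.KPA <- 0.1  # kPa -> N/cm^2

#' Rigid compression plates
#'
#' Two parallel rigid planes normal to y. The fixed (stationary, sensor-side)
#' plate sits at `fixed_plane`; the moving plate starts at `moving_plane` and
#' is displaced by `displacement` along -y as a monotone ramp. Contact is a
#' frictionless node-to-plane penalty: a node penetrating by `g` receives a
#' normal force `penalty * g * tributary_area`.
#'
#' @param fixed_plane,moving_plane initial y-coordinates (cm).
#' @param displacement prescribed moving-plate travel (cm) along -y;
#'   default 3.76, about half the phantom width.
#' @param extent_x,extent_z plate extent (cm), default 20 x 7.5.
#' @param penalty contact penalty stiffness (N/cm^3).
#' @return object of class `plate_model`.
#' @export
plate_model <- function(fixed_plane = -3.75, moving_plane = 3.75,
                        displacement = 3.76, extent_x = c(-10, 10),
                        extent_z = c(0, 7.5), penalty = 2000) {
  stopifnot(moving_plane > fixed_plane, displacement >= 0, penalty > 0)
  structure(list(fixed_plane = fixed_plane, moving_plane = moving_plane,
                 displacement = displacement, extent_x = extent_x,
                 extent_z = extent_z, penalty = penalty),
            class = "plate_model")
}

#' Per-element neo-Hookean law from a material map
#'
#' Compressible neo-Hookean strain energy
#' \eqn{W = \mu/2 (I_1 - 3) - \mu \ln J + \lambda/2 (\ln J)^2}; stress-free at
#' the reference (`W(I) = 0`, `P(I) = 0`).
#'
#' @param mesh a `tet_mesh` with `element_modulus` set (kPa), or NULL modulus
#'   with `E_uniform` supplied.
#' @param materials a [material_map()] (supplies nu).
#' @param E_uniform optional uniform modulus (kPa) overriding the per-element
#'   values (homogeneous verification problems).
#' @return list `mu`, `lambda` per element in N/cm^2.
#' @export
neo_hookean_law <- function(mesh, materials, E_uniform = NULL) {
  E <- if (!is.null(E_uniform)) rep(E_uniform, nrow(mesh$tets))
       else mesh$element_modulus
  if (is.null(E)) stop("mesh has no element moduli; run assign_materials()",
                       call. = FALSE)
  lp <- lame_parameters(E * .KPA, materials$nu)
  list(mu = lp$mu, lambda = lp$lambda, nu = materials$nu, E_kPa = E)
}

#' Internal nodal forces and consistent tangent
#'
#' Total-Lagrangian assembly of the per-element first Piola stress against the
#' shape-function gradients; the tangent is the exact derivative of the
#' forces (verifiable by finite differences).
#'
#' @param mesh a `tet_mesh`.
#' @param law from [neo_hookean_law()].
#' @param u nodal displacement vector, length `3 * n_nodes` (cm).
#' @param want_K assemble the sparse tangent too?
#' @return list `f` (N), `K` (dgCMatrix, N/cm), `minJ`, `energy` (N cm).
#' @export
internal_forces <- function(mesh, law, u, want_K = TRUE) {
  pre <- .mesh_precompute(mesh)
  res <- cpp_nh_assemble(mesh$tets, pre$gradN, pre$vol, law$mu, law$lambda,
                         u, want_K)
  out <- list(f = res$f, minJ = res$minJ, energy = res$energy)
  if (want_K) {
    n <- 3 * nrow(mesh$nodes)
    out$K <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                                  dims = c(n, n))
  }
  out
}

# cache the reference-configuration precompute on the mesh in the caller's
# frame is intrusive; use a local environment keyed by object identity instead
.precompute_cache <- new.env(parent = emptyenv())

.mesh_precompute <- function(mesh) {
  key <- attr(mesh, "precompute_key")
  if (!is.null(key) && !is.null(.precompute_cache[[key]]))
    return(.precompute_cache[[key]])
  cpp_tet_precompute(mesh$nodes, mesh$tets)
}

.with_precompute <- function(mesh) {
  n <- length(ls(.precompute_cache))
  key <- paste0("mesh", n + 1L, "_", nrow(mesh$nodes), "_", nrow(mesh$tets))
  .precompute_cache[[key]] <- cpp_tet_precompute(mesh$nodes, mesh$tets)
  attr(mesh, "precompute_key") <- key
  mesh
}

#' Penalty contact forces against the rigid plates
#'
#' @param mesh a `tet_mesh` (tributary areas from the undeformed boundary).
#' @param plate a [plate_model()].
#' @param u nodal displacements (length 3n).
#' @param moving_plane_y current y of the moving plate.
#' @return list: `f` (length-3n force vector, y-components only),
#'   `k_diag` (contact stiffness on y DOFs), `F_fixed`, `F_moving` (total
#'   y-force on the breast from each plate, N), `max_pen` (cm).
#' @export
contact_forces <- function(mesh, plate, u, moving_plane_y = plate$moving_plane) {
  n <- nrow(mesh$nodes)
  ydof <- 3 * seq_len(n) - 1
  ynow <- mesh$nodes[, 2] + u[ydof]
  a <- mesh$tributary_area
  k <- plate$penalty
  f <- numeric(3 * n)
  kd <- numeric(n)
  g_fix <- pmax(plate$fixed_plane - ynow, 0)       # penetration below fixed
  g_mov <- pmax(ynow - moving_plane_y, 0)          # penetration above moving
  act <- a > 0
  f_fix <- k * g_fix * a * act                      # pushes +y
  f_mov <- k * g_mov * a * act                      # pushes -y
  f[ydof] <- f_fix - f_mov
  kd <- k * a * act * ((g_fix > 0) + (g_mov > 0))
  list(f = f, k_diag = kd,
       F_fixed = sum(f_fix), F_moving = -sum(f_mov),
       max_pen = max(c(g_fix[act], g_mov[act], 0)),
       node_force_fixed = f_fix, node_force_moving = -f_mov)
}

.free_dofs <- function(mesh) {
  n <- nrow(mesh$nodes)
  fixed <- logical(3 * n)
  ns <- mesh$node_sets
  fixed[3 * ns$back_surface] <- TRUE                       # z on the back
  fixed[3 * ns$near_fixed_plate - 2] <- TRUE               # x near plates
  fixed[3 * ns$near_moving_plate - 2] <- TRUE
  fixed[3 * ns$anchor_node - (2:0)] <- TRUE                # anchor: all
  !fixed
}

#' Solve quasi-static plate compression
#'
#' Ramps the moving plate over `n_steps` equal increments; each step is solved
#' by damped Newton iteration on the free degrees of freedom with a direct
#' sparse factorisation. A step that fails to converge (or inverts an
#' element at full damping) is bisected into sub-steps, up to `max_bisect`
#' levels, before aborting with a diagnostic.
#'
#' @param mesh a `tet_mesh` with node sets populated.
#' @param law from [neo_hookean_law()].
#' @param plate a [plate_model()].
#' @param n_steps number of ramp increments.
#' @param tol relative residual tolerance (against the contact-force scale).
#' @param max_iter Newton iterations per step.
#' @param max_bisect recursive step-bisection depth.
#' @param store_history keep per-step displacement snapshots?
#' @param verbose print a per-step line?
#' @return object of class `compression_state`: final displacements `u`,
#'   per-step data frame `steps` (plate position, iterations, residual,
#'   reaction forces, strain energy, max penetration), final `contact`
#'   decomposition, and the node sets used.
#' @export
solve_compression <- function(mesh, law, plate, n_steps = 20L, tol = 1e-6,
                              max_iter = 30L, max_bisect = 4L,
                              store_history = FALSE, verbose = FALSE) {
  mesh <- .with_precompute(mesh)
  pre <- .mesh_precompute(mesh)
  n <- nrow(mesh$nodes)
  free <- .free_dofs(mesh)
  anchor_y <- 3 * mesh$node_sets$anchor_node - 1
  u <- numeric(3 * n)

  # The tangent's sparsity pattern (node adjacency) is fixed: build the
  # reduced free-DOF matrix once, then only refresh its values each
  # iteration via a precomputed triplet -> CSC-position map.
  nfree <- sum(free)
  dofmap <- integer(3 * n)
  dofmap[free] <- seq_len(nfree)
  res0 <- cpp_nh_assemble(mesh$tets, pre$gradN, pre$vol, law$mu, law$lambda,
                          u, TRUE)
  trip_keep <- which(free[res0$i] & free[res0$j])
  ri <- dofmap[res0$i[trip_keep]]
  rj <- dofmap[res0$j[trip_keep]]
  K0 <- Matrix::sparseMatrix(i = ri, j = rj, x = res0$x[trip_keep],
                             dims = c(nfree, nfree))
  trip_map <- cpp_csc_map(ri, rj, K0@p, K0@i)
  nnz <- length(K0@x)
  ydof_all <- 3 * seq_len(n) - 1
  ynodes <- which(free[ydof_all])
  diag_pos <- rep(NA_integer_, n)
  if (length(ynodes)) {
    rd <- dofmap[ydof_all[ynodes]]
    diag_pos[ynodes] <- cpp_csc_map(rd, rd, K0@p, K0@i)
  }

  evaluate <- function(u, plane_y) {
    fi <- internal_forces(mesh, law, u, want_K = FALSE)
    fc <- contact_forces(mesh, plate, u, plane_y)
    r <- fi$f - fc$f
    list(fi = fi, fc = fc, r = r, rn = sqrt(sum(r[free]^2)),
         ref = max(sqrt(sum(fc$f^2)), 1e-3))
  }

  reduced_tangent <- function(u, fc) {
    res <- cpp_nh_assemble(mesh$tets, pre$gradN, pre$vol, law$mu, law$lambda,
                           u, TRUE)
    xv <- cpp_csc_accumulate(trip_map, res$x[trip_keep], nnz)
    act <- which(fc$k_diag > 0 & !is.na(diag_pos))
    if (length(act)) xv[diag_pos[act]] <- xv[diag_pos[act]] + fc$k_diag[act]
    K <- K0
    K@x <- xv
    K
  }

  newton <- function(u, plane_y) {
    ev <- evaluate(u, plane_y)
    if (ev$fi$minJ <= 0) return(list(ok = FALSE, u = u, why = "inverted start"))
    for (it in seq_len(max_iter)) {
      # large factor objects accumulate faster than the collector reclaims
      # them on big meshes; keep the high-water mark bounded
      if (nfree > 10000L) gc(FALSE)
      if (ev$rn <= tol * ev$ref)
        return(list(ok = TRUE, u = u, iters = it - 1L, residual = ev$rn,
                    fi = ev$fi, fc = ev$fc))
      Kf <- reduced_tangent(u, ev$fc)
      du <- numeric(3 * n)
      # K is symmetric; Cholesky when (near-solution) positive definite.
      # Indefinite intermediate tangents get a growing diagonal shift
      # (a regularized modified-Newton direction; the line search absorbs
      # the inexactness), with sparse LU only as a last resort.
      rhs <- -ev$r[free]
      try_chol <- function(M) tryCatch(
        Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(M),
                                       LDL = FALSE, super = TRUE), rhs),
        warning = function(w) NULL, error = function(e) NULL)
      sol <- try_chol(Kf)
      if (is.null(sol) || any(!is.finite(as.numeric(sol)))) {
        dscale <- mean(abs(Matrix::diag(Kf)))
        for (tau in c(1e-6, 1e-4, 1e-2, 1) * dscale) {
          sol <- try_chol(Kf + Matrix::Diagonal(nfree, tau))
          if (!is.null(sol) && all(is.finite(as.numeric(sol)))) break
        }
      }
      if (is.null(sol) || any(!is.finite(as.numeric(sol))))
        sol <- try(Matrix::solve(Kf, rhs), silent = TRUE)
      if (inherits(sol, "try-error") || is.null(sol))
        return(list(ok = FALSE, u = u, why = "singular tangent"))
      du[free] <- as.numeric(sol)
      s <- 1; accepted <- FALSE
      for (ls in 1:10) {
        ut <- u + s * du
        evt <- evaluate(ut, plane_y)
        if (evt$fi$minJ > 0 &&
            (evt$rn < ev$rn || evt$rn <= tol * evt$ref)) {
          u <- ut; ev <- evt; accepted <- TRUE
          break
        }
        s <- s / 2
      }
      if (!accepted) return(list(ok = FALSE, u = u, why = "line search stalled",
                                 residual = ev$rn, minJ = ev$fi$minJ))
    }
    if (ev$rn <= tol * ev$ref)
      return(list(ok = TRUE, u = u, iters = max_iter, residual = ev$rn,
                  fi = ev$fi, fc = ev$fc))
    list(ok = FALSE, u = u, why = "max iterations", residual = ev$rn)
  }

  advance <- function(u, from_y, to_y, depth) {
    res <- newton(u, to_y)
    if (res$ok) return(res)
    if (depth >= max_bisect)
      stop(sprintf(
        "compression step failed (%s) at plate y = %.4f, residual %.3e",
        res$why, to_y, if (is.null(res$residual)) NA_real_ else res$residual),
        call. = FALSE)
    mid <- 0.5 * (from_y + to_y)
    half <- advance(u, from_y, mid, depth + 1L)
    advance(half$u, mid, to_y, depth + 1L)
  }

  steps <- vector("list", n_steps)
  history <- if (store_history) vector("list", n_steps) else NULL
  plane_prev <- plate$moving_plane
  total_iters <- 0L
  for (s in seq_len(n_steps)) {
    plane_y <- plate$moving_plane - plate$displacement * s / n_steps
    res <- advance(u, plane_prev, plane_y, 0L)
    u <- res$u
    fc <- res$fc
    F_fixed <- fc$F_fixed + res$fi$f[anchor_y] - fc$f[anchor_y]
    steps[[s]] <- data.frame(
      step = s, plate_y = plane_y, iterations = res$iters,
      residual = res$residual, F_moving = fc$F_moving, F_fixed = F_fixed,
      energy = res$fi$energy, max_penetration = fc$max_pen,
      min_J = res$fi$minJ)
    if (store_history) history[[s]] <- u
    if (verbose)
      message(sprintf(
        "step %2d/%d  plate y %7.3f  iters %2d  res %.2e  F_mov %8.3f N",
        s, n_steps, plane_y, res$iters, res$residual, fc$F_moving))
    plane_prev <- plane_y
    total_iters <- total_iters + res$iters
  }
  final_fc <- contact_forces(mesh, plate, u,
                             plate$moving_plane - plate$displacement)
  structure(list(u = u, steps = do.call(rbind, steps), contact = final_fc,
                 mesh = mesh, plate = plate, history = history,
                 anchor_reaction_y = steps[[n_steps]]$F_fixed - final_fc$F_fixed),
            class = "compression_state")
}

#' Plate reaction forces of a converged state
#' @param state a `compression_state`.
#' @return list `F_moving`, `F_fixed` (N, y-components; the anchor-node
#'   reaction is attributed to the fixed plate it touches).
#' @export
reaction_forces <- function(state) {
  last <- state$steps[nrow(state$steps), ]
  list(F_moving = last$F_moving, F_fixed = last$F_fixed)
}
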