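#' Fluid properties
#'
#' Newtonian fluid constants for the cerebrospinal-fluid model: water-like
#' density and viscosity.
#'
#' @param density Mass density, kg/m^3 (default 1000).
#' @param viscosity Dynamic viscosity, Pa s (default 1e-3, i.e. 1 centipoise).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1e-3) {
  if (!is.numeric(density) || density <= 0)
    stop("density must be positive (kg/m^3)", call. = FALSE)
  if (!is.numeric(viscosity) || viscosity <= 0)
    stop("viscosity must be positive (Pa s)", call. = FALSE)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Wall model for the no-slip floor
#'
#' The floor at y = 0 can be represented either by the exact image system
#' built into the wall-bounded kernel (default; the kernel itself vanishes on
#' y = 0) or by a finite strip of zero-velocity collocation points along the
#' floor using the free-space kernel (a cross-check mode).
#'
#' @param representation `"image-system"` or `"collocation-strip"`.
#' @param extent Strip length, micrometres, centred on the domain
#'   (collocation-strip mode only; must be at least 4x the domain width).
#' @param spacing Spacing of strip points, micrometres (default: the
#'   regularization length).
#' @param slip_tolerance Maximum admissible wall speed as a fraction of the
#'   peak cilium node speed, in (0, 0.05].
#' @return An object of class `wall_model`.
#' @export
wall_model <- function(representation = c("image-system", "collocation-strip"),
                       extent = 200, spacing = NULL, slip_tolerance = 0.01) {
  representation <- match.arg(representation)
  if (slip_tolerance <= 0 || slip_tolerance > 0.05)
    stop("slip_tolerance must lie in (0, 0.05]", call. = FALSE)
  structure(list(representation = representation, extent = extent,
                 spacing = spacing, slip_tolerance = slip_tolerance),
            class = "wall_model")
}

#' Assemble the instantaneous Stokes mobility system
#'
#' Builds the dense linear map from point forces (line densities, pN per
#' micrometre of depth) at the collocation points to velocities (micrometres
#' per second) at the same points, using the regularized 2D Stokeslet kernel.
#' In image-system mode every source carries its wall image so the flow
#' vanishes identically on y = 0; in collocation-strip mode zero-velocity wall
#' points are appended and the free-space kernel is used.
#'
#' @param points `n x 2` matrix of collocation coordinates, micrometres; all
#'   points must lie in the closed upper half-plane.
#' @param epsilon Regularization length, micrometres.
#' @param fluid A [fluid_properties()] object.
#' @param wall A [wall_model()] object.
#' @return A `stokes_system`: the point set (with any appended wall points),
#'   `epsilon`, `fluid`, `wall`, the index of body (non-wall) points, and the
#'   symmetric `mobility` matrix (2n x 2n, stacked as all x-components then
#'   all y-components).
#' @export
assemble_system <- function(points, epsilon, fluid = fluid_properties(),
                            wall = wall_model()) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an n x 2 matrix", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be positive", call. = FALSE)
  if (any(points[, 2] < -1e-12))
    stop("domain error: collocation points must lie on or above the wall (y >= 0)",
         call. = FALSE)
  nb <- nrow(points)
  if (nb >= 2) {
    dmin <- min(stats::dist(points))
    if (dmin < epsilon / 10)
      stop(sprintf(paste0("conditioning error: collocation points %.3g um apart ",
                          "(closer than epsilon/10 = %.3g um)"),
                   dmin, epsilon / 10), call. = FALSE)
  }
  mode <- if (wall$representation == "image-system") "image-system" else "free-space"
  pts <- points
  if (wall$representation == "collocation-strip") {
    sp <- if (is.null(wall$spacing)) epsilon else wall$spacing
    cx <- mean(range(points[, 1]))
    xw <- seq(cx - wall$extent / 2, cx + wall$extent / 2, by = sp)
    pts <- rbind(points, cbind(xw, 0))
  }
  M <- kernel_matrix(pts, pts, epsilon^2, mode, fluid$viscosity)
  M <- (M + t(M)) / 2  # kernel is exactly reciprocal; remove roundoff skew
  structure(list(points = pts, epsilon = epsilon, fluid = fluid, wall = wall,
                 body_idx = seq_len(nb), mobility = M),
            class = "stokes_system")
}

#' @export
print.stokes_system <- function(x, ...) {
  cat(sprintf("Stokes system: %d collocation points (%d body), eps %.3g um, wall: %s\n",
              nrow(x$points), length(x$body_idx), x$epsilon,
              x$wall$representation))
  invisible(x)
}

#' Solve for the point forces realizing prescribed boundary velocities
#'
#' Inverts the mobility map: finds the force line-densities at the
#' collocation points whose induced flow matches the prescribed velocities
#' there. Solved directly via the symmetric factorization; if the system is
#' too ill-conditioned, a Tikhonov-regularized least-squares fallback is used
#' and flagged in the result attributes.
#'
#' @param system A `stokes_system`.
#' @param bv `n x 2` matrix of prescribed velocities at the body points
#'   (micrometres per second). Wall strip points, if any, are automatically
#'   assigned zero velocity.
#' @return `n_total x 2` matrix of forces (pN per micrometre of depth), with
#'   attributes `residual` (relative), `rcond`, `fallback` (logical) and
#'   `dissipation` (sum of f.v, always non-negative up to roundoff).
#' @export
solve_forces <- function(system, bv) {
  bv <- as.matrix(bv)
  nb <- length(system$body_idx)
  nt <- nrow(system$points)
  if (nrow(bv) == nb && nt > nb) bv <- rbind(bv, matrix(0, nt - nb, 2))
  if (nrow(bv) != nt || ncol(bv) != 2)
    stop("boundary velocities must match the system point count", call. = FALSE)
  if (any(!is.finite(bv))) stop("boundary velocities must be finite", call. = FALSE)
  rhs <- c(bv[, 1], bv[, 2])
  M <- system$mobility
  rc <- rcond(M)
  fallback <- FALSE
  f <- tryCatch({
    if (rc < 1e-14) stop("ill-conditioned")
    solve(M, rhs)
  }, error = function(e) {
    fallback <<- TRUE
    lam <- max(abs(M)) * 1e-12
    solve(M + diag(lam, nrow(M)), rhs)
  })
  res <- sqrt(sum((M %*% f - rhs)^2))
  rel <- if (sqrt(sum(rhs^2)) > 0) res / sqrt(sum(rhs^2)) else res
  if (rel > 1e-8 && !fallback) {
    fallback <- TRUE
    lam <- max(abs(M)) * 1e-12
    f <- solve(M + diag(lam, nrow(M)), rhs)
    rel <- sqrt(sum((M %*% f - rhs)^2)) / max(sqrt(sum(rhs^2)), .Machine$double.xmin)
  }
  if (!all(is.finite(f)))
    stop(sprintf("singular mobility system (rcond = %.3g)", rc), call. = FALSE)
  forces <- cbind(f[seq_len(nt)], f[nt + seq_len(nt)])
  structure(forces, residual = rel, rcond = rc, fallback = fallback,
            dissipation = sum(forces * bv))
}

#' Evaluate the flow velocity at arbitrary points
#'
#' Superposes the regularized kernels (plus wall images in image-system mode)
#' of all point forces. At the collocation points this reproduces the
#' prescribed velocities to the solver residual; on the wall the image-system
#' flow is identically zero.
#'
#' @param system A `stokes_system`.
#' @param forces Force matrix as returned by [solve_forces()].
#' @param query `m x 2` matrix of evaluation points (micrometres), in the
#'   closed upper half-plane.
#' @param chunk Number of query points per kernel block (memory control).
#' @return `m x 2` matrix of velocities, micrometres per second.
#' @export
evaluate_velocity <- function(system, forces, query, chunk = 4096L) {
  query <- matrix(as.numeric(query), ncol = 2)
  if (any(query[, 2] < -1e-12))
    stop("domain error: query points must lie on or above the wall (y >= 0)",
         call. = FALSE)
  mode <- if (system$wall$representation == "image-system") "image-system" else "free-space"
  fvec <- c(forces[, 1], forces[, 2])
  m <- nrow(query)
  out <- matrix(0, m, 2)
  nt <- nrow(system$points)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    K <- kernel_matrix(query[lo:hi, , drop = FALSE], system$points,
                       system$epsilon^2, mode, system$fluid$viscosity)
    u <- K %*% fvec
    nq <- hi - lo + 1L
    out[lo:hi, 1] <- u[seq_len(nq)]
    out[lo:hi, 2] <- u[nq + seq_len(nq)]
  }
  out
}

#' Wall slip diagnostic
#'
#' Maximum flow speed sampled along the wall, as a fraction of a reference
#' speed (typically the peak cilium node speed). Used to assert the no-slip
#' contract each timestep.
#'
#' @param system A `stokes_system`.
#' @param forces Forces from [solve_forces()].
#' @param x_range Horizontal extent to sample, micrometres.
#' @param n Number of sample points.
#' @param reference_speed Speed to normalize by (default 1: absolute).
#' @return Maximum relative wall speed.
#' @export
wall_slip <- function(system, forces, x_range = c(0, 50), n = 50,
                      reference_speed = 1) {
  xs <- seq(x_range[1], x_range[2], length.out = n)
  u <- evaluate_velocity(system, forces, cbind(xs, 0))
  max(sqrt(rowSums(u^2))) / reference_speed
}
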