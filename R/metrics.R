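#' Rectangular metrics window
#'
#' The rectangle over which observables are computed: the wall is its bottom
#' edge, the origin its bottom-left corner. The 50 um extent runs horizontally
#' (the pumping direction), 25 um vertically.
#'
#' @param width Horizontal extent, micrometres.
#' @param height Vertical extent, micrometres.
#' @return An object of class `flow_domain`.
#' @export
flow_domain <- function(width = 50, height = 25) {
  if (width <= 0 || height <= 0)
    stop("domain width and height must be positive", call. = FALSE)
  structure(list(width = width, height = height), class = "flow_domain")
}

# resolve a velocity source: either a function(xy-matrix) -> m x 2 velocities,
# or a stokes_system + forces pair
velocity_fun <- function(system, forces) {
  if (is.function(system)) return(system)
  function(xy) evaluate_velocity(system, forces, xy)
}

#' Volumetric flux across the right boundary line
#'
#' Gauss-Legendre quadrature of the horizontal velocity component over the
#' vertical segment x = width, y in \[0, height\]. Positive flux is rightward
#' (downstream). Units: um^2/s per unit depth.
#'
#' @param system A `stokes_system`, or a function mapping an `m x 2`
#'   coordinate matrix to an `m x 2` velocity matrix (used directly).
#' @param forces Forces from [solve_forces()] (ignored when `system` is a
#'   function).
#' @param domain A [flow_domain()].
#' @param n_quad Number of quadrature nodes (at least 8).
#' @return Volumetric flux per unit depth, um^2/s.
#' @export
flux_across_right_line <- function(system, forces = NULL,
                                   domain = flow_domain(), n_quad = 32) {
  if (n_quad < 8) stop("n_quad must be at least 8", call. = FALSE)
  gl <- pracma::gaussLegendre(n_quad, 0, domain$height)
  uf <- velocity_fun(system, forces)
  u <- uf(cbind(domain$width, gl$x))
  sum(gl$w * u[, 1])
}

#' Net outward flux over the four sides of the metrics window
#'
#' Integral-form incompressibility check: the outward fluxes over the left,
#' right, top and bottom edges of the rectangle must cancel. The bottom edge
#' lies on the no-slip wall (identically zero flow in image-system mode).
#'
#' @inheritParams flux_across_right_line
#' @return A list with `net` (sum of outward side fluxes, um^2/s), `gross`
#'   (sum of their absolute values) and the per-side values.
#' @export
boundary_balance <- function(system, forces = NULL, domain = flow_domain(),
                             n_quad = 32) {
  uf <- velocity_fun(system, forces)
  glv <- pracma::gaussLegendre(n_quad, 0, domain$height)
  glh <- pracma::gaussLegendre(n_quad, 0, domain$width)
  right <- sum(glv$w * uf(cbind(domain$width, glv$x))[, 1])
  left <- -sum(glv$w * uf(cbind(0, glv$x))[, 1])
  top <- sum(glh$w * uf(cbind(glh$x, domain$height))[, 2])
  bottom <- -sum(glh$w * uf(cbind(glh$x, 0))[, 2])
  sides <- c(right = right, left = left, top = top, bottom = bottom)
  list(net = sum(sides), gross = sum(abs(sides)), sides = sides)
}

#' Sample the velocity field on a regular grid
#'
#' Evaluates the flow on a rectangular grid covering the metrics window, for
#' contour plotting and field export. Grid points within one regularization
#' length of a force point are flagged (velocities there are blob-smoothed).
#'
#' @inheritParams flux_across_right_line
#' @param spacing Grid spacing, micrometres (default 0.25).
#' @return A `velocity_field`: grid coordinate vectors `x`, `y`, velocity
#'   component matrices `u`, `v` (rows follow `x`), `spacing`, and a logical
#'   `near_source` matrix.
#' @export
sample_field <- function(system, forces, domain = flow_domain(),
                         spacing = 0.25) {
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  xs <- seq(0, domain$width, by = spacing)
  ys <- seq(0, domain$height, by = spacing)
  g <- expand.grid(x = xs, y = ys)
  uf <- velocity_fun(system, forces)
  u <- uf(as.matrix(g))
  near <- rep(FALSE, nrow(g))
  if (!is.function(system)) {
    P <- system$points
    for (k in seq_len(nrow(P))) {
      d2 <- (g$x - P[k, 1])^2 + (g$y - P[k, 2])^2
      near <- near | d2 < system$epsilon^2
    }
  }
  structure(list(x = xs, y = ys,
                 u = matrix(u[, 1], length(xs), length(ys)),
                 v = matrix(u[, 2], length(xs), length(ys)),
                 spacing = spacing,
                 near_source = matrix(near, length(xs), length(ys))),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("Velocity field: %d x %d grid (spacing %.3g um), max speed %.4g um/s\n",
              length(x$x), length(x$y), x$spacing, max(sp)))
  invisible(x)
}

#' Flux time series over a simulated run
#'
#' Container for the per-timestep volumetric flux across the right boundary
#' line, with the bookkeeping needed to convert to mass flow rates and to
#' form per-cycle aggregates.
#'
#' @param values Numeric vector of fluxes, um^2/s per unit depth, one per
#'   timestep (length `n_frames * n_cycles`).
#' @param timestep Timestep, seconds.
#' @param n_frames Frames (timesteps) per beat cycle.
#' @param n_cycles Number of cycles.
#' @param reference_depth Out-of-plane depth for mass-flow conversion,
#'   micrometres (default 1e6, i.e. the 1 m convention of planar solvers).
#' @param density Fluid density, kg/m^3.
#' @return An object of class `flux_series`.
#' @export
flux_series <- function(values, timestep, n_frames, n_cycles,
                        reference_depth = 1e6, density = 1000) {
  if (length(values) != n_frames * n_cycles)
    stop(sprintf("flux series length %d does not equal n_frames * n_cycles = %d",
                 length(values), n_frames * n_cycles), call. = FALSE)
  structure(list(values = values, timestep = timestep,
                 n_frames = as.integer(n_frames), n_cycles = as.integer(n_cycles),
                 reference_depth = reference_depth, density = density),
            class = "flux_series")
}

# ug/s per (um^2/s) at the stored density and depth
mass_flow_factor <- function(fs) fs$density * fs$reference_depth * 1e-9

#' Aggregate a flux series into per-cycle and whole-run observables
#'
#' Per-cycle mean (mean flux over that cycle's timesteps), whole-run mean,
#' the maximum per-cycle mean, and the instantaneous extrema, each both as
#' volumetric flux per unit depth (um^2/s) and as a mass flow rate (ug/s) at
#' the stored density and reference depth.
#'
#' @param fs A [flux_series()].
#' @return A list with elements `cycle_means`, `run_mean`, `max_cycle_mean`,
#'   `inst_max`, `inst_min` (um^2/s) and their `*_ug_s` counterparts.
#' @export
aggregate_flux <- function(fs) {
  v <- fs$values
  cyc <- rep(seq_len(fs$n_cycles), each = fs$n_frames)
  if (length(cyc) != length(v))
    stop("structural error: flux series length mismatch", call. = FALSE)
  cm <- as.numeric(tapply(v, cyc, mean))
  k <- mass_flow_factor(fs)
  list(cycle_means = cm,
       run_mean = mean(v),
       max_cycle_mean = max(cm),
       inst_max = max(v),
       inst_min = min(v),
       cycle_means_ug_s = cm * k,
       run_mean_ug_s = mean(v) * k,
       max_cycle_mean_ug_s = max(cm) * k,
       inst_max_ug_s = max(v) * k)
}

#' @export
print.flux_series <- function(x, ...) {
  ag <- aggregate_flux(x)
  cat(sprintf("Flux series: %d cycles x %d frames (dt %.4g s), depth %.3g um\n",
              x$n_cycles, x$n_frames, x$timestep, x$reference_depth))
  cat(sprintf("  run mean %.5g um^2/s (%.5g ug/s), max cycle mean %.5g um^2/s\n",
              ag$run_mean, ag$run_mean_ug_s, ag$max_cycle_mean))
  invisible(x)
}

#' Export a flux series to CSV
#'
#' One row per timestep: index, time, cycle, volumetric flux and mass flow.
#'
#' @param fs A [flux_series()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(fs, path) {
  k <- mass_flow_factor(fs)
  n <- length(fs$values)
  df <- data.frame(timestep = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) * fs$timestep,
                   cycle_index = rep(seq_len(fs$n_cycles), each = fs$n_frames),
                   flux_um2_per_s = fs$values,
                   massflow_ug_per_s = fs$values * k)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a sampled velocity field
#'
#' `write_field_csv` writes one row per grid point (x_um, y_um, u_um_s,
#' v_um_s); `write_field_vtk` writes a legacy-VTK structured-points ASCII
#' file with the velocity as a vector field, readable by ParaView.
#'
#' @param field A `velocity_field` from [sample_field()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  g <- expand.grid(x_um = field$x, y_um = field$y)
  df <- data.frame(g, u_um_s = as.vector(field$u), v_um_s = as.vector(field$v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
write_field_vtk <- function(field, path) {
  nx <- length(field$x); ny <- length(field$y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ciliaflow velocity field (um, um/s)",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", field$x[1], field$y[1]),
               sprintf("SPACING %g %g 1", field$spacing, field$spacing),
               sprintf("POINT_DATA %d", nx * ny),
               "VECTORS velocity float"), con)
  # VTK structured points iterate x fastest, matching our matrix layout
  rows <- sprintf("%.7g %.7g 0", as.vector(field$u), as.vector(field$v))
  writeLines(rows, con)
  invisible(path)
}
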