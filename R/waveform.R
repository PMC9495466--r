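#' Beat parameters for the synthetic cilium waveform
#'
#' Parametrizes the cyclic beat of a single motile cilium anchored to the
#' wall. The shape model is a tangent-angle wave along the filament,
#' \deqn{\theta(s,t) = \theta_0 + A\,\mathrm{ramp}(s)\,[\cos(ks)\cos(\omega t)
#'   + a\,\sin(ks)\sin(\omega t)],}
#' where \eqn{s} is arc length, \eqn{\theta} the local tangent angle from the
#' vertical, and \eqn{\mathrm{ramp}(s) = 0.3 + 0.7 s/L} grades the modulation
#' from base to tip. At `asymmetry = 0` the wave is a standing wave and the
#' beat is exactly time-reversible (reciprocal); at `asymmetry = 1` it is a
#' pure traveling wave, the maximally non-reciprocal member of the family.
#' Positions are arc-length integrals of \eqn{(\sin\theta, \cos\theta)}, so
#' the filament is inextensible by construction.
#'
#' @param length Cilium arc length, micrometres.
#' @param frequency Beat frequency, Hz. The default is the reciprocal of a
#'   0.033 s cycle, approximately 30 Hz.
#' @param n_nodes Number of nodes along the filament (the anchor is node 1).
#' @param n_frames Frames per beat cycle.
#' @param base_tilt Angle of the spatial mean line from the vertical axis,
#'   degrees, positive toward +X.
#' @param asymmetry Stroke asymmetry coefficient in \[0, 1\]; 0 gives a
#'   reciprocal (zero-net-pumping) beat.
#' @param amplitude Peak tangent-angle modulation at the tip, radians.
#' @param wavenumber Phase lag of the tangent-angle wave along the filament,
#'   radians per micrometre.
#' @return An object of class `beat_params`.
#' @export
beat_params <- function(length = 4.75,
                        frequency = 1 / 0.033,
                        n_nodes = 20L,
                        n_frames = 33L,
                        base_tilt = 30,
                        asymmetry = 0.8,
                        amplitude = 0.85,
                        wavenumber = 0.45) {
  p <- list(length = length, frequency = frequency,
            n_nodes = as.integer(n_nodes), n_frames = as.integer(n_frames),
            base_tilt = base_tilt, asymmetry = asymmetry,
            amplitude = amplitude, wavenumber = wavenumber)
  class(p) <- "beat_params"
  validate_beat_params(p)
  p
}

validate_beat_params <- function(p) {
  bad <- function(field, msg) {
    stop(sprintf("invalid beat parameter `%s`: %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(p$length) || length(p$length) != 1 || p$length <= 0)
    bad("length", "must be a single positive number (micrometres)")
  if (!is.numeric(p$frequency) || p$frequency <= 0)
    bad("frequency", "must be positive (Hz)")
  if (p$n_nodes < 3) bad("n_nodes", "at least 3 nodes are required")
  if (p$n_frames < 4) bad("n_frames", "at least 4 frames are required")
  if (!is.numeric(p$amplitude) || p$amplitude < 0)
    bad("amplitude", "must be non-negative (radians)")
  if (p$asymmetry < 0 || p$asymmetry > 1)
    bad("asymmetry", "must lie in [0, 1]")
  if (abs(p$base_tilt) >= 90)
    bad("base_tilt", "mean line must stay above the wall (|angle| < 90)")
  invisible(p)
}

#' @export
print.beat_params <- function(x, ...) {
  cat("Cilium beat parameters\n")
  cat(sprintf("  length     %.3f um   frequency  %.3f Hz (period %.4f s)\n",
              x$length, x$frequency, 1 / x$frequency))
  cat(sprintf("  nodes      %d        frames/cycle %d\n", x$n_nodes, x$n_frames))
  cat(sprintf("  base tilt  %.1f deg  asymmetry  %.2f\n", x$base_tilt, x$asymmetry))
  cat(sprintf("  amplitude  %.2f rad  wavenumber %.2f rad/um\n",
              x$amplitude, x$wavenumber))
  invisible(x)
}

new_waveform <- function(positions, period, anchor) {
  w <- list(positions = positions, period = period, anchor = anchor)
  class(w) <- "cilium_waveform"
  w
}

#' Number of frames / nodes of a waveform
#' @param w A `cilium_waveform`.
#' @return Integer count.
#' @export
n_frames <- function(w) dim(w$positions)[1]

#' @rdname n_frames
#' @export
n_nodes <- function(w) dim(w$positions)[2]

#' Per-frame polyline arc lengths of a waveform
#' @param w A `cilium_waveform`.
#' @return Numeric vector, one arc length (micrometres) per frame.
#' @export
arc_lengths <- function(w) {
  P <- w$positions
  vapply(seq_len(dim(P)[1]), function(f) {
    d <- diff(P[f, , ])
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
}

#' Validate a cilium waveform
#'
#' Checks the structural invariants: the anchor (node 1) is identical in every
#' frame, and the polyline arc length is constant across frames within 1%
#' (inextensible filament).
#'
#' @param w A `cilium_waveform`.
#' @return `w`, invisibly; errors with a diagnostic naming the violated
#'   invariant otherwise.
#' @export
validate_waveform <- function(w) {
  P <- w$positions
  if (length(dim(P)) != 3 || dim(P)[3] != 2)
    stop("waveform positions must be an n_frames x n_nodes x 2 array",
         call. = FALSE)
  if (dim(P)[1] < 4) stop("waveform needs at least 4 frames", call. = FALSE)
  if (dim(P)[2] < 3) stop("waveform needs at least 3 nodes", call. = FALSE)
  if (!is.numeric(w$period) || w$period <= 0)
    stop("waveform period must be positive", call. = FALSE)
  anchors <- P[, 1, , drop = FALSE]
  dev <- max(abs(sweep(anchors, 3, w$anchor)))
  if (dev > 1e-9)
    stop(sprintf(paste0("anchoring invariant violated: node 1 moves by up to ",
                        "%.3g um across frames (anchor must be stationary)"),
                 dev), call. = FALSE)
  al <- arc_lengths(w)
  rel <- (max(al) - min(al)) / stats::median(al)
  if (rel > 0.01)
    stop(sprintf(paste0("inextensibility invariant violated: arc length ",
                        "varies by %.2f%% across frames (limit 1%%)"),
                 100 * rel), call. = FALSE)
  invisible(w)
}

#' @export
print.cilium_waveform <- function(x, ...) {
  al <- arc_lengths(x)
  cat(sprintf("Cilium waveform: %d frames x %d nodes, period %.4f s\n",
              n_frames(x), n_nodes(x), x$period))
  cat(sprintf("  anchor (%.2f, %.2f) um, arc length %.3f um, mean line %.1f deg from vertical\n",
              x$anchor[1], x$anchor[2], stats::median(al), mean_line_angle(x)))
  invisible(x)
}

# tangent angle (radians from vertical) at arc position s, cycle phase u = t/T
beat_tangent_angle <- function(p, s, u) {
  ramp <- 0.3 + 0.7 * s / p$length
  wave <- cos(p$wavenumber * s) * cos(2 * pi * u) +
    p$asymmetry * sin(p$wavenumber * s) * sin(2 * pi * u)
  p$amplitude * ramp * wave
}

# integrate tangent angles (theta0 = 0) into node positions for phases u
integrate_shape <- function(p, u, n_nodes = p$n_nodes) {
  ds <- p$length / (n_nodes - 1)
  smid <- (seq_len(n_nodes - 1) - 0.5) * ds
  pos <- array(0, dim = c(length(u), n_nodes, 2))
  for (f in seq_along(u)) {
    th <- beat_tangent_angle(p, smid, u[f])
    pos[f, , 1] <- c(0, cumsum(ds * sin(th)))
    pos[f, , 2] <- c(0, cumsum(ds * cos(th)))
  }
  pos
}

#' Generate a synthetic cilium beat waveform
#'
#' Builds one cycle of the parametric beat described in [beat_params()]:
#' tangent angles are evaluated at segment midpoints and integrated from the
#' anchor, so every frame's polyline has exactly the requested arc length and
#' the anchor never moves. The whole cycle is then rigidly rotated about the
#' anchor so that the spatial mean line (principal direction of the pooled
#' node displacements) makes exactly `base_tilt` degrees with the vertical.
#'
#' @param params A `beat_params` object.
#' @return A `cilium_waveform`: positions array (`n_frames x n_nodes x 2`,
#'   micrometres, node 1 = anchor at the origin), cycle `period` in seconds,
#'   and the `anchor` coordinate.
#' @examples
#' w <- generate_beat(beat_params())
#' range(arc_lengths(w))   # constant 4.75 um
#' @export
generate_beat <- function(params) {
  validate_beat_params(params)
  u <- (seq_len(params$n_frames) - 1) / params$n_frames
  pos <- integrate_shape(params, u)
  w <- new_waveform(pos, period = 1 / params$frequency, anchor = c(0, 0))
  w <- apply_tilt(w, params$base_tilt, warn_above = 90)
  validate_waveform(w)
  w
}

#' Spatial mean-line angle of a waveform
#'
#' The mean line is the principal direction of the node displacements from the
#' anchor, pooled over all frames; its angle is measured from the vertical
#' (+Y) axis, positive toward +X.
#'
#' @param w A `cilium_waveform`.
#' @return Angle in degrees.
#' @export
mean_line_angle <- function(w) {
  P <- w$positions
  dx <- as.vector(P[, , 1]) - w$anchor[1]
  dy <- as.vector(P[, , 2]) - w$anchor[2]
  M <- matrix(c(sum(dx * dx), sum(dx * dy), sum(dx * dy), sum(dy * dy)), 2, 2)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  atan2(v[1], v[2]) * 180 / pi
}

#' Tilt a waveform to a requested mean-line angle
#'
#' Rigidly rotates every frame about the anchor so that the spatial mean line
#' makes `angle_deg` degrees with the vertical (positive toward +X). Being an
#' isometry about the fixed anchor, arc lengths and inter-node distances are
#' preserved exactly.
#'
#' @param w A `cilium_waveform`.
#' @param angle_deg Target mean-line angle, degrees. Magnitudes of 90 or more
#'   are rejected (the cilium would intersect the floor); above 60 a warning
#'   is issued, since large tilts bring the stroke into contact with the wall.
#' @param warn_above Tilt magnitude above which to warn (default 60).
#' @return The tilted `cilium_waveform`.
#' @export
apply_tilt <- function(w, angle_deg, warn_above = 60) {
  if (abs(angle_deg) >= 90)
    stop("tilt angle must satisfy |angle| < 90 degrees: the cilium would intersect the floor",
         call. = FALSE)
  if (abs(angle_deg) > warn_above)
    warning(sprintf("tilt angle %.1f deg exceeds %g deg; the stroke may collide with the wall",
                    angle_deg, warn_above), call. = FALSE)
  rot <- (angle_deg - mean_line_angle(w)) * pi / 180
  # clockwise rotation by `rot` moves the mean line toward +X for rot > 0
  cs <- cos(rot); sn <- sin(rot)
  P <- w$positions
  dx <- P[, , 1] - w$anchor[1]
  dy <- P[, , 2] - w$anchor[2]
  P2 <- P
  P2[, , 1] <- w$anchor[1] + cs * dx + sn * dy
  P2[, , 2] <- w$anchor[2] - sn * dx + cs * dy
  new_waveform(P2, w$period, w$anchor)
}

#' Cyclically shift the phase of a waveform
#'
#' Frame `i` of the output is frame `(i + frame_offset)` of the input, indices
#' wrapping cyclically; shifting by the full frame count is the identity.
#'
#' @param w A `cilium_waveform`.
#' @param frame_offset Integer number of frames (any sign; taken modulo the
#'   frame count).
#' @return The phase-shifted `cilium_waveform`.
#' @export
phase_shift <- function(w, frame_offset) {
  nf <- n_frames(w)
  idx <- ((seq_len(nf) - 1 + frame_offset) %% nf) + 1
  new_waveform(w$positions[idx, , , drop = FALSE], w$period, w$anchor)
}

#' Node velocities at one frame
#'
#' Velocities of the prescribed boundary motion, by centered finite
#' differences with cyclic wrap:
#' \eqn{v_i(f) = (x_i(f+1) - x_i(f-1)) / (2\Delta t)},
#' \eqn{\Delta t = } period / frames. Second-order accurate and exactly
#' periodic; the anchor node velocity is exactly zero.
#'
#' @param w A `cilium_waveform`.
#' @param frame Frame index (1-based).
#' @return `n_nodes x 2` matrix of velocities, micrometres per second.
#' @export
node_velocities <- function(w, frame) {
  nf <- n_frames(w)
  if (frame < 1 || frame > nf || frame != round(frame))
    stop(sprintf("frame must be an integer in 1..%d", nf), call. = FALSE)
  dt <- w$period / nf
  nxt <- (frame %% nf) + 1
  prv <- ((frame - 2) %% nf) + 1
  v <- (w$positions[nxt, , ] - w$positions[prv, , ]) / (2 * dt)
  v[1, ] <- 0
  v
}

#' Write / read a waveform as tabular text
#'
#' The on-disk dialect is CSV with a leading metadata comment line
#' `# period_s=<seconds>` followed by a header `frame,node,x_um,y_um`; frames
#' and nodes are numbered from 0. `read_waveform(write_waveform(w))` restores
#' coordinates to full stored precision, and the reader validates the waveform
#' invariants (consistent node counts, stationary anchor, constant arc
#' length), failing with a diagnostic that names the violation.
#'
#' @param w A `cilium_waveform`.
#' @param path File path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform` returns
#'   a validated `cilium_waveform`.
#' @export
write_waveform <- function(w, path) {
  nf <- n_frames(w); nn <- n_nodes(w)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = nn),
    node = rep(seq_len(nn) - 1L, times = nf),
    x_um = as.vector(t(w$positions[, , 1])),
    y_um = as.vector(t(w$positions[, , 2])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%.17g", w$period), con)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  pm <- regmatches(meta, regexpr("period_s=[0-9eE.+-]+", meta))
  if (length(pm) != 1)
    stop("waveform file format error: missing `# period_s=` metadata line",
         call. = FALSE)
  period <- as.numeric(sub("period_s=", "", pm))
  df <- utils::read.csv(textConnection(grep("^#", lines, invert = TRUE,
                                            value = TRUE)))
  need <- c("frame", "node", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("waveform file format error: columns must be frame,node,x_um,y_um",
         call. = FALSE)
  frames <- sort(unique(df$frame))
  if (!identical(as.integer(frames), seq_along(frames) - 1L))
    stop("waveform file format error: frames must be 0..n_frames-1",
         call. = FALSE)
  counts <- table(df$frame)
  if (length(unique(counts)) != 1) {
    off <- names(counts)[counts != stats::median(counts)]
    stop(sprintf("waveform file format error: frame %s has %s nodes while others have %d",
                 paste(off, collapse = ", "),
                 paste(counts[off], collapse = ", "),
                 stats::median(counts)), call. = FALSE)
  }
  nn <- unique(counts)[[1]]
  nf <- length(frames)
  df <- df[order(df$frame, df$node), ]
  pos <- array(0, dim = c(nf, nn, 2))
  pos[, , 1] <- matrix(df$x_um, nf, nn, byrow = TRUE)
  pos[, , 2] <- matrix(df$y_um, nf, nn, byrow = TRUE)
  w <- new_waveform(pos, period, anchor = pos[1, 1, ])
  validate_waveform(w)
  w
}
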