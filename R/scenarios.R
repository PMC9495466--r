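#' Placement of one cilium in a scenario
#'
#' @param anchor_x Anchor position along the wall, micrometres (strictly
#'   inside the metrics window).
#' @param tilt Mean-line tilt from the vertical, degrees.
#' @param phase_frames Integer cyclic frame offset of the beat.
#' @return An object of class `cilium_placement`.
#' @export
cilium_placement <- function(anchor_x, tilt, phase_frames = 0L) {
  if (abs(tilt) >= 90)
    stop("placement tilt must satisfy |tilt| < 90 degrees", call. = FALSE)
  structure(list(anchor_x = anchor_x, tilt = tilt,
                 phase_frames = as.integer(phase_frames)),
            class = "cilium_placement")
}

#' Define a full simulation scenario
#'
#' Bundles the fluid, the metrics window, the beat parameters, the cilium
#' placements and the run length into one validated description. The timestep
#' must tile the beat period exactly: `timestep * n_frames == period`.
#'
#' @param beat A [beat_params()] object (its `base_tilt` is overridden per
#'   placement).
#' @param placements List of [cilium_placement()] objects.
#' @param fluid A [fluid_properties()] object.
#' @param domain A [flow_domain()] object.
#' @param n_cycles Number of beat cycles to simulate (default 10).
#' @param timestep Timestep, seconds (default 0.001).
#' @param case_label Free-text label for reports.
#' @param epsilon Regularization length, micrometres; default is the node
#'   spacing `length / (n_nodes - 1)`.
#' @param wall A [wall_model()] object.
#' @param reference_depth Out-of-plane depth for mass-flow conversion,
#'   micrometres (default 1e6 = 1 m, the planar-solver convention).
#' @return An object of class `scenario`.
#' @export
scenario <- function(beat, placements, fluid = fluid_properties(),
                     domain = flow_domain(), n_cycles = 10L, timestep = 0.001,
                     case_label = "custom", epsilon = NULL,
                     wall = wall_model(), reference_depth = 1e6) {
  if (inherits(placements, "cilium_placement")) placements <- list(placements)
  if (n_cycles < 1) stop("n_cycles must be at least 1", call. = FALSE)
  period <- 1 / beat$frequency
  if (abs(timestep * beat$n_frames - period) > 1e-9)
    stop(sprintf("timestep (%g s) x n_frames (%d) must equal the beat period (%g s)",
                 timestep, beat$n_frames, period), call. = FALSE)
  for (p in placements) {
    if (p$anchor_x <= 0 || p$anchor_x >= domain$width)
      stop("placement anchor_x must lie strictly inside the domain width",
           call. = FALSE)
  }
  if (is.null(epsilon)) epsilon <- beat$length / (beat$n_nodes - 1)
  structure(list(beat = beat, placements = placements, fluid = fluid,
                 domain = domain, n_cycles = as.integer(n_cycles),
                 timestep = timestep, case_label = case_label,
                 epsilon = epsilon, wall = wall,
                 reference_depth = reference_depth),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d cilium/cilia, %d cycles x %d frames (dt %g s)\n",
              x$case_label, length(x$placements), x$n_cycles,
              x$beat$n_frames, x$timestep))
  for (p in x$placements)
    cat(sprintf("  cilium at x = %.2f um, tilt %.1f deg, phase %+d frames\n",
                p$anchor_x, p$tilt, p$phase_frames))
  invisible(x)
}

#' Build one of the five standard comparison cases
#'
#' Case 1: one cilium, tilt 30 deg. Case 2: one, 50 deg. Case 3: one, 60 deg.
#' Case 4: two cilia, both 60 deg, beating in phase. Case 5: two cilia, both
#' 60 deg, out of phase (half-cycle offset, realized as `floor(n_frames/2)`
#' frames: one cilium is at the end of its cycle while the other is at the
#' middle). A single cilium is anchored at `anchor_x`; a pair is centred in
#' the window and separated by `spacing`.
#'
#' @param case_id Integer in 1..5.
#' @param beat A [beat_params()] (tilt is set per case).
#' @param anchor_x Single-cilium anchor position, micrometres (default 15,
#'   the upstream third of the window, leaving room for the downstream flow).
#' @param spacing Two-cilium anchor separation, micrometres (default 5,
#'   about one cilium length).
#' @param ... Further arguments passed to [scenario()].
#' @return A `scenario`.
#' @export
build_case <- function(case_id, beat = beat_params(), anchor_x = 15,
                       spacing = 5, ...) {
  if (!case_id %in% 1:5) stop("unknown case id: must be 1..5", call. = FALSE)
  tilts <- c(30, 50, 60, 60, 60)
  tilt <- tilts[case_id]
  half <- as.integer(floor(beat$n_frames / 2))
  if (case_id <= 3) {
    pl <- list(cilium_placement(anchor_x, tilt))
    lab <- sprintf("Case %d: 1 cilium, tilt %g deg", case_id, tilt)
  } else {
    cx <- 25  # centre of the default 50 um window
    xs <- cx + c(-spacing / 2, spacing / 2)
    ph <- if (case_id == 4) c(0L, 0L) else c(0L, half)
    pl <- list(cilium_placement(xs[1], tilt, ph[1]),
               cilium_placement(xs[2], tilt, ph[2]))
    lab <- sprintf("Case %d: 2 cilia, tilt %g deg, %s", case_id, tilt,
                   if (case_id == 4) "in phase" else
                     sprintf("out of phase (%d frames)", half))
  }
  scenario(beat = beat, placements = pl, case_label = lab, ...)
}

# per-placement kinematics: positions and velocities for every frame,
# tilted, phase-shifted and translated to the anchor
placement_kinematics <- function(base, placement) {
  w <- apply_tilt(base, placement$tilt, warn_above = 90)
  w <- phase_shift(w, placement$phase_frames)
  w$positions[, , 1] <- w$positions[, , 1] + placement$anchor_x
  w$anchor <- w$anchor + c(placement$anchor_x, 0)
  nf <- n_frames(w)
  vel <- array(0, dim = dim(w$positions))
  for (f in seq_len(nf)) vel[f, , ] <- node_velocities(w, f)
  list(waveform = w, velocities = vel)
}

#' Run a scenario end to end
#'
#' For every timestep: place, tilt and phase-shift the beat waveforms, take
#' the prescribed node velocities, assemble and solve the instantaneous
#' Stokes system, and record the volumetric flux across the right boundary
#' line. The anchor nodes (on the wall) are excluded from the collocation
#' set: the wall already enforces zero velocity there and the wall-bounded
#' kernel vanishes identically at y = 0. The pipeline contains no source of
#' randomness, so identical configurations give bit-identical results.
#'
#' @param s A [scenario()].
#' @param fields Which end-of-cycle velocity fields to sample: `"last"`
#'   (default; in the quasi-steady solver every cycle is identical, so the
#'   last end-of-cycle snapshot represents them all), `"all"`, or `"none"`.
#' @param field_spacing Grid spacing for sampled fields, micrometres.
#' @param n_quad Quadrature nodes for the flux line integral.
#' @return A `scenario_result`: the [flux_series()], any sampled
#'   `velocity_field`s, a per-timestep diagnostics data frame (solver
#'   residual, reciprocal condition number, wall slip relative to the peak
#'   node speed, minimum inter-cilium distance) and a provenance block.
#' @export
run_scenario <- function(s, fields = c("last", "all", "none"),
                         field_spacing = 0.25, n_quad = 32) {
  fields <- match.arg(fields)
  base <- generate_beat(s$beat)
  kin <- lapply(s$placements, function(p) placement_kinematics(base, p))
  nf <- s$beat$n_frames
  nsteps <- nf * s$n_cycles
  npl <- length(kin)
  flux <- numeric(nsteps)
  diag_df <- data.frame(timestep = seq_len(nsteps) - 1L,
                        residual = NA_real_, rcond = NA_real_,
                        wall_slip = NA_real_, min_separation = NA_real_)
  snaps <- list()
  collided <- FALSE
  # cache one cycle of solves; later cycles repeat them identically
  cycle_cache <- vector("list", nf)
  for (t in seq_len(nsteps)) {
    f <- ((t - 1) %% nf) + 1
    if (is.null(cycle_cache[[f]])) {
      pts <- do.call(rbind, lapply(kin, function(k) k$waveform$positions[f, -1, ]))
      bv <- do.call(rbind, lapply(kin, function(k) k$velocities[f, -1, ]))
      pts[, 2] <- pmax(pts[, 2], 0)
      sys <- assemble_system(pts, s$epsilon, s$fluid, s$wall)
      forces <- solve_forces(sys, bv)
      peak <- max(sqrt(rowSums(bv^2)), .Machine$double.eps)
      slip <- wall_slip(sys, forces, c(0, s$domain$width), 25, peak)
      minsep <- NA_real_
      if (npl >= 2) {
        a <- kin[[1]]$waveform$positions[f, , ]
        b <- kin[[2]]$waveform$positions[f, , ]
        minsep <- sqrt(min(outer(a[, 1], b[, 1], "-")^2 +
                             outer(a[, 2], b[, 2], "-")^2))
        if (minsep < s$epsilon && !collided) {
          collided <- TRUE
          warning(sprintf("cilium-cilium separation %.3g um below epsilon at frame %d (logged, not prevented)",
                          minsep, f), call. = FALSE)
        }
      }
      cycle_cache[[f]] <- list(
        sys = sys, forces = forces,
        flux = flux_across_right_line(sys, forces, s$domain, n_quad),
        residual = attr(forces, "residual"), rcond = attr(forces, "rcond"),
        slip = slip, minsep = minsep)
    }
    cc <- cycle_cache[[f]]
    flux[t] <- cc$flux
    diag_df$residual[t] <- cc$residual
    diag_df$rcond[t] <- cc$rcond
    diag_df$wall_slip[t] <- cc$slip
    diag_df$min_separation[t] <- cc$minsep
    end_of_cycle <- (t %% nf) == 0
    if (end_of_cycle &&
        (fields == "all" || (fields == "last" && t == nsteps))) {
      snaps[[length(snaps) + 1]] <-
        sample_field(cc$sys, cc$forces, s$domain, field_spacing)
    }
  }
  fs <- flux_series(flux, s$timestep, nf, s$n_cycles,
                    reference_depth = s$reference_depth,
                    density = s$fluid$density)
  res <- list(flux = fs, fields = snaps, diagnostics = diag_df,
              scenario = s, provenance = provenance_block(s))
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  ag <- aggregate_flux(x$flux)
  cat(sprintf("Result of %s\n", x$scenario$case_label))
  cat(sprintf("  run-mean flux %.5g um^2/s = %.5g ug/s (depth %.3g um)\n",
              ag$run_mean, ag$run_mean_ug_s, x$flux$reference_depth))
  cat(sprintf("  max cycle-mean %.5g ug/s, instantaneous range [%.5g, %.5g] um^2/s\n",
              ag$max_cycle_mean_ug_s, ag$inst_min, ag$inst_max))
  cat(sprintf("  max wall slip %.3g of peak node speed, max residual %.3g\n",
              max(x$diagnostics$wall_slip), max(x$diagnostics$residual)))
  invisible(x)
}

provenance_block <- function(s) {
  cfg <- scenario_config_list(s)
  list(package = "ciliaflow",
       version = as.character(utils::packageVersion("ciliaflow")),
       solver = "quasi-steady regularized-Stokeslet boundary solver",
       wall = s$wall$representation,
       note = paste("open half-plane with exact no-slip floor; the",
                    "25 x 50 um rectangle is the metrics window, not a",
                    "closed pressure-boundary box"),
       reference_depth_um = s$reference_depth,
       config = cfg,
       config_hash = fnv1a_hash(deparse(cfg)))
}

#' Run the five-case comparison suite
#'
#' Runs the standard cases end to end and tabulates the pumping observables:
#' whole-run mean flux, maximum per-cycle mean, the mass-flow conversions,
#' and the instantaneous extremes.
#'
#' @param cases Integer vector of case ids (default 1:5).
#' @param beat Shared [beat_params()].
#' @param n_cycles,fields Passed to [scenario()] / [run_scenario()].
#' @param ... Further arguments to [build_case()].
#' @return A data frame with one row per case, with the full
#'   `scenario_result` objects attached as attribute `"results"`.
#' @export
run_case_suite <- function(cases = 1:5, beat = beat_params(), n_cycles = 10L,
                           fields = "none", ...) {
  results <- lapply(cases, function(id) {
    run_scenario(build_case(id, beat = beat, n_cycles = n_cycles, ...),
                 fields = fields)
  })
  rows <- lapply(seq_along(cases), function(i) {
    r <- results[[i]]
    ag <- aggregate_flux(r$flux)
    s <- r$scenario
    data.frame(case = cases[i],
               label = s$case_label,
               n_cilia = length(s$placements),
               tilt_deg = s$placements[[1]]$tilt,
               phase = if (length(s$placements) < 2) "" else
                 if (s$placements[[2]]$phase_frames == 0) "in phase" else "out of phase",
               mean_flux_um2_s = ag$run_mean,
               max_cycle_flux_um2_s = ag$max_cycle_mean,
               mean_massflow_ug_s = ag$run_mean_ug_s,
               max_massflow_ug_s = ag$max_cycle_mean_ug_s,
               inst_min_um2_s = ag$inst_min,
               inst_max_um2_s = ag$inst_max)
  })
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}

#' Read / write a scenario configuration (YAML)
#'
#' The configuration mirrors the [scenario()] fields; unspecified entries
#' take the package defaults.
#'
#' @param path YAML file path.
#' @param s A `scenario` (for writing).
#' @return `read_scenario_config` returns a `scenario`;
#'   `write_scenario_config` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  beat <- do.call(beat_params, cfg$beat %||% list())
  placements <- lapply(cfg$placements, function(p)
    cilium_placement(p$anchor_x, p$tilt, p$phase_frames %||% 0L))
  args <- list(beat = beat, placements = placements)
  if (!is.null(cfg$fluid)) args$fluid <- do.call(fluid_properties, cfg$fluid)
  if (!is.null(cfg$domain)) args$domain <- do.call(flow_domain, cfg$domain)
  for (nm in c("n_cycles", "timestep", "case_label", "epsilon",
               "reference_depth"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$wall)) args$wall <- do.call(wall_model, cfg$wall)
  do.call(scenario, args)
}

scenario_config_list <- function(s) {
  list(beat = unclass(s$beat),
       placements = lapply(s$placements, unclass),
       fluid = unclass(s$fluid),
       domain = unclass(s$domain),
       n_cycles = s$n_cycles, timestep = s$timestep,
       case_label = s$case_label, epsilon = s$epsilon,
       wall = unclass(s$wall)[c("representation", "slip_tolerance")],
       reference_depth = s$reference_depth)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(s, path) {
  yaml::write_yaml(scenario_config_list(s), path)
  invisible(path)
}

#' Write the provenance sidecar of a result
#'
#' @param result A `scenario_result`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(result, path) {
  jsonlite::write_json(result$provenance, path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a over a character vector; provenance fingerprint only.
# Kept in double arithmetic: the 32-bit product is split 16/16 so no
# intermediate exceeds 2^53.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi16 * p) %% 65536) * 65536 + lo16 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
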