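test_that("generated beats are inextensible, anchored, and tilted as requested", {
  w <- generate_beat(beat_params())
  al <- arc_lengths(w)
  expect_lt(max(abs(al - 4.75)) / 4.75, 0.01)
  expect_lt(max(abs(al - 4.75)), 1e-9)  # midpoint integration is exact
  expect_true(all(w$positions[, 1, 1] == w$anchor[1]))
  expect_true(all(w$positions[, 1, 2] == w$anchor[2]))

  # brute-force mean line: principal direction of pooled node displacements
  for (ang in c(30, 50, 60)) {
    wt <- suppressWarnings(apply_tilt(w, ang))
    D <- cbind(as.vector(wt$positions[, , 1]) - wt$anchor[1],
               as.vector(wt$positions[, , 2]) - wt$anchor[2])
    v <- eigen(crossprod(D), symmetric = TRUE)$vectors[, 1]
    if (v[2] < 0) v <- -v
    expect_lt(abs(atan2(v[1], v[2]) * 180 / pi - ang), 2)
    expect_equal(arc_lengths(wt), al, tolerance = 1e-12)
  }
})

test_that("invalid beat parameters are rejected naming the field", {
  expect_error(beat_params(length = -1), "length")
  expect_error(beat_params(n_nodes = 2), "n_nodes")
  expect_error(beat_params(n_frames = 3), "n_frames")
  expect_error(beat_params(amplitude = -0.1), "amplitude")
  expect_error(beat_params(asymmetry = 1.2), "asymmetry")
})

test_that("zero amplitude gives a static straight rod along the mean line", {
  w <- generate_beat(beat_params(amplitude = 0))
  for (f in 2:n_frames(w))
    expect_equal(w$positions[f, , ], w$positions[1, , ], tolerance = 1e-12)
  d <- w$positions[1, n_nodes(w), ] - w$anchor
  expect_equal(atan2(d[1], d[2]) * 180 / pi, 30, tolerance = 1e-6)
  expect_equal(sqrt(sum(d^2)), 4.75, tolerance = 1e-9)
})

test_that("zero asymmetry gives a time-reversible frame sequence", {
  w <- generate_beat(beat_params(asymmetry = 0))
  nf <- n_frames(w)
  best <- min(sapply(0:(nf - 1), function(off) {
    idx <- ((rev(seq_len(nf)) - 1 + off) %% nf) + 1
    max(abs(w$positions[idx, , ] - w$positions))
  }))
  expect_lt(best, 1e-9)

  # the default (asymmetric) beat is not reversible
  wd <- generate_beat(beat_params())
  worst <- min(sapply(0:(nf - 1), function(off) {
    idx <- ((rev(seq_len(nf)) - 1 + off) %% nf) + 1
    max(abs(wd$positions[idx, , ] - wd$positions))
  }))
  expect_gt(worst, 0.01)
})

test_that("tip excursion matches dense-time re-evaluation within 5%", {
  # independent oracle: the same closed-form tangent-angle model evaluated on
  # a 10x finer frame grid, written out from scratch
  p <- beat_params()
  oracle_shape <- function(n_t) {
    u <- (seq_len(n_t) - 1) / n_t
    ds <- p$length / (p$n_nodes - 1)
    smid <- (seq_len(p$n_nodes - 1) - 0.5) * ds
    ramp <- 0.3 + 0.7 * smid / p$length
    pos <- array(0, c(n_t, p$n_nodes, 2))
    for (f in seq_len(n_t)) {
      th <- p$amplitude * ramp * (cos(p$wavenumber * smid) * cos(2 * pi * u[f]) +
        p$asymmetry * sin(p$wavenumber * smid) * sin(2 * pi * u[f]))
      pos[f, , 1] <- c(0, cumsum(ds * sin(th)))
      pos[f, , 2] <- c(0, cumsum(ds * cos(th)))
    }
    # rotate so pooled principal direction sits at base_tilt
    D <- cbind(as.vector(pos[, , 1]), as.vector(pos[, , 2]))
    v <- eigen(crossprod(D), symmetric = TRUE)$vectors[, 1]
    if (v[2] < 0) v <- -v
    rot <- (p$base_tilt - atan2(v[1], v[2]) * 180 / pi) * pi / 180
    x2 <- cos(rot) * pos[, , 1] + sin(rot) * pos[, , 2]
    pos[, , 2] <- -sin(rot) * pos[, , 1] + cos(rot) * pos[, , 2]
    pos[, , 1] <- x2
    pos
  }
  tip_dense <- oracle_shape(330)[, p$n_nodes, 1]
  w <- generate_beat(p)
  tip <- w$positions[, p$n_nodes, 1]
  exc <- max(tip) - min(tip)
  exc_dense <- max(tip_dense) - min(tip_dense)
  expect_lt(abs(exc - exc_dense) / exc_dense, 0.05)
})

test_that("apply_tilt is an identity at the current angle and caps at 90", {
  w <- generate_beat(beat_params())
  w2 <- apply_tilt(w, mean_line_angle(w))
  expect_lt(max(abs(w2$positions - w$positions)), 1e-9)
  expect_error(apply_tilt(w, 90), "90")
  expect_error(apply_tilt(w, -95), "90")
  expect_warning(apply_tilt(w, 75), "collide")
})

test_that("phase_shift is a cyclic group action", {
  w <- generate_beat(beat_params())
  nf <- n_frames(w)
  expect_identical(phase_shift(w, 0)$positions, w$positions)
  expect_identical(phase_shift(w, nf)$positions, w$positions)
  expect_identical(phase_shift(w, 16)$positions[1, , ], w$positions[17, , ])
  set.seed(7)
  for (i in 1:5) {
    a <- sample(-40:40, 1); b <- sample(-40:40, 1)
    expect_identical(phase_shift(phase_shift(w, a), b)$positions,
                     phase_shift(w, (a + b) %% nf)$positions)
  }
})

test_that("node velocities are centered differences with a fixed anchor", {
  # static waveform: zero everywhere
  ws <- generate_beat(beat_params(amplitude = 0))
  expect_true(all(node_velocities(ws, 5) == 0))

  # positions linear in frame index: centered difference is the exact slope
  nf <- 12; dtw <- 0.5 / nf
  pos <- array(0, c(nf, 3, 2))
  for (f in seq_len(nf)) {
    pos[f, 2, ] <- c(1 + 0.2 * (f - 1), 1)
    pos[f, 3, ] <- c(2, 1 + 0.1 * (f - 1))
  }
  wl <- ciliaflow:::new_waveform(pos, period = 0.5, anchor = c(0, 0))
  for (f in 2:(nf - 1)) {
    v <- node_velocities(wl, f)
    expect_equal(v[2, 1], 0.2 / dtw, tolerance = 1e-12)
    expect_equal(v[3, 2], 0.1 / dtw, tolerance = 1e-12)
    expect_true(all(v[1, ] == 0))
  }

  # sinusoidal node: matches the analytic derivative to O(dt^2)
  nf <- 33; Tp <- 0.033
  t_f <- (seq_len(nf) - 1) / nf * Tp
  pos <- array(0, c(nf, 3, 2))
  pos[, 2, 1] <- sin(2 * pi * t_f / Tp)
  pos[, 2, 2] <- 1
  pos[, 3, ] <- matrix(c(0, 2), nf, 2, byrow = TRUE)
  wsin <- ciliaflow:::new_waveform(pos, period = Tp, anchor = c(0, 0))
  om <- 2 * pi / Tp
  dt <- Tp / nf
  bound <- om^3 * dt^2 / 6 * 1.05  # third-derivative remainder
  for (f in seq_len(nf)) {
    v <- node_velocities(wsin, f)[2, 1]
    expect_lt(abs(v - om * cos(om * t_f[f])), bound)
  }
})

test_that("waveform files round trip and malformed files are diagnosed", {
  w <- generate_beat(beat_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(w, path)
  w2 <- read_waveform(path)
  expect_identical(w2$positions, w$positions)
  expect_identical(w2$period, w$period)

  # frame 3 (0-based) with one node missing
  lines <- readLines(path)
  drop <- which(grepl("^3,19,", lines))
  writeLines(lines[-drop], path)
  expect_error(read_waveform(path), "frame 3")

  # anchor displaced in one frame
  write_waveform(w, path)
  lines <- readLines(path)
  i <- which(grepl("^5,0,", lines))
  parts <- strsplit(lines[i], ",")[[1]]
  parts[3] <- sprintf("%.17g", as.numeric(parts[3]) + 0.1)
  lines[i] <- paste(parts, collapse = ",")
  writeLines(lines, path)
  expect_error(read_waveform(path), "anchor")

  # missing metadata line
  write_waveform(w, path)
  writeLines(readLines(path)[-1], path)
  expect_error(read_waveform(path), "period_s")
})
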