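# shared fixtures built in code at test time

# a random well-separated point cloud above the wall
random_points <- function(n, seed, xlim = c(5, 45), ylim = c(0.5, 20)) {
  set.seed(seed)
  cbind(runif(n, xlim[1], xlim[2]), runif(n, ylim[1], ylim[2]))
}

# kinematics of one placed cilium: positions/velocities for every frame,
# anchor node dropped from the collocation set
placed_cilium <- function(tilt = 60, anchor_x = 15, beat = beat_params(),
                          phase = 0L) {
  w <- apply_tilt(generate_beat(beat), tilt, warn_above = 90)
  w <- phase_shift(w, phase)
  w$positions[, , 1] <- w$positions[, , 1] + anchor_x
  w$anchor[1] <- w$anchor[1] + anchor_x
  nf <- n_frames(w)
  vel <- array(0, dim = dim(w$positions))
  for (f in seq_len(nf)) vel[f, , ] <- node_velocities(w, f)
  list(w = w, vel = vel)
}

snapshot_system <- function(k, frame, epsilon = 0.25, ...) {
  pts <- k$w$positions[frame, -1, ]
  pts[, 2] <- pmax(pts[, 2], 0)
  sys <- assemble_system(pts, epsilon, ...)
  list(sys = sys, forces = solve_forces(sys, k$vel[frame, -1, ]),
       bv = k$vel[frame, -1, ])
}

# independent oracle: the wall-bounded kernel by central finite differences of
# the scalar stream potential G = F(r^2) - F(rho^2) + 4 y eta F'(rho^2)
numeric_wall_kernel <- function(x, y, xi, eta, eps, mu, h = 1e-5) {
  a <- eps^2
  Ffun <- function(s) (s + a) * log(s + a) / (16 * pi)
  Fp <- function(s) (log(s + a) + 1) / (16 * pi)
  G <- function(xx, yy, ee) {
    r2 <- (xx - xi)^2 + (yy - ee)^2
    rho2 <- (xx - xi)^2 + (yy + ee)^2
    Ffun(r2) - Ffun(rho2) + 4 * yy * ee * Fp(rho2)
  }
  dG_eta <- function(xx, yy) (G(xx, yy, eta + h) - G(xx, yy, eta - h)) / (2 * h)
  dG_X <- function(xx, yy) (G(xx + h, yy, eta) - G(xx - h, yy, eta)) / (2 * h)
  K11 <- (dG_eta(x, y + h) - dG_eta(x, y - h)) / (2 * h)
  K21 <- -(dG_eta(x + h, y) - dG_eta(x - h, y)) / (2 * h)
  K12 <- (dG_X(x, y + h) - dG_X(x, y - h)) / (2 * h)
  K22 <- -(dG_X(x + h, y) - dG_X(x - h, y)) / (2 * h)
  matrix(c(K11, K21, K12, K22), 2, 2) / mu
}
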