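test_that("mobility is symmetric, positive and dissipative for random systems", {
  for (seed in 1:20) {
    sys <- assemble_system(random_points(8, seed), 0.25)
    M <- sys$mobility
    expect_lt(max(abs(M - t(M))) / max(abs(M)), 1e-10)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-12 * max(ev))
    set.seed(seed + 1000)
    f <- matrix(rnorm(16), 8, 2)
    v <- matrix(M %*% c(f[, 1], f[, 2]), ncol = 2)
    expect_gte(sum(f * v), -1e-12 * sum(abs(f) * abs(v)))
  }
})

test_that("velocities scale inversely with viscosity and linearly with forces", {
  pts <- random_points(10, 42)
  s1 <- assemble_system(pts, 0.25, fluid_properties(viscosity = 1e-3))
  s2 <- assemble_system(pts, 0.25, fluid_properties(viscosity = 2e-3))
  expect_equal(s2$mobility, s1$mobility / 2, tolerance = 1e-14)
  set.seed(1)
  f <- matrix(rnorm(20), 10, 2)
  q <- cbind(runif(5, 5, 45), runif(5, 1, 20))
  expect_equal(evaluate_velocity(s1, 3 * f, q), 3 * evaluate_velocity(s1, f, q),
               tolerance = 1e-12)
})

test_that("the image system enforces no-slip on the wall exactly", {
  sys <- assemble_system(matrix(c(20, 3), 1), 0.25)
  f <- matrix(c(1, 0), 1)
  u_wall <- evaluate_velocity(sys, f, cbind(seq(0, 50, length.out = 50), 0))
  u_src <- evaluate_velocity(sys, f, matrix(c(20, 3), 1))
  expect_lt(max(sqrt(rowSums(u_wall^2))), 1e-8 * sqrt(sum(u_src^2)))
})

test_that("the kernel matches independent differentiation of its stream potential", {
  # oracle: central finite differences of the scalar potential, implemented
  # from scratch in the helper
  for (pt in list(c(11, 7), c(30, 1.5), c(22, 0.4))) {
    Ka <- ciliaflow:::kernel_matrix(matrix(pt, 1), matrix(c(20, 3), 1),
                                    0.25^2, "image-system", 1e-3)
    Kn <- numeric_wall_kernel(pt[1], pt[2], 20, 3, 0.25, 1e-3)
    expect_lt(max(abs(Ka - Kn)) / max(abs(Ka)), 2e-3)
  }
})

test_that("force solve round-trips and degenerate inputs behave", {
  sys <- assemble_system(random_points(20, 3), 0.25)
  set.seed(4)
  f <- matrix(rnorm(40), 20, 2)
  v <- matrix(sys$mobility %*% c(f[, 1], f[, 2]), ncol = 2)
  f2 <- solve_forces(sys, v)
  expect_lt(sqrt(sum((f2 - f)^2)) / sqrt(sum(f^2)), 1e-6)
  expect_lt(attr(f2, "residual"), 1e-8)

  f0 <- solve_forces(sys, matrix(0, 20, 2))
  expect_lt(max(abs(f0)), 1e-10)
})

test_that("a translating rod drags the fluid along; dissipation is positive", {
  xs <- seq(10, 20, length.out = 20)
  sys <- assemble_system(cbind(xs, 2), 0.25)
  fo <- solve_forces(sys, cbind(rep(1, 20), 0))
  # forces act on the fluid: their sum points with the motion, so the
  # reaction (the drag on the rod) opposes it
  expect_gt(sum(fo[, 1]), 0)
  expect_lt(-sum(fo[, 1]), 0)
  expect_gt(attr(fo, "dissipation"), 0)
})

test_that("evaluated flow is interpolation-consistent and incompressible", {
  k <- placed_cilium(tilt = 60)
  snap <- snapshot_system(k, 8)
  u_c <- evaluate_velocity(snap$sys, snap$forces, snap$sys$points)
  expect_lt(max(abs(u_c - snap$bv)) / max(abs(snap$bv)), 1e-6)

  set.seed(11)
  q <- cbind(runif(100, 2, 48), runif(100, 1, 23))
  keep <- apply(q, 1, function(p)
    min(sqrt((snap$sys$points[, 1] - p[1])^2 +
               (snap$sys$points[, 2] - p[2])^2)) >= 1)
  q <- q[keep, ]
  h <- 0.02  # small against the O(1 um) scale of the near field
  spd <- sqrt(rowSums(evaluate_velocity(snap$sys, snap$forces, q)^2))
  div <- sapply(seq_len(nrow(q)), function(i) {
    p <- q[i, ]
    ue <- evaluate_velocity(snap$sys, snap$forces,
                            rbind(p + c(h, 0), p - c(h, 0),
                                  p + c(0, h), p - c(0, h)))
    (ue[1, 1] - ue[2, 1]) / (2 * h) + (ue[3, 2] - ue[4, 2]) / (2 * h)
  })
  expect_lt(max(abs(div)) * 4.75 / max(spd), 1e-2)
})

test_that("the far field decays like a wall-bounded flow", {
  k <- placed_cilium(tilt = 60)
  snap <- snapshot_system(k, 8)
  sp <- sapply(c(10, 20, 40), function(h)
    sqrt(sum(evaluate_velocity(snap$sys, snap$forces, cbind(15, h))^2)))
  expect_true(all(diff(sp) < 0))
  expect_lt(sp[3], sp[1] / 4)
})

test_that("invalid geometries are rejected", {
  expect_error(assemble_system(rbind(c(5, 1), c(6, -0.5)), 0.25), "wall")
  expect_error(assemble_system(rbind(c(5, 1), c(5, 1.001)), 0.25),
               "conditioning")
  sys <- assemble_system(matrix(c(20, 3), 1), 0.25)
  expect_error(evaluate_velocity(sys, matrix(c(1, 0), 1),
                                 matrix(c(10, -1), 1)), "wall")
  expect_error(wall_model(slip_tolerance = 0.2), "slip_tolerance")
})

test_that("the collocation-strip mode reproduces the image-system pumping", {
  k <- placed_cilium(tilt = 60)
  q_img <- numeric(6); q_str <- numeric(6)
  frames <- c(1, 7, 13, 19, 25, 31)
  for (i in seq_along(frames)) {
    si <- snapshot_system(k, frames[i])
    ss <- snapshot_system(k, frames[i],
                          wall = wall_model("collocation-strip", extent = 200))
    q_img[i] <- flux_across_right_line(si$sys, si$forces)
    q_str[i] <- flux_across_right_line(ss$sys, ss$forces)
  }
  expect_lt(abs(mean(q_str) - mean(q_img)) / abs(mean(q_img)), 0.05)
})
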