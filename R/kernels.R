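#' @title Regularized 2D Stokeslet kernels
#' @name kernels
#' @description Low-level velocity kernels for planar creeping flow. Two forms
#'   are provided: the free-space regularized Stokeslet, and a wall-bounded
#'   kernel whose image system satisfies the no-slip condition on y = 0
#'   exactly. Both derive from the blob
#'   \eqn{\phi_\varepsilon(r) = 2\varepsilon^4/\pi(r^2+\varepsilon^2)^3}
#'   through the biharmonic potential
#'   \eqn{F(s) = (s+\varepsilon^2)\log(s+\varepsilon^2)/16\pi}, \eqn{s = r^2}.
#'   The wall-bounded kernel is built from the clamped half-plane Green's
#'   function \eqn{G = F(r^2) - F(\rho^2) + 4y\eta F'(\rho^2)} (\eqn{\rho} the
#'   distance to the image point), which vanishes together with its normal
#'   derivative on the wall; velocities are perpendicular gradients of stream
#'   functions, so the field is exactly divergence-free and the kernel exactly
#'   reciprocal.
#'
#'   Units: lengths in micrometres, viscosity in Pa s, forces as line densities
#'   in pN per micrometre of depth, velocities in micrometres per second.
NULL

# Four m x n kernel blocks K[[ab]] such that u_a(field i) receives
# K[[ab]][i, j] * f_b(source j) / mu.  Expressions are machine-generated from
# the symbolically verified clamped half-plane stream function (see vignette).
wall_kernel_blocks <- function(xf, yf, xs, ys, eps2) {
  m <- length(xf); n <- length(xs)
  X   <- outer(xf, xs, "-")
  y   <- matrix(yf, m, n)
  eta <- matrix(ys, m, n, byrow = TRUE)
  a <- eps2

  t0 <- eta + y
  t1 <- t0^2
  t2 <- eta - y
  t3 <- t2^2
  t4 <- X^2
  t5 <- a + t4
  t6 <- t3 + t5                    # r^2 + eps^2
  t7 <- eta * t6
  t8 <- t7 * y
  t9 <- t1 + t5                    # rho^2 + eps^2
  t10 <- t9^2
  t11 <- 0.25 * t10
  t13 <- 2 * eta * y
  t14 <- t0 * y
  t15 <- t6 * t9
  t16 <- 0.25 * t15
  t17 <- 0.125 * t10 * t6 * (log(t6) - log(t9))
  t18 <- 1 / (pi * t10 * t6)
  t19 <- t10 * t2
  t20 <- 4 * t14 * t7
  t21 <- t15 * t2
  t22 <- 0.25 * X * t18

  K11 <- -t18 * (t1 * t8 + t11 * t3 - t16 * (2 * eta * t0 - t1 + t13 + 2 * t14) + t17)
  K12 <- -t22 * (t19 + t20 - t21)
  K21 <- t22 * (-t19 + t20 + t21)
  K22 <- t18 * (-t11 * t4 + t16 * (t4 - t13) - t17 + t4 * t8)
  list(K11 = K11, K12 = K12, K21 = K21, K22 = K22)
}

# Free-space regularized Stokeslet: S = (1/4pi)[-delta_ij A(s) + d_i d_j/(s+a)],
# A(s) = log(s+a)/2 + 1/2 + s/(s+a).
free_kernel_blocks <- function(xf, yf, xs, ys, eps2) {
  m <- length(xf); n <- length(xs)
  dx <- outer(xf, xs, "-")
  dy <- outer(yf, ys, "-")
  s <- dx^2 + dy^2
  sa <- s + eps2
  A <- 0.5 * log(sa) + 0.5 + s / sa
  c4 <- 1 / (4 * pi)
  list(K11 = c4 * (-A + dx * dx / sa),
       K12 = c4 * (dx * dy / sa),
       K21 = c4 * (dx * dy / sa),
       K22 = c4 * (-A + dy * dy / sa))
}

kernel_blocks <- function(xf, yf, xs, ys, eps2,
                          mode = c("image-system", "free-space")) {
  mode <- match.arg(mode)
  if (mode == "image-system") wall_kernel_blocks(xf, yf, xs, ys, eps2)
  else free_kernel_blocks(xf, yf, xs, ys, eps2)
}

# Assemble the (2m x 2n) velocity map [u1; u2] = K %*% [f1; f2] / mu
kernel_matrix <- function(field, source, eps2, mode, mu) {
  B <- kernel_blocks(field[, 1], field[, 2], source[, 1], source[, 2],
                     eps2, mode)
  rbind(cbind(B$K11, B$K12), cbind(B$K21, B$K22)) / mu
}
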