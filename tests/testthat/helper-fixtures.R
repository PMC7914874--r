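# Shared fixtures and independent oracle helpers.

# small random recording (valid) for round-trip / property tests; values in
# [0, 1) so a 9-significant-digit CSV round trip is exact to 1e-8 relative.
random_recording <- function(n = 20, k = 4, labeled = FALSE, seed = 1) {
  withr::with_seed(seed, {
    quat <- matrix(rnorm(n * 4), ncol = 4)
    quat <- quat / sqrt(rowSums(quat^2))
    gait_recording(
      t = cumsum(runif(n, 0.01, 0.05)),
      md = matrix(runif(n * k), ncol = k),
      quat = quat,
      omega = matrix(runif(n * 3, -1, 1), ncol = 3),
      kind = "walk",
      labels = if (labeled) sample(phase_levels(), n, replace = TRUE) else NULL
    )
  })
}

# a fixed tiny model for detection arithmetic
toy_model <- function(w = c(1, -1), b = 0) {
  structure(list(w = w, b = b, channel_count = length(w),
                 condition = NA_integer_),
            class = "trained_model")
}

# reduced-size simulation for fast end-to-end tests (study-condition values
# for stance fraction, cadence, rate; fewer cycles where full scale is not
# the point)
small_sim <- function(seed = 0, n_cycles = 10, ...) {
  sim_config(seed = seed, n_cycles = n_cycles, ...)
}

# -- quaternion oracle helpers (independent of the package's formulas) -------

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

# ZYX (yaw-pitch-roll) Euler angles -> quaternion
quat_from_euler <- function(phi, theta, psi) {
  qx <- c(cos(phi / 2), sin(phi / 2), 0, 0)
  qy <- c(cos(theta / 2), 0, sin(theta / 2), 0)
  qz <- c(cos(psi / 2), 0, 0, sin(psi / 2))
  quat_mult(quat_mult(qz, qy), qx)
}

# quaternion -> rotation matrix (body to world), standard formula
quat_to_rotmat <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2
  ), nrow = 3, byrow = TRUE)
}

# rotation matrix -> ZYX Euler extraction (the matrix-based oracle path)
rotmat_to_euler <- function(R) {
  list(phi = atan2(R[3, 2], R[3, 3]),
       theta = -asin(max(-1, min(1, R[3, 1]))),
       psi = atan2(R[2, 1], R[1, 1]))
}

# body angular velocity from a quaternion trajectory by central differences:
# omega_body = 2 * vec(conj(q) x dq/dt)
body_omega_from_quats <- function(quats, dt) {
  n <- nrow(quats)
  t(vapply(2:(n - 1), function(i) {
    dq <- (quats[i + 1, ] - quats[i - 1, ]) / (2 * dt)
    2 * quat_mult(quat_conj(quats[i, ]), dq)[2:4]
  }, numeric(3)))
}
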