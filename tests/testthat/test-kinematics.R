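test_that("quaternion to Euler handles canonical rotations", {
  e <- quaternion_to_euler(c(1, 0, 0, 0))
  expect_equal(unlist(e), c(phi = 0, theta = 0, psi = 0))

  # quarter-turn about x: roll pi/2
  e <- quaternion_to_euler(c(sqrt(2) / 2, sqrt(2) / 2, 0, 0))
  expect_equal(e$phi, pi / 2, tolerance = 1e-12)
  expect_equal(e$theta, 0, tolerance = 1e-12)
  expect_equal(e$psi, 0, tolerance = 1e-12)
})

test_that("quaternion to Euler matches the rotation-matrix oracle", {
  withr::with_seed(11, {
    count <- 0
    while (count < 1000) {
      q <- rnorm(4)
      q <- q / sqrt(sum(q^2))
      e <- quaternion_to_euler(q)
      if (abs(e$theta) >= 80 * pi / 180) next   # stay away from gimbal lock
      count <- count + 1
      o <- rotmat_to_euler(quat_to_rotmat(q))
      expect_equal(e$phi, o$phi, tolerance = 1e-9)
      expect_equal(e$theta, o$theta, tolerance = 1e-9)
      expect_equal(e$psi, o$psi, tolerance = 1e-9)
    }
  })
})

test_that("asin clamping makes pitch extraction total on near-unit input", {
  # rounding can push |2(q0 q2 - q1 q3)| microscopically above 1
  q <- c(sqrt(2) / 2, 0, sqrt(2) / 2 * (1 + 1e-16), 0)
  e <- quaternion_to_euler(q)
  expect_equal(e$theta, pi / 2, tolerance = 1e-6)
  expect_false(is.nan(e$theta))
})

test_that("spatial rate transform reproduces its defining arithmetic", {
  # at zero roll/pitch the transform rows read off directly
  r <- spatial_angular_velocity(list(phi = 0, theta = 0), c(1, 2, 3))
  expect_equal(unlist(r), c(phi_dot = 1, theta_dot = 2, psi_dot = -3))
  expect_equal(
    unlist(spatial_angular_velocity(list(phi = 0, theta = 0), c(0, 0, 0))),
    c(phi_dot = 0, theta_dot = 0, psi_dot = 0))

  # the standard-matrix variant flips only the wz contribution to yaw rate
  r_std <- spatial_angular_velocity(list(phi = 0, theta = 0), c(1, 2, 3),
                                    standard_rate_matrix = TRUE)
  expect_equal(r_std$psi_dot, 3)
  expect_equal(r_std$phi_dot, r$phi_dot)
  expect_equal(r_std$theta_dot, r$theta_dot)
})

test_that("spatial rate transform is linear in the body rates", {
  withr::with_seed(5, {
    for (i in 1:50) {
      e <- list(phi = runif(1, -1, 1), theta = runif(1, -1, 1))
      w1 <- rnorm(3); w2 <- rnorm(3); a <- rnorm(1); b <- rnorm(1)
      lhs <- spatial_angular_velocity(e, a * w1 + b * w2)
      r1 <- spatial_angular_velocity(e, w1)
      r2 <- spatial_angular_velocity(e, w2)
      for (comp in names(lhs)) {
        expect_equal(lhs[[comp]], a * r1[[comp]] + b * r2[[comp]],
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("gimbal-singular pitch raises an error", {
  expect_error(
    spatial_angular_velocity(list(phi = 0, theta = pi / 2), c(0, 1, 0)),
    "gimbal")
})

test_that("pitch rate matches finite differences on a pure-pitch trajectory", {
  # theta(t) = 0.5 sin(2 pi 0.8 t), phi = psi = 0, sampled at 1 kHz.
  # Body rates come independently from the quaternion derivative.
  dt <- 1e-3
  t <- seq(0, 1, by = dt)
  theta <- 0.5 * sin(2 * pi * 0.8 * t)
  quats <- cbind(cos(theta / 2), 0, sin(theta / 2), 0)
  omega <- body_omega_from_quats(quats, dt)
  inner <- 2:(length(t) - 1)
  theta_extracted <- vapply(inner, function(i) {
    quaternion_to_euler(quats[i, ])$theta
  }, numeric(1))
  theta_dot_fd <- (theta[inner + 1] - theta[inner - 1]) / (2 * dt)
  theta_dot_pkg <- vapply(seq_along(inner), function(j) {
    i <- inner[j]
    e <- quaternion_to_euler(quats[i, ])
    spatial_angular_velocity(e, omega[j, ])$theta_dot
  }, numeric(1))
  expect_equal(theta_extracted, theta[inner], tolerance = 1e-9)
  expect_lt(max(abs(theta_dot_pkg - theta_dot_fd)), 1e-3)
})

test_that("standard-matrix rates match finite differences on a 3-axis trajectory", {
  dt <- 1e-3
  t <- seq(0, 1, by = dt)
  phi <- 0.3 * sin(t); theta <- 0.4 * sin(0.7 * t); psi <- 0.5 * sin(1.3 * t)
  quats <- t(mapply(quat_from_euler, phi, theta, psi))
  omega <- body_omega_from_quats(quats, dt)
  inner <- 2:(length(t) - 1)
  fd <- function(x) (x[inner + 1] - x[inner - 1]) / (2 * dt)
  rates <- t(vapply(seq_along(inner), function(j) {
    i <- inner[j]
    e <- quaternion_to_euler(quats[i, ])
    unlist(spatial_angular_velocity(e, omega[j, ],
                                    standard_rate_matrix = TRUE))
  }, numeric(3)))
  expect_lt(max(abs(rates[, "phi_dot"] - fd(phi))), 1e-3)
  expect_lt(max(abs(rates[, "theta_dot"] - fd(theta))), 1e-3)
  expect_lt(max(abs(rates[, "psi_dot"] - fd(psi))), 1e-3)
})

test_that("anterior rate selects, sign-flips and rectifies as configured", {
  rates <- list(phi_dot = 0.1, theta_dot = 0.5, psi_dot = -0.3)
  expect_equal(anterior_rate(rates, detection_config()), 0.5)
  expect_equal(anterior_rate(rates, detection_config(upside_down = TRUE)),
               -0.5)
  expect_equal(
    anterior_rate(rates, detection_config(gy_component = "psi_dot")), -0.3)
  expect_equal(
    anterior_rate(rates, detection_config(gy_component = "psi_dot",
                                          absolute_gy = TRUE)), 0.3)
})

test_that("reliability guard trips on extreme pitch and is monotone", {
  expect_true(reliability_guard(rep(0, 10)))
  expect_false(reliability_guard(c(rep(0, 9), atan(60))))
  expect_true(reliability_guard(c(rep(0, 9), atan(60)), limit = Inf))
  expect_error(reliability_guard(numeric(0)), "nonempty")

  # enlarging the series can only flip permitted -> forbidden
  withr::with_seed(9, {
    theta <- runif(50, -1.5, 1.5)
    ok <- vapply(seq_along(theta), function(n) {
      reliability_guard(theta[seq_len(n)])
    }, logical(1))
    expect_true(all(diff(as.integer(ok)) <= 0))
  })
})
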