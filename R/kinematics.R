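# Orientation and angular-velocity kinematics for the shank-worn sensor.
#
# The device reports a unit quaternion (scalar-first) and body-frame gyroscope
# rates. The detector needs the spatial (world-frame) pitch rate of the shank
# — the component tied to anterior leg motion — so we convert quaternion ->
# ZYX Euler angles, then body rates -> Euler-angle rates.

#' Quaternion to Euler angles (roll, pitch, yaw)
#'
#' Scalar-first convention (q0 = w). Roll `phi = atan2(2(q0 q1 + q2 q3),
#' q0^2 - q1^2 - q2^2 + q3^2)`, pitch `theta = asin(2(q0 q2 - q1 q3))` with
#' the asin argument clamped to \[-1, 1\], yaw `psi = atan2(2(q0 q3 + q1 q2),
#' q0^2 + q1^2 - q2^2 - q3^2)`.
#'
#' @param quat Numeric length-4 vector or n x 4 matrix, unit quaternion(s).
#' @return A list (or, for matrix input, a 3-column matrix) with components
#'   `phi`, `theta`, `psi` in radians; `theta` lies in \[-pi/2, pi/2\].
#' @export
quaternion_to_euler <- function(quat) {
  if (is.matrix(quat)) {
    q0 <- quat[, 1]; q1 <- quat[, 2]; q2 <- quat[, 3]; q3 <- quat[, 4]
  } else {
    stopifnot(length(quat) == 4L)
    q0 <- quat[1]; q1 <- quat[2]; q2 <- quat[3]; q3 <- quat[4]
  }
  phi <- atan2(2 * (q0 * q1 + q2 * q3), q0^2 - q1^2 - q2^2 + q3^2)
  s <- pmin(pmax(2 * (q0 * q2 - q1 * q3), -1), 1)
  theta <- asin(s)
  psi <- atan2(2 * (q0 * q3 + q1 * q2), q0^2 + q1^2 - q2^2 - q3^2)
  if (is.matrix(quat)) {
    cbind(phi = phi, theta = theta, psi = psi)
  } else {
    list(phi = phi, theta = theta, psi = psi)
  }
}

#' Euler-rate transform matrix
#'
#' Maps body-frame gyroscope rates to Euler-angle rates. The default form is
#' the one this detector was designed around, whose third row is
#' `(0, sin(phi) sec(theta), -cos(phi) sec(theta))`; the textbook ZYX form
#' (third row `(0, sin(phi) sec(theta), +cos(phi) sec(theta))`, second row
#' unchanged) is available via `standard = TRUE`. The two differ only in the
#' sign of the yaw-rate contribution of `wz`, which the default pitch-rate
#' gating never uses.
#'
#' @param phi,theta Roll and pitch in radians.
#' @param standard Use the textbook ZYX rate matrix instead.
#' @return 3 x 3 numeric matrix.
#' @keywords internal
euler_rate_matrix <- function(phi, theta, standard = FALSE) {
  sec_t <- 1 / cos(theta)
  third <- if (standard) {
    c(0, sin(phi) * sec_t, cos(phi) * sec_t)
  } else {
    c(0, sin(phi) * sec_t, -cos(phi) * sec_t)
  }
  rbind(
    c(1, sin(phi) * tan(theta), cos(phi) * tan(theta)),
    c(0, cos(phi), -sin(phi)),
    third
  )
}

#' Body-frame angular velocity to spatial Euler-angle rates
#'
#' Applies the Euler-rate transform at the current roll/pitch. Near gimbal
#' lock (|cos(theta)| <= `tol`) the transform is singular and an error is
#' raised; [detect_sequence()] falls back to the unadjusted probability for
#' such frames.
#'
#' @param euler List or vector with `phi`, `theta` (radians); `psi` unused.
#' @param omega_body Numeric length-3 body rates (wx, wy, wz), rad/s.
#' @param standard_rate_matrix Use the textbook ZYX rate matrix.
#' @param tol Gimbal-singularity tolerance on |cos(theta)|.
#' @return List with `phi_dot`, `theta_dot`, `psi_dot` in rad/s.
#' @export
spatial_angular_velocity <- function(euler, omega_body,
                                     standard_rate_matrix = FALSE,
                                     tol = 1e-6) {
  phi <- euler[["phi"]]; theta <- euler[["theta"]]
  if (abs(cos(theta)) <= tol) {
    stop("gimbal singularity: |cos(theta)| <= ", tol, " at theta = ", theta)
  }
  r <- euler_rate_matrix(phi, theta, standard = standard_rate_matrix) %*%
    as.numeric(omega_body)
  list(phi_dot = r[1L], theta_dot = r[2L], psi_dot = r[3L])
}

#' Anterior-direction angular velocity gy
#'
#' Selects the spatial-rate component tied to anterior (forward) leg motion —
#' by default the pitch rate `theta_dot`, the sagittal-plane rotation of a
#' shank-mounted band — and corrects its sign when the band was worn upside
#' down. With `absolute_gy = TRUE` the magnitude is used instead of the
#' signed rate.
#'
#' @param rates List with `phi_dot`, `theta_dot`, `psi_dot` (rad/s).
#' @param config A [detection_config()].
#' @return gy in rad/s.
#' @export
anterior_rate <- function(rates, config = detection_config()) {
  gy <- rates[[config$gy_component]]
  if (config$upside_down) gy <- -gy
  if (config$absolute_gy) gy <- abs(gy)
  gy
}

#' Orientation-reliability guard for the probability adjustment
#'
#' Large pitch makes the rate transform (its sec(theta) terms) numerically
#' fragile, so the probability adjustment is disabled for a whole recording
#' when the maximum |tan(theta)| over its frames exceeds `limit` (default
#' 50).
#'
#' @param theta Numeric vector of per-frame pitch angles (radians).
#' @param limit Dimensionless guard threshold on |tan(theta)|.
#' @return `TRUE` if the adjustment may be applied, `FALSE` otherwise.
#' @export
reliability_guard <- function(theta, limit = 50) {
  if (length(theta) == 0L) stop("reliability_guard needs a nonempty series")
  stopifnot(limit > 0)
  max(abs(tan(theta))) <= limit
}

# internal: full per-frame kinematics of a recording. Returns a data.frame
# with euler angles and gy; frames at gimbal singularity get gy = NA.
recording_kinematics <- function(rec, config = detection_config()) {
  eul <- quaternion_to_euler(rec$quat)
  n <- n_frames(rec)
  gy <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rates <- tryCatch(
      spatial_angular_velocity(
        list(phi = eul[i, "phi"], theta = eul[i, "theta"]),
        rec$omega[i, ],
        standard_rate_matrix = config$standard_rate_matrix
      ),
      error = function(e) NULL
    )
    if (!is.null(rates)) gy[i] <- anterior_rate(rates, config)
  }
  data.frame(phi = eul[, "phi"], theta = eul[, "theta"], psi = eul[, "psi"],
             gy = gy)
}
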