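# Per-frame stance/swing classification: logistic probability of the swing
# phase from the muscle-deformation vector, optionally shifted on the logit
# scale by +/- a according to the anterior angular velocity gy:
#
#   gy < th1        -> p = sigmoid(z + a)   (leg moving forward: swing-like)
#   gy > th2        -> p = sigmoid(z - a)   (not moving forward: stance-like)
#   th1 <= gy <= th2 -> p = sigmoid(z)      (dead zone: no adjustment)
#
# with z = w . md + b. A frame is classified swing iff p > 0.5.

#' Detection configuration
#'
#' @param a Logit adjustment magnitude, dimensionless, >= 0. Default 8, the
#'   value that maximized accuracy over the 0-10 range in the original
#'   tuning.
#' @param th1,th2 Gating thresholds on gy in rad/s, `th1 < th2`. Below
#'   `th1` the leg is taken to move forward; above `th2` it is not; between
#'   them no adjustment is applied. Defaults 0.6 and 0.7.
#' @param tan_theta_limit Reliability guard: if the maximum |tan(pitch)|
#'   over a recording exceeds this, the adjustment is disabled for the whole
#'   recording. Default 50.
#' @param upside_down Flip the sign of gy (band worn upside down).
#' @param gy_component Which spatial rate is the anterior rate:
#'   `"theta_dot"` (pitch, default), `"phi_dot"` or `"psi_dot"`.
#' @param standard_rate_matrix Use the textbook ZYX Euler-rate matrix (see
#'   [spatial_angular_velocity()]).
#' @param absolute_gy Gate on |gy| instead of signed gy.
#' @param majority_width Odd window width for an optional majority filter on
#'   the output phase sequence; 1 (default) disables smoothing.
#' @return A `detection_config` list.
#' @export
detection_config <- function(a = 8, th1 = 0.6, th2 = 0.7,
                             tan_theta_limit = 50, upside_down = FALSE,
                             gy_component = c("theta_dot", "phi_dot", "psi_dot"),
                             standard_rate_matrix = FALSE,
                             absolute_gy = FALSE, majority_width = 1L) {
  gy_component <- match.arg(gy_component)
  if (!(is.numeric(a) && a >= 0)) stop("a must be >= 0")
  if (!(th1 < th2)) stop("th1 must be < th2")
  if (!(tan_theta_limit > 0)) stop("tan_theta_limit must be > 0")
  if (majority_width %% 2L != 1L) stop("majority_width must be odd")
  structure(
    list(a = a, th1 = th1, th2 = th2, tan_theta_limit = tan_theta_limit,
         upside_down = upside_down, gy_component = gy_component,
         standard_rate_matrix = standard_rate_matrix,
         absolute_gy = absolute_gy, majority_width = as.integer(majority_width)),
    class = "detection_config"
  )
}

# overflow-safe sigmoid on the logit scale
sigmoid <- function(z) plogis(z)

#' Swing-phase probability of one muscle-deformation vector
#'
#' `p = 1 / (1 + exp(-(w . md + b)))`, evaluated overflow-safely. `p = 0.5`
#' exactly on the decision boundary `w . md + b = 0`.
#'
#' @param model A `trained_model` from [fit_lr()].
#' @param md Numeric channel vector (or matrix of rows).
#' @return Probability (vector) in (0, 1).
#' @export
lr_probability <- function(model, md) {
  if (is.matrix(md)) {
    if (ncol(md) != model$channel_count) {
      stop("md has ", ncol(md), " channels; model expects ", model$channel_count)
    }
    sigmoid(drop(md %*% model$w) + model$b)
  } else {
    if (length(md) != model$channel_count) {
      stop("md has ", length(md), " channels; model expects ", model$channel_count)
    }
    sigmoid(sum(model$w * md) + model$b)
  }
}

#' Gated adjusted swing probability of one frame
#'
#' Shifts the logit by `+a` when `gy < th1`, by `-a` when `gy > th2`, and
#' not at all in the dead zone or when `reliable = FALSE` (orientation
#' guard failed) or gy is not finite.
#'
#' @param model A `trained_model`.
#' @param md Channel vector.
#' @param gy Anterior angular velocity, rad/s (may be `NA` for
#'   gimbal-singular frames).
#' @param config A [detection_config()].
#' @param reliable Result of [reliability_guard()] for the recording.
#' @return List: `p_swing`, `phase`, `branch` (`"plus_a"`, `"minus_a"` or
#'   `"none"`).
#' @export
adjusted_probability <- function(model, md, gy, config = detection_config(),
                                 reliable = TRUE) {
  z <- sum(model$w * md) + model$b
  branch <- "none"
  if (reliable && is.finite(gy)) {
    if (gy < config$th1) {
      z <- z + config$a
      branch <- "plus_a"
    } else if (gy > config$th2) {
      z <- z - config$a
      branch <- "minus_a"
    }
  }
  p <- sigmoid(z)
  list(p_swing = p, phase = classify(p), branch = branch)
}

#' Classify a swing probability into a phase label
#'
#' `swing` iff `p > 0.5`; exactly 0.5 ties to `stance`, the majority phase.
#'
#' @param p Probability (vectorized), must lie in \[0, 1\].
#' @return Character vector of `"stance"` / `"swing"`.
#' @export
classify <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  ifelse(p > 0.5, "swing", "stance")
}

# internal: odd-window majority filter on a stance/swing character vector
majority_filter <- function(phase, width) {
  if (width <= 1L || length(phase) == 0L) return(phase)
  half <- (width - 1L) %/% 2L
  n <- length(phase)
  sw <- as.integer(phase == "swing")
  out <- phase
  for (i in seq_len(n)) {
    idx <- max(1L, i - half):min(n, i + half)
    out[i] <- if (sum(sw[idx]) * 2L > length(idx)) "swing" else "stance"
  }
  out
}

#' Detect the phase sequence of a walking recording
#'
#' Runs the full per-frame pipeline: quaternion to Euler angles, body rates
#' to spatial rates, anterior rate gy, gated adjusted probability, and the
#' p > 0.5 decision. The orientation reliability guard is evaluated once
#' over the whole recording; if it fails, every frame uses the plain
#' logistic probability. Frames at the gimbal singularity fall back to the
#' unadjusted probability.
#'
#' @param walk A walking `gait_recording`.
#' @param model A `trained_model` with matching channel count.
#' @param config A [detection_config()].
#' @return A data.frame with one row per frame: `t`, `gy`, `p_swing`,
#'   `phase`, `branch`; attribute `reliable` records the guard outcome.
#' @export
detect_sequence <- function(walk, model, config = detection_config()) {
  stopifnot(inherits(walk, "gait_recording"), inherits(model, "trained_model"))
  if (walk$kind != "walk") stop("detect_sequence expects a walking recording")
  if (n_channels(walk) != model$channel_count) {
    stop("recording has ", n_channels(walk), " channels; model expects ",
         model$channel_count)
  }
  kin <- recording_kinematics(walk, config)
  reliable <- reliability_guard(kin$theta, limit = config$tan_theta_limit)
  n <- n_frames(walk)
  p <- numeric(n)
  phase <- character(n)
  branch <- character(n)
  for (i in seq_len(n)) {
    res <- adjusted_probability(model, walk$md[i, ], kin$gy[i], config,
                                reliable = reliable)
    p[i] <- res$p_swing
    phase[i] <- res$phase
    branch[i] <- res$branch
  }
  phase <- majority_filter(phase, config$majority_width)
  out <- data.frame(t = walk$t, gy = kin$gy, p_swing = p, phase = phase,
                    branch = branch)
  attr(out, "reliable") <- reliable
  out
}
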