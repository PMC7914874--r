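# Synthetic gait generator. Emulates what the detector assumes about real
# data: (i) each standing posture has a characteristic muscle-deformation
# prototype vector and standing samples scatter around it with Gaussian
# channel noise; (ii) walking muscle deformation traverses the stance
# prototypes (heel contact -> foot flat -> single support -> back foot flat
# -> heel off) and then the swing prototypes (back foot off -> front foot
# off) once per gait cycle; (iii) the shank pitch rate gy is high in
# mid-stance and low (negative) in swing, matching the gating convention
# that forward leg motion means gy below th1; (iv) a stance:swing sample
# ratio of 1.5 at the default stance fraction 0.6.

#' Default posture prototype matrix
#'
#' Prototypes are built from a smooth per-channel loading profile scaled by
#' a posture-specific weight-bearing load (high for stance postures, where
#' the calf bulges under body weight; low for the two foot-off postures)
#' plus a small posture-specific shape term that keeps all seven prototypes
#' pairwise distinct. Units are arbitrary sensor counts around a baseline
#' of 100.
#'
#' @param channel_count Number of muscle channels (default 11).
#' @return 7 x `channel_count` matrix with posture rownames.
#' @export
default_prototypes <- function(channel_count = 11) {
  k <- seq_len(channel_count)
  bell <- exp(-((k - (channel_count + 1) / 2) / (channel_count / 4))^2)
  loads <- c(back_foot_flat = 0.85, back_heel_off = 0.95, back_foot_off = 0.15,
             front_foot_flat = 0.90, front_heel_contact = 0.75,
             front_foot_off = 0.10, single_support = 1.00)
  postures <- posture_labels()
  proto <- t(vapply(seq_along(postures), function(i) {
    p <- postures[i]
    shape <- sin(2 * pi * k / channel_count + 2 * pi * i / 7)
    100 + 30 * loads[[p]] * bell + 8 * shape
  }, numeric(channel_count)))
  rownames(proto) <- postures
  proto
}

#' Simulation configuration
#'
#' @param channel_count Muscle channels (default 11, the usable-channel
#'   count of the 14-channel band).
#' @param prototypes 7 x `channel_count` posture prototype matrix; default
#'   [default_prototypes()].
#' @param noise_sd Gaussian channel noise SD in sensor counts (default 2).
#' @param cadence Gait cadence in cycles/min (default 50, a slow ~3 km/h
#'   treadmill pace).
#' @param stance_fraction Fraction of each cycle spent in stance (default
#'   0.6, giving a 1.5:1 stance:swing sample ratio).
#' @param n_cycles Number of gait cycles in a walk (default 30).
#' @param sample_rate Sensor rate in Hz (default 50).
#' @param gy_stance Mid-stance anterior rate plateau in rad/s (default 1.2,
#'   above th2 = 0.7).
#' @param gy_swing Swing plateau in rad/s; `NULL` (default) solves for the
#'   value that zeroes the per-cycle gy integral so the pitch angle is
#'   periodic (about -1.9 rad/s at the defaults, below th1 = 0.6).
#' @param ramp Fraction of the cycle spent ramping between gy plateaus at
#'   each phase boundary (default 0.04).
#' @param gyro_noise_sd Gyroscope noise SD in rad/s (default 0.02).
#' @param gyro_bias Constant gyro drift bias in rad/s (default 0.01).
#' @param boundary_mismatch Displacement (sensor counts) of all walking
#'   frames along the unit vector from the stance-prototype centroid toward
#'   the swing-prototype centroid, emulating the standing/walking
#'   decision-boundary drift the probability adjustment compensates for.
#'   Default 0.
#' @param seed RNG seed; the generators are deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(channel_count = 11, prototypes = NULL, noise_sd = 2,
                       cadence = 50, stance_fraction = 0.6, n_cycles = 30,
                       sample_rate = 50, gy_stance = 1.2, gy_swing = NULL,
                       ramp = 0.04, gyro_noise_sd = 0.02, gyro_bias = 0.01,
                       boundary_mismatch = 0, seed = 0) {
  if (is.null(prototypes)) prototypes <- default_prototypes(channel_count)
  prototypes <- as.matrix(prototypes)
  if (nrow(prototypes) != 7L || is.null(rownames(prototypes))) {
    stop("prototypes must be a 7-row matrix with posture rownames")
  }
  rownames(prototypes) <- canonical_posture(rownames(prototypes))
  if (!setequal(rownames(prototypes), posture_labels())) {
    stop("prototypes must cover all 7 postures")
  }
  if (ncol(prototypes) != channel_count) {
    stop("prototypes must have channel_count columns")
  }
  if (any(duplicated(prototypes))) stop("prototypes must be pairwise distinct")
  if (!(stance_fraction > 0 && stance_fraction < 1)) {
    stop("stance_fraction must be in (0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(channel_count = channel_count, prototypes = prototypes,
         noise_sd = noise_sd, cadence = cadence,
         stance_fraction = stance_fraction, n_cycles = n_cycles,
         sample_rate = sample_rate, gy_stance = gy_stance,
         gy_swing = gy_swing, ramp = ramp, gyro_noise_sd = gyro_noise_sd,
         gyro_bias = gyro_bias, boundary_mismatch = boundary_mismatch,
         seed = seed),
    class = "sim_config"
  )
}

# internal: per-cycle gy waypoints (cycle fraction u, value). Plateaus at
# gy_stance in mid-stance and gy_swing in swing; ramps of width 2*ramp pass
# through the dead-zone midpoint exactly at the phase boundaries u =
# stance_fraction and u = 1, so stance frames never dip below th1 and swing
# frames never rise above th2.
gy_waypoints <- function(cfg, gy_swing) {
  sf <- cfg$stance_fraction
  r <- cfg$ramp
  mid <- 0.65                       # dead-zone midpoint between th1 and th2
  u <- c(0, r, sf - r, sf, sf + r, 1 - r, 1)
  v <- c(mid, cfg$gy_stance, cfg$gy_stance, mid, gy_swing, gy_swing, mid)
  list(u = u, v = v)
}

# internal: solve gy_swing so the per-cycle integral of the piecewise-linear
# profile is zero (pitch returns to its start each cycle). The integral is
# affine in gy_swing, so two evaluations determine the root.
solve_gy_swing <- function(cfg) {
  integral <- function(gs) {
    wp <- gy_waypoints(cfg, gs)
    sum(diff(wp$u) * (utils::head(wp$v, -1) + utils::tail(wp$v, -1)) / 2)
  }
  s0 <- integral(0); s1 <- integral(1)
  -s0 / (s1 - s0)
}

#' Generate the seven standing-posture calibration recordings
#'
#' Each posture yields `n_per_posture` frames of prototype + Gaussian
#' channel noise, an identity quaternion (the wearer stands still), and a
#' gyroscope reading of small noise plus a constant drift bias.
#'
#' @param cfg A [sim_config()].
#' @param n_per_posture Frames per posture (default 500, i.e. 10 s at
#'   50 Hz).
#' @return Named list of 7 posture `gait_recording`s.
#' @export
generate_posture_recordings <- function(cfg = sim_config(),
                                        n_per_posture = 500) {
  withr::with_seed(cfg$seed, {
    recs <- lapply(posture_labels(), function(p) {
      n <- n_per_posture
      md <- matrix(rep(cfg$prototypes[p, ], each = n), nrow = n) +
        matrix(stats::rnorm(n * cfg$channel_count, sd = cfg$noise_sd), nrow = n)
      omega <- matrix(stats::rnorm(n * 3, mean = cfg$gyro_bias,
                                   sd = cfg$gyro_noise_sd), nrow = n)
      quat <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
      gait_recording(
        t = seq_len(n) / cfg$sample_rate, md = md, quat = quat,
        omega = omega, kind = "posture", posture = p,
        sample_rate_hz = cfg$sample_rate
      )
    })
    names(recs) <- posture_labels()
    recs
  })
}

# internal: md waypoint schedule over the whole walk (global cycle-fraction
# positions and posture names). Within each cycle the trajectory visits the
# five stance prototypes and then the two swing prototypes; the crossing of
# the midpoint between the last prototype of one phase and the first of the
# next is placed just before the label flip, so every frame lies on its own
# phase's side of the stance/swing prototype midline.
md_waypoints <- function(cfg) {
  sf <- cfg$stance_fraction
  stance_seq <- c("front_heel_contact", "front_foot_flat", "single_support",
                  "back_foot_flat", "back_heel_off")
  # stance prototypes spread over the stance window, heel-off close to
  # toe-off; swing prototypes just after toe-off and just before the next
  # heel contact, so the prototype-midline crossings fall fractionally
  # before the label flips at u = sf and u = 1
  u_stance <- sf * c(0.025, 0.25, 0.50, 0.75, 0.958)
  u_swing <- sf + (1 - sf) * c(0.0375, 0.9375)      # back/front foot off
  list(u = c(u_stance, u_swing), posture = c(stance_seq, "back_foot_off",
                                             "front_foot_off"))
}

#' Generate a labeled synthetic walking recording
#'
#' Builds `n_cycles` gait cycles at the configured cadence and sampling
#' rate. Muscle deformation linearly interpolates through the posture
#' prototypes in gait order plus channel noise and the `boundary_mismatch`
#' offset; per-frame labels follow `stance_fraction`; the anterior rate gy
#' is a piecewise-linear profile (mid-stance plateau above th2, swing
#' plateau below th1, dead-zone ramps at the phase boundaries) with zero
#' per-cycle integral; the quaternion encodes the pitch angle obtained by
#' integrating gy, and the body-frame gyroscope reads gy on its y axis (at
#' zero roll the pitch rate equals the y gyro rate), plus noise.
#'
#' @param cfg A [sim_config()].
#' @return A labeled walking `gait_recording` with attribute `gy_true`
#'   (noise-free gy) for inspection.
#' @export
generate_walk <- function(cfg = sim_config()) {
  sf <- cfg$stance_fraction
  frames_per_cycle <- round(cfg$sample_rate * 60 / cfg$cadence)
  n_stance <- round(sf * frames_per_cycle)
  n <- frames_per_cycle * cfg$n_cycles
  u_global <- (seq_len(n) - 1) / frames_per_cycle   # cycles since start
  u <- u_global %% 1
  cycle <- floor(u_global)

  labels <- ifelse((seq_len(n) - 1) %% frames_per_cycle < n_stance,
                   "stance", "swing")

  # gy profile (noise-free), periodic with zero mean per cycle
  gy_swing <- if (is.null(cfg$gy_swing)) solve_gy_swing(cfg) else cfg$gy_swing
  wp <- gy_waypoints(cfg, gy_swing)
  gy_true <- stats::approx(wp$u, wp$v, xout = u, rule = 2)$y

  # pitch angle from gy by forward integration, centered on zero
  theta <- cumsum(c(0, gy_true[-n])) / cfg$sample_rate
  theta <- theta - mean(theta)

  # md trajectory through the prototype waypoints (global positions)
  mwp <- md_waypoints(cfg)
  u_all <- as.vector(outer(mwp$u, seq_len(cfg$n_cycles) - 1, `+`))
  p_all <- rep(mwp$posture, times = cfg$n_cycles)
  ord <- order(u_all)
  u_all <- u_all[ord]; p_all <- p_all[ord]
  proto_path <- cfg$prototypes[p_all, , drop = FALSE]
  md <- vapply(seq_len(cfg$channel_count), function(kk) {
    stats::approx(u_all, proto_path[, kk], xout = u_global, rule = 2)$y
  }, numeric(n))

  # standing/walking boundary drift along the stance -> swing centroid axis
  if (cfg$boundary_mismatch != 0) {
    swing_p <- c("back_foot_off", "front_foot_off")
    dir <- colMeans(cfg$prototypes[swing_p, , drop = FALSE]) -
      colMeans(cfg$prototypes[setdiff(posture_labels(), swing_p), , drop = FALSE])
    dir <- dir / sqrt(sum(dir^2))
    md <- md + matrix(rep(cfg$boundary_mismatch * dir, each = n), nrow = n)
  }

  withr::with_seed(cfg$seed + 1L, {
    md <- md + matrix(stats::rnorm(n * cfg$channel_count, sd = cfg$noise_sd),
                      nrow = n)
    omega <- cbind(stats::rnorm(n, sd = cfg$gyro_noise_sd),
                   gy_true + stats::rnorm(n, sd = cfg$gyro_noise_sd),
                   stats::rnorm(n, sd = cfg$gyro_noise_sd))
  })
  quat <- cbind(cos(theta / 2), 0, sin(theta / 2), 0)

  rec <- gait_recording(
    t = seq_len(n) / cfg$sample_rate, md = md, quat = quat, omega = omega,
    kind = "walk", labels = labels, sample_rate_hz = cfg$sample_rate
  )
  attr(rec, "gy_true") <- gy_true
  rec
}
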