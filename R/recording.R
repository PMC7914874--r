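# -- label vocabularies -------------------------------------------------------

#' Gait phase labels
#'
#' The two phases of the gait cycle: `stance` (foot-contact, heel contact to
#' toe-off) and `swing` (foot-off, toe-off to the next heel contact).
#'
#' @return Character vector `c("stance", "swing")`.
#' @export
phase_levels <- function() c("stance", "swing")

#' The seven calibration standing postures
#'
#' Static standing postures used as calibration data, spanning foot position
#' (back or front) and foot-contact state. Two of them mimic the swing phase
#' (the foot is off the ground): `back_foot_off` and `front_foot_off`; the
#' remaining five mimic stance.
#'
#' @return Character vector of the 7 canonical posture names.
#' @seealso [posture_phase()], [training_conditions()]
#' @export
posture_labels <- function() {
  c("back_foot_flat", "back_heel_off", "back_foot_off",
    "front_foot_flat", "front_heel_contact", "front_foot_off",
    "single_support")
}

# alias table: the same postures appear in the field under "foot-on" /
# "heel-on" / "heel-contact" naming; normalize to the canonical enum.
.posture_aliases <- c(
  back_foot_on       = "back_foot_flat",
  front_foot_on      = "front_foot_flat",
  front_heel_on      = "front_heel_contact",
  heel_contact       = "front_heel_contact",
  heel_off           = "back_heel_off"
)

#' Canonicalize a posture name
#'
#' Accepts canonical names plus common aliases (`back_foot_on`,
#' `front_foot_on`, `front_heel_on`, `heel_contact`, `heel_off`), in any
#' case, with spaces or hyphens.
#'
#' @param x Character vector of posture names.
#' @return Character vector of canonical posture names.
#' @export
canonical_posture <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(x)))
  out <- ifelse(key %in% names(.posture_aliases),
                unname(.posture_aliases[key]), key)
  bad <- !(out %in% posture_labels())
  if (any(bad)) {
    stop("unknown posture name(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Phase side of a standing posture
#'
#' `back_foot_off` and `front_foot_off` are foot-off postures and map to
#' `swing`; the other five map to `stance`.
#'
#' @param posture Character vector of posture names (aliases accepted).
#' @return Character vector of `"stance"` / `"swing"`.
#' @export
posture_phase <- function(posture) {
  p <- canonical_posture(posture)
  ifelse(p %in% c("back_foot_off", "front_foot_off"), "swing", "stance")
}

# -- Recording ---------------------------------------------------------------

#' Construct a sensor recording
#'
#' A recording is a fixed-rate multi-channel time series from a shank-worn
#' band: per frame a muscle-deformation channel vector (dimensionless sensor
#' counts), a scalar-first unit quaternion (q0, q1, q2, q3) and a body-frame
#' angular velocity (wx, wy, wz) in rad/s. Quaternions are renormalized on
#' construction; a norm deviating from 1 by more than 0.1 is rejected.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param md Numeric matrix, one row per frame, one column per muscle channel.
#' @param quat Numeric matrix with 4 columns (q0 = scalar first).
#' @param omega Numeric matrix with 3 columns, body-frame rad/s.
#' @param kind `"posture"` (static calibration recording) or `"walk"`.
#' @param posture Posture name; required iff `kind = "posture"`.
#' @param labels Optional per-frame phase labels (`"stance"`/`"swing"`),
#'   walking recordings only.
#' @param sample_rate_hz Nominal sampling rate (default 50).
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(t, md, quat, omega, kind = c("walk", "posture"),
                           posture = NULL, labels = NULL,
                           sample_rate_hz = 50) {
  kind <- match.arg(kind)
  md <- as.matrix(md)
  quat <- as.matrix(quat)
  omega <- as.matrix(omega)
  n <- length(t)
  if (nrow(md) != n || nrow(quat) != n || nrow(omega) != n) {
    stop("t, md, quat and omega must have one entry per frame")
  }
  if (ncol(quat) != 4L) stop("quat must have 4 columns (q0..q3)")
  if (ncol(omega) != 3L) stop("omega must have 3 columns (wx, wy, wz)")
  if (n > 1L && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1L] + 1L
    stop("timestamps must be strictly increasing (violated at frame ", bad, ")")
  }
  if (anyNA(md) || anyNA(quat) || anyNA(omega) || anyNA(t)) {
    stop("recording contains missing values")
  }
  if (n > 0L) {
    nrm <- sqrt(rowSums(quat^2))
    off <- which(abs(nrm - 1) > 0.1)
    if (length(off) > 0L) {
      stop("quaternion norm deviates from 1 by more than 0.1 at frame(s): ",
           paste(utils::head(off, 5L), collapse = ", "))
    }
    quat <- quat / nrm
  }
  if (kind == "posture") {
    if (is.null(posture)) stop("posture recordings must carry a posture label")
    posture <- canonical_posture(posture)
    if (!is.null(labels)) stop("per-frame phase labels apply to walking recordings only")
  } else {
    if (!is.null(posture)) stop("walking recordings must not carry a posture label")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length must equal frame count")
    if (!all(labels %in% phase_levels())) {
      stop("labels must be 'stance' or 'swing'")
    }
  }
  structure(
    list(t = as.numeric(t), md = unname(md), quat = unname(quat),
         omega = unname(omega), kind = kind, posture = posture,
         labels = labels, sample_rate_hz = sample_rate_hz),
    class = "gait_recording"
  )
}

#' Number of frames in a recording
#' @param rec A `gait_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(rec) length(rec$t)

#' Number of muscle-deformation channels in a recording
#' @param rec A `gait_recording`.
#' @return Integer channel count.
#' @export
n_channels <- function(rec) ncol(rec$md)

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s, %d frames x %d channels @ %g Hz\n",
              x$kind, n_frames(x), n_channels(x), x$sample_rate_hz))
  if (!is.null(x$posture)) cat("  posture:", x$posture, "\n")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = phase_levels()))
    cat(sprintf("  labels: %d stance / %d swing\n", tab[["stance"]], tab[["swing"]]))
  }
  invisible(x)
}

# -- CSV I/O -----------------------------------------------------------------

# schema: t, md_1..md_K, q0..q3, wx, wy, wz [, label]

#' Read a recording from CSV
#'
#' Expects the column layout `t, md_1..md_K, q0..q3, wx, wy, wz` with an
#' optional trailing `label` column (values `stance`/`swing`). The channel
#' count K is inferred from the header unless `channels` is given, in which
#' case a mismatch is an error. Quaternions are renormalized after load.
#'
#' @param path CSV file path.
#' @param channels Optional expected channel count.
#' @param kind,posture,sample_rate_hz Passed through to [gait_recording()].
#' @return A `gait_recording`.
#' @export
read_recording <- function(path, channels = NULL, kind = c("walk", "posture"),
                           posture = NULL, sample_rate_hz = 50) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  md_cols <- grep("^md_[0-9]+$", names(df), value = TRUE)
  md_cols <- md_cols[order(as.integer(sub("^md_", "", md_cols)))]
  needed <- c("t", "q0", "q1", "q2", "q3", "wx", "wy", "wz")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L || length(md_cols) == 0L) {
    stop("malformed recording CSV '", path, "': missing column(s) ",
         paste(c(missing, if (length(md_cols) == 0L) "md_*"), collapse = ", "))
  }
  if (!is.null(channels) && length(md_cols) != channels) {
    stop("channel count mismatch in '", path, "': expected ", channels,
         " md_* columns, found ", length(md_cols))
  }
  labels <- if ("label" %in% names(df) && nrow(df) > 0L) df$label else NULL
  gait_recording(
    t = df$t,
    md = as.matrix(df[md_cols]),
    quat = as.matrix(df[c("q0", "q1", "q2", "q3")]),
    omega = as.matrix(df[c("wx", "wy", "wz")]),
    kind = kind, posture = posture, labels = labels,
    sample_rate_hz = sample_rate_hz
  )
}

#' Write a recording to CSV
#'
#' Emits the schema read by [read_recording()]; numeric values are written
#' with 9 significant digits, so a read-back round trip agrees to relative
#' 1e-8.
#'
#' @param rec A `gait_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  k <- n_channels(rec)
  num <- cbind(rec$t, rec$md, rec$quat, rec$omega)
  colnames(num) <- c("t", paste0("md_", seq_len(k)),
                     paste0("q", 0:3), c("wx", "wy", "wz"))
  df <- as.data.frame(apply(num, 2L, function(col) {
    formatC(col, digits = 9L, format = "g")
  }, simplify = FALSE), check.names = FALSE)
  if (n_frames(rec) == 0L) {
    df <- as.data.frame(matrix(character(0), nrow = 0L, ncol = ncol(num),
                               dimnames = list(NULL, colnames(num))))
  }
  if (!is.null(rec$labels)) df$label <- rec$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: check a set of recordings shares one channel count; returns it.
common_channel_count <- function(recs) {
  ks <- vapply(recs, n_channels, integer(1))
  if (length(unique(ks)) != 1L) {
    stop("recordings disagree on channel count: ",
         paste(unique(ks), collapse = " vs "))
  }
  ks[[1L]]
}
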