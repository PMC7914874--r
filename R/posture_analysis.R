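# Posture-to-phase similarity analysis: for each gait cycle of a labeled
# walk, find the walking frame nearest (Euclidean distance over channels) to
# each standing posture's mean deformation vector and tally that frame's
# phase. A posture whose nearest frames are mostly stance-labeled resembles
# the stance phase, and vice versa; this ranking motivates which postures to
# include in the training conditions.

#' Mean muscle-deformation vector of each posture
#'
#' @param recordings List of posture `gait_recording`s.
#' @return Numeric matrix, one row per posture (rownames = posture), channel
#'   means over all frames of that posture.
#' @export
posture_means <- function(recordings) {
  if (length(recordings) == 0L) stop("no posture recordings supplied")
  common_channel_count(recordings)
  rows <- lapply(recordings, function(rec) {
    if (rec$kind != "posture") stop("posture_means expects posture recordings")
    if (n_frames(rec) == 0L) stop("empty posture recording: ", rec$posture)
    colMeans(rec$md)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(recordings, function(r) r$posture, character(1))
  m
}

#' Gait-cycle boundaries from a phase-label sequence
#'
#' A cycle starts at each swing-to-stance transition (heel contact). The
#' leading partial segment before the first transition belongs to no cycle
#' and is dropped; if the labels contain no transition the whole recording
#' is one cycle.
#'
#' @param labels Character vector of per-frame `"stance"`/`"swing"`.
#' @return Data.frame with columns `start`, `end` (inclusive frame indices).
#' @export
gait_cycle_bounds <- function(labels) {
  n <- length(labels)
  if (n == 0L) stop("empty label sequence")
  starts <- which(labels[-1L] == "stance" & labels[-n] == "swing") + 1L
  if (labels[1L] == "stance") starts <- c(1L, starts)
  if (length(starts) == 0L) starts <- 1L
  data.frame(start = starts, end = c(starts[-1L] - 1L, n))
}

#' Per-posture closest-frame phase percentages
#'
#' For each gait cycle and each posture, locates the frame within the cycle
#' whose muscle-deformation vector minimizes the Euclidean distance to that
#' posture's mean vector (ties broken toward the earliest frame) and tallies
#' the frame's ground-truth phase. Percentages divide the tallies by the
#' number of cycles, so `stance_pct + swing_pct = 100` for every posture.
#'
#' With `per_frame = TRUE` an alternative reading is computed: every frame
#' votes for its nearest posture, and percentages are per-posture phase
#' shares of those votes.
#'
#' @param walk A labeled walking `gait_recording`.
#' @param means Posture-mean matrix from [posture_means()].
#' @param cycles Cycle boundaries; defaults to
#'   `gait_cycle_bounds(walk$labels)`.
#' @param per_frame Use the per-frame nearest-posture reading instead.
#' @return Data.frame with columns `posture`, `stance_pct`, `swing_pct`.
#' @export
closest_label_percentages <- function(walk, means, cycles = NULL,
                                      per_frame = FALSE) {
  if (is.null(walk$labels)) stop("walk must carry ground-truth phase labels")
  if (ncol(means) != n_channels(walk)) {
    stop("means and walk disagree on channel count")
  }
  postures <- rownames(means)
  if (per_frame) {
    # distance of every frame to every posture mean; nearest posture votes
    d2 <- outer(rowSums(walk$md^2), rep(1, nrow(means))) -
      2 * walk$md %*% t(means) +
      outer(rep(1, n_frames(walk)), rowSums(means^2))
    nearest <- postures[max.col(-d2, ties.method = "first")]
    out <- do.call(rbind, lapply(postures, function(p) {
      lab <- walk$labels[nearest == p]
      tot <- length(lab)
      data.frame(posture = p,
                 stance_pct = if (tot) 100 * mean(lab == "stance") else NA_real_,
                 swing_pct = if (tot) 100 * mean(lab == "swing") else NA_real_)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(cycles)) cycles <- gait_cycle_bounds(walk$labels)
  if (nrow(cycles) < 1L) stop("need at least one gait cycle")
  tall <- matrix(0L, nrow = length(postures), ncol = 2L,
                 dimnames = list(postures, phase_levels()))
  for (ci in seq_len(nrow(cycles))) {
    idx <- cycles$start[ci]:cycles$end[ci]
    seg <- walk$md[idx, , drop = FALSE]
    for (p in postures) {
      d2 <- rowSums(sweep(seg, 2L, means[p, ])^2)
      j <- which.min(d2)            # which.min takes the earliest tie
      lab <- walk$labels[idx[j]]
      tall[p, lab] <- tall[p, lab] + 1L
    }
  }
  out <- data.frame(posture = postures,
                    stance_pct = 100 * tall[, "stance"] / nrow(cycles),
                    swing_pct = 100 * tall[, "swing"] / nrow(cycles))
  rownames(out) <- NULL
  out
}

#' Training conditions implied by the similarity ranking
#'
#' Returns the fixed ten-condition set of [training_conditions()], annotated
#' with the similarity evidence: the documented construction adds stance
#' postures in descending order of their stance percentage and toggles the
#' second swing posture (`front_foot_off`), but the condition set itself is
#' fixed — the ranking only orders the annotation.
#'
#' @param result Data.frame from [closest_label_percentages()] covering all
#'   7 postures.
#' @return Named list of 10 posture sets (as [training_conditions()]), with
#'   attribute `stance_ranking`: stance postures by descending stance_pct.
#' @export
rank_training_conditions <- function(result) {
  if (!all(posture_labels() %in% result$posture)) {
    stop("result must cover all 7 postures")
  }
  stance_post <- setdiff(posture_labels(), c("back_foot_off", "front_foot_off"))
  sub <- result[result$posture %in% stance_post, ]
  ranking <- sub$posture[order(-sub$stance_pct, sub$posture)]
  conds <- training_conditions()
  attr(conds, "stance_ranking") <- ranking
  conds
}
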