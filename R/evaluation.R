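# Evaluation: video-rate to sensor-rate label alignment, sample-based
# accuracy, per-phase true positive rates, and per-subject summaries.

#' Align video-rate labels to sensor timestamps
#'
#' Ground-truth phase labels typically come from video annotated at a higher
#' rate (120 Hz) than the sensor (50 Hz). Each sensor frame takes the label
#' of the nearest-in-time video frame; sensor frames outside the video time
#' range are dropped with a warning. Both series must share a time origin.
#'
#' @param video_t Numeric video timestamps (seconds).
#' @param video_labels Phase labels, one per video timestamp.
#' @param sensor_t Numeric sensor timestamps (seconds).
#' @return List: `labels` (per kept sensor frame), `kept` (logical over
#'   sensor frames), `n_dropped`.
#' @export
align_labels <- function(video_t, video_labels, sensor_t) {
  if (length(video_t) != length(video_labels)) {
    stop("video_t and video_labels lengths differ")
  }
  if (length(video_t) == 0L || length(sensor_t) == 0L) {
    stop("empty label or timestamp series")
  }
  lo <- min(video_t); hi <- max(video_t)
  kept <- sensor_t >= lo & sensor_t <= hi
  if (!any(kept)) stop("sensor and video time ranges do not overlap")
  n_dropped <- sum(!kept)
  if (n_dropped > 0L) {
    warning(n_dropped, " sensor frame(s) outside the video time range dropped")
  }
  idx <- vapply(sensor_t[kept], function(ts) which.min(abs(video_t - ts)),
                integer(1))
  list(labels = as.character(video_labels)[idx], kept = kept,
       n_dropped = n_dropped)
}

#' Sample-based accuracy and per-phase true positive rates
#'
#' Sample-based accuracy is `100 * N_true / N`, the percentage of frames
#' whose predicted phase matches the ground truth. The true positive rate of
#' a phase is `100 * N_phase_true / N_phase`, the percentage of that phase's
#' ground-truth frames correctly identified. The false positive rate of a
#' phase equals `100 -` the true positive rate of the other phase.
#'
#' @param pred,truth Equal-length character vectors of `"stance"`/`"swing"`.
#' @return List of class `evaluation_result`: `n`, `n_true`, `accuracy`
#'   (percent), and per phase `n_phase`, `n_phase_true`, `tpr`, `fpr`
#'   (percent; `tpr` is `NA` for a phase absent from `truth`).
#' @export
evaluate_phases <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) == 0L) stop("empty prediction series")
  if (!all(pred %in% phase_levels()) || !all(truth %in% phase_levels())) {
    stop("labels must be 'stance'/'swing'")
  }
  n <- length(truth)
  correct <- pred == truth
  n_true <- sum(correct)
  per <- lapply(phase_levels(), function(ph) {
    in_ph <- truth == ph
    n_ph <- sum(in_ph)
    n_ph_true <- sum(correct & in_ph)
    list(n_phase = n_ph, n_phase_true = n_ph_true,
         tpr = if (n_ph > 0L) 100 * n_ph_true / n_ph else NA_real_)
  })
  names(per) <- phase_levels()
  for (ph in phase_levels()) {
    other <- setdiff(phase_levels(), ph)
    per[[ph]]$fpr <- 100 - per[[other]]$tpr
  }
  structure(
    list(n = n, n_true = n_true, accuracy = 100 * n_true / n, phases = per),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %d frames, accuracy %.1f%%\n", x$n, x$accuracy))
  for (ph in names(x$phases)) {
    p <- x$phases[[ph]]
    cat(sprintf("  %-6s n = %5d  TPR = %5.1f%%  FPR = %5.1f%%\n",
                ph, p$n_phase, p$tpr, p$fpr))
  }
  invisible(x)
}

#' Median and IQR of per-subject metrics
#'
#' Aggregates a list of [evaluate_phases()] results across subjects:
#' median and interquartile range (Q3 - Q1, linear-interpolation quantiles)
#' of accuracy and of each phase's true positive rate.
#'
#' @param results Nonempty list of `evaluation_result`s.
#' @return Data.frame with columns `metric`, `median`, `iqr`.
#' @export
summarize_subjects <- function(results) {
  if (length(results) == 0L) stop("no subject results to summarize")
  grab <- function(f) vapply(results, f, numeric(1))
  metrics <- list(
    accuracy = grab(function(r) r$accuracy),
    tpr_stance = grab(function(r) r$phases$stance$tpr),
    tpr_swing = grab(function(r) r$phases$swing$tpr)
  )
  out <- do.call(rbind, lapply(names(metrics), function(m) {
    v <- metrics[[m]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
    data.frame(metric = m, median = unname(q[2L]),
               iqr = unname(q[3L] - q[1L]))
  }))
  rownames(out) <- NULL
  out
}
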