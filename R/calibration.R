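# Standing-based calibration: assemble labeled training data from static
# posture recordings, fit the logistic classifier, derive gyro gating
# thresholds, and fit the SVM baseline.

#' The ten standing-posture training combinations
#'
#' The fixed set of posture combinations used to calibrate the classifier
#' from standing data. Every condition includes the two anchor postures
#' `back_foot_off` (swing side) and `front_heel_contact` (stance side);
#' conditions 1-5 use one swing posture and conditions 6-10 add the second
#' (`front_foot_off`); stance postures are added one at a time in order
#' `single_support`, `back_foot_flat`, `front_foot_flat`, `back_heel_off`.
#' Condition 9 has six postures; condition 10 has all seven.
#'
#' @return Named list of 10 character vectors of canonical posture names.
#' @export
training_conditions <- function() {
  stance_order <- c("front_heel_contact", "single_support", "back_foot_flat",
                    "front_foot_flat", "back_heel_off")
  conds <- vector("list", 10L)
  for (i in 1:5) {
    conds[[i]] <- c("back_foot_off", stance_order[seq_len(i)])
    conds[[i + 5L]] <- c("back_foot_off", "front_foot_off",
                         stance_order[seq_len(i)])
  }
  names(conds) <- paste0("condition_", 1:10)
  conds
}

#' Postures of one training condition
#'
#' @param id Condition id, 1-10.
#' @return Character vector of canonical posture names.
#' @export
condition_postures <- function(id) {
  if (!(is.numeric(id) && length(id) == 1L && id %in% 1:10)) {
    stop("condition id must be an integer in 1..10")
  }
  training_conditions()[[as.integer(id)]]
}

#' Assemble a training set from standing-posture recordings
#'
#' Takes the chronologically first `n_per_posture` frames of each posture
#' included in the condition and labels them by the posture's phase side:
#' foot-off postures (`back_foot_off`, `front_foot_off`) as `swing`, the
#' rest as `stance`.
#'
#' @param recordings List of posture `gait_recording`s (names ignored; the
#'   recordings' own posture labels are used).
#' @param condition Condition id (1-10) or a character vector of postures.
#' @param n_per_posture Frames to take per posture.
#' @return List with `X` (numeric matrix), `y` (character phase vector) and
#'   `postures` (per-row source posture).
#' @export
assemble_training_set <- function(recordings, condition = 9,
                                  n_per_posture = 500) {
  if (!(is.numeric(n_per_posture) && n_per_posture >= 1)) {
    stop("n_per_posture must be a positive count")
  }
  wanted <- if (is.character(condition)) {
    canonical_posture(condition)
  } else {
    condition_postures(condition)
  }
  have <- vapply(recordings, function(r) {
    if (r$kind != "posture") stop("all calibration recordings must have kind 'posture'")
    r$posture
  }, character(1))
  missing <- setdiff(wanted, have)
  if (length(missing) > 0L) {
    stop("missing posture recording(s): ", paste(missing, collapse = ", "))
  }
  common_channel_count(recordings)
  rows <- lapply(wanted, function(p) {
    rec <- recordings[[match(p, have)]]
    if (n_frames(rec) < n_per_posture) {
      stop("posture '", p, "' has ", n_frames(rec), " frames, need ",
           n_per_posture)
    }
    rec$md[seq_len(n_per_posture), , drop = FALSE]
  })
  X <- do.call(rbind, rows)
  postures <- rep(wanted, each = n_per_posture)
  list(X = X, y = posture_phase(postures), postures = postures)
}

# -- logistic fit ------------------------------------------------------------

# Objective (swing coded +1, stance -1, z = X w + b):
#   J(w, b) = 0.5 * ||w||^2 + sum_i log(1 + exp(-y_i z_i))
# i.e. an L2 penalty of unit strength on the weights, intercept unpenalized.
# Solved by damped Newton iterations (IRLS with ridge); the problem is
# strictly convex so the fit is deterministic.

#' Fit the penalized logistic classifier
#'
#' Maximum penalized likelihood logistic regression with a unit-strength L2
#' penalty on the channel weights (intercept unpenalized) and `swing` coded
#' as the positive class. Fitted by damped Newton iterations to a gradient
#' norm below `tol`; the objective is strictly convex, so the result is
#' deterministic and independent of row order.
#'
#' @param X Numeric matrix of muscle-deformation vectors (rows = frames).
#' @param y Phase labels (`"stance"`/`"swing"`), one per row.
#' @param tol Convergence tolerance on the max-norm of the gradient.
#' @param max_iter Iteration cap.
#' @return A `trained_model`: list with `w`, `b`, `channel_count`,
#'   `condition` (filled by the caller when known).
#' @export
fit_lr <- function(X, y, tol = 1e-9, max_iter = 200L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values")
  if (length(y) != nrow(X)) stop("y length must match nrow(X)")
  if (!all(y %in% phase_levels())) stop("y must be 'stance'/'swing'")
  if (length(unique(y)) < 2L) stop("both phases must be present in y")
  s <- ifelse(y == "swing", 1, -1)
  k <- ncol(X)
  Z <- cbind(X, 1)            # last coefficient is the intercept
  beta <- numeric(k + 1L)
  pen <- c(rep(1, k), 0)      # intercept unpenalized
  obj <- function(beta) {
    m <- s * drop(Z %*% beta)
    # log(1 + exp(-m)) computed stably
    0.5 * sum(pen * beta^2) + sum(ifelse(m > 0, log1p(exp(-m)),
                                         -m + log1p(exp(m))))
  }
  f <- obj(beta)
  for (iter in seq_len(max_iter)) {
    z <- drop(Z %*% beta)
    p <- plogis(z)                       # P(swing | x)
    yi <- as.numeric(s > 0)
    g <- drop(crossprod(Z, p - yi)) + pen * beta
    if (max(abs(g)) < tol) break
    wgt <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Z * wgt, Z) + diag(pen)
    step <- solve(H, g)
    # damped update: halve until the objective decreases
    eta <- 1
    repeat {
      cand <- beta - eta * step
      fc <- obj(cand)
      if (fc <= f + 1e-12 || eta < 1e-8) break
      eta <- eta / 2
    }
    beta <- cand
    f <- fc
  }
  structure(
    list(w = beta[seq_len(k)], b = beta[k + 1L], channel_count = k,
         condition = NA_integer_),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> logistic, %d channels, |w| = %.4g, b = %.4g\n",
              x$channel_count, sqrt(sum(x$w^2)), x$b))
  invisible(x)
}

#' Calibrate a model from posture recordings
#'
#' Convenience wrapper: [assemble_training_set()] then [fit_lr()], recording
#' the condition id on the model.
#'
#' @inheritParams assemble_training_set
#' @return A `trained_model`.
#' @export
calibrate <- function(recordings, condition = 9, n_per_posture = 500) {
  ts <- assemble_training_set(recordings, condition, n_per_posture)
  model <- fit_lr(ts$X, ts$y)
  model$condition <- if (is.numeric(condition)) as.integer(condition) else NA_integer_
  model
}

#' Save / load a trained model as JSON
#'
#' @param model A `trained_model`.
#' @param path JSON file path.
#' @return `read_model` returns a `trained_model`; `write_model` the path,
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  jsonlite::write_json(
    list(w = model$w, b = model$b, channel_count = model$channel_count,
         condition = model$condition),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(w = as.numeric(obj$w), b = as.numeric(obj$b),
         channel_count = as.integer(obj$channel_count),
         condition = as.integer(obj$condition)),
    class = "trained_model"
  )
}

# -- gating thresholds -------------------------------------------------------

#' Gyro gating thresholds th1 < th2
#'
#' In `"fixed"` mode returns the operating defaults (0.6, 0.7) rad/s. In
#' `"standing"` mode the thresholds are derived from the anterior angular
#' velocity observed while the wearer stands still — accounting for gyro
#' drift — as the 95th percentile of standing gy plus margins `delta`
#' (defaults 0.1 and 0.2 rad/s).
#'
#' @param standing List of posture `gait_recording`s (used in
#'   `"standing"` mode).
#' @param mode `"fixed"` or `"standing"`.
#' @param delta Length-2 increments above the standing percentile,
#'   `delta[1] < delta[2]`.
#' @param config A [detection_config()] (controls the gy pipeline).
#' @return Named numeric vector `c(th1 = , th2 = )` in rad/s.
#' @export
derive_thresholds <- function(standing = NULL, mode = c("fixed", "standing"),
                              delta = c(0.1, 0.2),
                              config = detection_config()) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(c(th1 = 0.6, th2 = 0.7))
  if (is.null(standing) || length(standing) == 0L) {
    stop("standing recordings are required in 'standing' mode")
  }
  gy <- unlist(lapply(standing, function(rec) {
    recording_kinematics(rec, config)$gy
  }))
  gy <- gy[is.finite(gy)]
  if (length(gy) == 0L) stop("no finite gy values in standing recordings")
  p95 <- unname(stats::quantile(gy, 0.95, type = 7))
  th <- c(th1 = p95 + delta[1L], th2 = p95 + delta[2L])
  if (th[["th1"]] >= th[["th2"]]) stop("derived th1 >= th2; check delta")
  th
}

# -- SVM baseline ------------------------------------------------------------

#' RBF-kernel SVM baseline with oracle grid selection
#'
#' Trains a maximum-margin RBF classifier at every point of the grid
#' C in \{1, 10, 100, 1000\} x gamma in \{1e-4, 1e-3, 1e-2, 0.1\} and keeps
#' the pair with the highest accuracy on the supplied labeled evaluation
#' set (ties broken toward smaller C, then smaller gamma). Selecting against
#' the evaluation labels makes this an oracle-tuned reference, not a
#' deployable mode: in the standing-calibration setting there is no walking
#' label to tune against.
#'
#' @param X,y Training muscle-deformation matrix and phase labels.
#' @param eval_X,eval_y Labeled evaluation set used for grid selection.
#' @param cost_grid,gamma_grid Candidate values.
#' @return List with `model` (an [e1071::svm] fit), `best_C`, `best_gamma`,
#'   `grid` (data.frame of all candidates and their evaluation accuracy).
#' @export
fit_svm_baseline <- function(X, y, eval_X, eval_y,
                             cost_grid = c(1, 10, 100, 1000),
                             gamma_grid = c(1e-4, 1e-3, 1e-2, 0.1)) {
  if (length(unique(y)) < 2L) stop("both phases must be present in y")
  if (length(eval_y) != nrow(eval_X)) stop("eval_y length must match eval_X")
  yf <- factor(y, levels = phase_levels())
  grid <- expand.grid(gamma = gamma_grid, C = cost_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  grid$accuracy <- NA_real_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- e1071::svm(x = X, y = yf, kernel = "radial",
                      cost = grid$C[i], gamma = grid$gamma[i],
                      scale = FALSE)
    pred <- as.character(stats::predict(fit, eval_X))
    grid$accuracy[i] <- mean(pred == eval_y)
    fits[[i]] <- fit
  }
  # highest accuracy; ties -> smaller C then smaller gamma (grid is sorted)
  ord <- order(-grid$accuracy, grid$C, grid$gamma)
  best <- ord[1L]
  list(model = fits[[best]], best_C = grid$C[best],
       best_gamma = grid$gamma[best], grid = grid)
}
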