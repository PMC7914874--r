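test_that("the ten training conditions have the expected structure", {
  conds <- training_conditions()
  expect_length(conds, 10L)
  for (cond in conds) {
    expect_true(all(c("back_foot_off", "front_heel_contact") %in% cond))
  }
  expect_length(condition_postures(1), 2L)
  expect_setequal(condition_postures(1), c("back_foot_off", "front_heel_contact"))
  expect_length(condition_postures(9), 6L)
  expect_false("back_heel_off" %in% condition_postures(9))
  expect_setequal(condition_postures(10), posture_labels())
  # conditions 6-10 add the second swing posture
  for (i in 6:10) expect_true("front_foot_off" %in% condition_postures(i))
  for (i in 1:5) expect_false("front_foot_off" %in% condition_postures(i))
  expect_error(condition_postures(11), "1..10")
})

test_that("assemble_training_set sizes and labels follow the condition", {
  post <- generate_posture_recordings(small_sim(), n_per_posture = 60)

  ts1 <- assemble_training_set(post, 1, n_per_posture = 50)
  expect_equal(nrow(ts1$X), 100L)
  expect_equal(sum(ts1$y == "swing"), 50L)
  expect_equal(sum(ts1$y == "stance"), 50L)

  ts9 <- assemble_training_set(post, 9, n_per_posture = 50)
  expect_equal(nrow(ts9$X), 300L)   # 6 postures
  # swing rows come only from the two foot-off postures
  expect_setequal(unique(ts9$postures[ts9$y == "swing"]),
                  c("back_foot_off", "front_foot_off"))

  for (cid in 1:10) {
    ts <- assemble_training_set(post, cid, n_per_posture = 20)
    expect_equal(nrow(ts$X), 20L * length(condition_postures(cid)))
  }

  expect_error(assemble_training_set(post, 9, n_per_posture = 0),
               "positive count")
  expect_error(assemble_training_set(post, 9, n_per_posture = 1000),
               "need 1000")
  expect_error(assemble_training_set(post[-3], 10, n_per_posture = 10),
               "missing posture")
})

test_that("the logistic fit separates a 1-D separable problem", {
  X <- matrix(c(rep(-1, 20), rep(1, 20)), ncol = 1)
  y <- c(rep("stance", 20), rep("swing", 20))
  m <- fit_lr(X, y)
  expect_gt(m$w[1], 0)   # swing is the positive class
  expect_true(all(classify(lr_probability(m, X)) == y))
  expect_error(fit_lr(X, rep("stance", 40)), "both phases")
})

test_that("the fit satisfies penalized-likelihood stationarity", {
  withr::with_seed(42, {
    n <- 200
    X <- matrix(rnorm(n * 3), ncol = 3)
    z <- 1.2 * X[, 1] - 0.8 * X[, 2] + 0.3
    y <- ifelse(runif(n) < plogis(z), "swing", "stance")
  })
  m <- fit_lr(X, y)
  # gradient of 0.5||w||^2 + sum log(1 + exp(-s (Xw + b))), written out
  # independently of the fitting code
  s <- ifelse(y == "swing", 1, -1)
  Z <- cbind(X, 1)
  p <- 1 / (1 + exp(-drop(Z %*% c(m$w, m$b))))
  grad <- drop(crossprod(Z, p - as.numeric(s > 0))) + c(m$w, 0)
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("the fit agrees with an independent ridge-logistic solver", {
  skip_if_not_installed("glmnet")
  withr::with_seed(42, {
    n <- 200
    X <- matrix(rnorm(n * 3), ncol = 3)
    z <- 1.2 * X[, 1] - 0.8 * X[, 2] + 0.3
    y <- ifelse(runif(n) < plogis(z), "swing", "stance")
  })
  m <- fit_lr(X, y)
  ref <- glmnet::glmnet(X, factor(y, levels = phase_levels()),
                        family = "binomial", alpha = 0, lambda = 1 / n,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e6)
  beta_ref <- as.numeric(stats::coef(ref))      # intercept first
  p_ref <- plogis(drop(cbind(X, 1) %*% c(beta_ref[-1], beta_ref[1])))
  p_fit <- lr_probability(m, X)
  expect_lt(max(abs(p_fit - p_ref)), 1e-6)
})

test_that("the fit is row-order invariant and stable under row duplication", {
  # overlapping classes at a size where the likelihood dominates the
  # penalty, so halving the relative penalty weight barely moves the fit
  withr::with_seed(8, {
    n <- 2000
    X <- matrix(rnorm(n * 2), ncol = 2)
    y <- ifelse(runif(n) < plogis(X[, 1] - 0.5 * X[, 2]), "swing", "stance")
    perm <- sample(n)
  })
  m <- fit_lr(X, y)
  m_perm <- fit_lr(X[perm, ], y[perm])
  expect_equal(lr_probability(m_perm, X), lr_probability(m, X),
               tolerance = 1e-9)

  # duplicating every row only halves the relative penalty strength
  m_dup <- fit_lr(rbind(X, X), c(y, y))
  expect_lt(max(abs(lr_probability(m_dup, X) - lr_probability(m, X))), 1e-3)
})

test_that("models persist to JSON and back losslessly", {
  post <- generate_posture_recordings(small_sim(), n_per_posture = 60)
  m <- calibrate(post, 2, n_per_posture = 50)
  expect_equal(m$condition, 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$w, m$w)
  expect_equal(back$b, m$b)
  expect_equal(back$channel_count, m$channel_count)
  expect_equal(back$condition, m$condition)
})

test_that("threshold derivation: fixed defaults and standing percentiles", {
  expect_equal(derive_thresholds(mode = "fixed"), c(th1 = 0.6, th2 = 0.7))

  # standing gy identically 0 -> thresholds equal the margins
  quiet <- gait_recording(
    t = (1:100) / 50, md = matrix(1, 100, 2),
    quat = matrix(rep(c(1, 0, 0, 0), each = 100), ncol = 4),
    omega = matrix(0, 100, 3), kind = "posture", posture = "single_support")
  th <- derive_thresholds(list(quiet), mode = "standing")
  expect_equal(th, c(th1 = 0.1, th2 = 0.2))

  # known gy series: p95 by a sort-based oracle + margins
  withr::with_seed(3, gy <- runif(200, 0, 0.35))
  drifting <- gait_recording(
    t = (1:200) / 50, md = matrix(1, 200, 2),
    quat = matrix(rep(c(1, 0, 0, 0), each = 200), ncol = 4),
    omega = cbind(0, gy, 0), kind = "posture", posture = "single_support")
  th <- derive_thresholds(list(drifting), mode = "standing")
  s <- sort(gy)
  h <- (length(gy) - 1) * 0.95 + 1
  p95_oracle <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  expect_equal(unname(th), p95_oracle + c(0.1, 0.2), tolerance = 1e-12)
  expect_lt(th[["th1"]], th[["th2"]])

  expect_error(derive_thresholds(list(quiet), mode = "standing",
                                 delta = c(0.2, 0.2)), "th1 >= th2")
  expect_error(derive_thresholds(NULL, mode = "standing"), "required")
})

test_that("the SVM baseline searches a 16-point grid and matches brute force", {
  withr::with_seed(21, {
    n <- 120
    X <- matrix(rnorm(n * 2, sd = 0.6), ncol = 2)
    y <- ifelse(X[, 1] + 0.4 * rnorm(n) > 0, "swing", "stance")
    Xe <- matrix(rnorm(n * 2, sd = 0.6), ncol = 2)
    ye <- ifelse(Xe[, 1] > 0, "swing", "stance")
  })
  res <- fit_svm_baseline(X, y, Xe, ye)
  expect_equal(nrow(res$grid), 16L)
  expect_setequal(unique(res$grid$C), c(1, 10, 100, 1000))
  expect_setequal(unique(res$grid$gamma), c(1e-4, 1e-3, 1e-2, 0.1))

  # brute force: re-fit every grid point and confirm the winner (with the
  # smaller-C-then-smaller-gamma tie break)
  acc <- apply(expand.grid(C = c(1, 10, 100, 1000),
                           gamma = c(1e-4, 1e-3, 1e-2, 0.1)), 1, function(gp) {
    fit <- e1071::svm(X, factor(y, levels = phase_levels()), kernel = "radial",
                      cost = gp[["C"]], gamma = gp[["gamma"]], scale = FALSE)
    mean(as.character(predict(fit, Xe)) == ye)
  })
  gp <- expand.grid(C = c(1, 10, 100, 1000), gamma = c(1e-4, 1e-3, 1e-2, 0.1))
  best <- gp[order(-acc, gp$C, gp$gamma)[1], ]
  expect_equal(res$best_C, best$C)
  expect_equal(res$best_gamma, best$gamma)
  expect_equal(max(res$grid$accuracy), max(acc))
})

test_that("the SVM baseline nails linearly separable toy data somewhere on the grid", {
  withr::with_seed(4, {
    X <- rbind(matrix(rnorm(60, -2, 0.2), ncol = 2),
               matrix(rnorm(60, 2, 0.2), ncol = 2))
  })
  y <- rep(c("stance", "swing"), each = 30)
  res <- fit_svm_baseline(X, y, X, y)
  expect_equal(max(res$grid$accuracy), 1)
})
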