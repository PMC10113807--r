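test_that("ridge readout matches the closed-form solution", {
  # 3-sample, 2-feature toy at lambda = 0.05, no intercept: compare with
  # the closed form computed by explicit matrix inversion
  S <- rbind(c(1, 2), c(0.5, -1), c(2, 0.3))
  y <- c(1.1, -0.4, 2.0)
  fit <- train_ridge(S, y, lambda = 0.05, intercept = FALSE)
  W_hand <- solve(t(S) %*% S + 0.05 * diag(2)) %*% t(S) %*% y
  expect_equal(drop(fit$w_out), drop(W_hand), tolerance = 1e-12)

  # lambda = 0 on a square invertible system: exact interpolation
  S2 <- rbind(c(1, 0.2), c(0.4, 1))
  y2 <- c(0.7, -0.3)
  fit2 <- train_ridge(S2, y2, lambda = 0, intercept = FALSE)
  expect_lt(max(abs(readout_predict(fit2, S2) - y2)), 1e-8)

  # heavy shrinkage drives weights to zero
  fit_small <- train_ridge(S, y, lambda = 0.05, intercept = FALSE)
  fit_big <- train_ridge(S, y, lambda = 1e12, intercept = FALSE)
  expect_lt(sqrt(sum(fit_big$w_out^2)),
            1e-6 * sqrt(sum(fit_small$w_out^2)))

  # singular system at lambda = 0 errors with advice
  S3 <- cbind(1:4, (1:4) * 2)
  expect_error(train_ridge(S3, rnorm(4), lambda = 0, intercept = FALSE),
               "singular; increase lambda")
})

test_that("ridge readout agrees with an independent QR-based route", {
  # ridge as augmented least squares solved by QR: independent of the
  # normal-equations route used by train_ridge
  set.seed(10)
  S <- matrix(rnorm(60), 20, 3)
  y <- S %*% c(1, -2, 0.5) + rnorm(20, 0, 0.1)
  lam <- 0.7
  fit <- train_ridge(S, y, lambda = lam, intercept = FALSE)
  aug <- stats::lm.fit(rbind(S, sqrt(lam) * diag(3)), c(y, rep(0, 3)))
  expect_equal(drop(fit$w_out), unname(aug$coefficients), tolerance = 1e-10)
})

test_that("readout objective is at a minimum and monotone in lambda", {
  set.seed(11)
  S <- matrix(rnorm(100), 25, 4)
  y <- rnorm(25)
  lam <- 0.3
  fit <- train_ridge(S, y, lambda = lam, intercept = FALSE)
  obj <- function(w) sum((y - S %*% w)^2) + lam * sum(w^2)
  w0 <- drop(fit$w_out)
  base <- obj(w0)
  for (j in 1:4) {
    for (eps in c(-1e-3, 1e-3)) {
      w <- w0; w[j] <- w[j] + eps
      expect_gte(obj(w), base)
    }
  }
  # training NMSE non-decreasing in lambda
  nm <- vapply(c(0.001, 0.1, 10, 1000), function(l) {
    f <- train_ridge(S, y, lambda = l, intercept = FALSE)
    nmse(drop(readout_predict(f, S)), y)
  }, numeric(1))
  expect_true(all(diff(nm) >= -1e-12))
})

test_that("readout prediction handles washout, intercept and dimensions", {
  set.seed(12)
  S <- matrix(rnorm(80), 40, 2)
  y <- S %*% c(2, -1) + 3
  fit <- train_ridge(S, y, lambda = 0, intercept = TRUE, washout = 5)
  expect_equal(fit$feature_dim, 3L)
  expect_lt(max(abs(readout_predict(fit, S) - y)), 1e-6)

  # zero weights -> zero output
  fit0 <- fit; fit0$w_out[] <- 0
  expect_true(all(readout_predict(fit0, S) == 0))

  expect_error(readout_predict(fit, matrix(rnorm(12), 4, 3)),
               "feature dimension mismatch")
  expect_error(train_ridge(S, y[1:10]), "lengths differ")
  expect_error(train_ridge(S, y, washout = 40), "washout")
})

test_that("closed-loop generation iterates feedback and flags divergence", {
  # zero-weight model: autonomous run with u = 0
  esn <- esn_reservoir(10, spectral_radius = 0.5, seed = 1)
  model0 <- train_ridge(matrix(rnorm(40), 4, 10), rnorm(4),
                        lambda = 1, intercept = FALSE)
  model0$w_out[] <- 0
  step_fn <- function(x, u) run_reservoir(esn, matrix(u, 1), init = x)$final_state
  out <- closed_loop_generate(step_fn, model0, rep(0.1, 10), 0.5, 50)
  expect_false(out$diverged)
  expect_true(all(out$generated == 0))
  # the reservoir is then driven by u = 0 after the first step
  direct <- run_reservoir(esn, c(0.5, rep(0, 49)), init = rep(0.1, 10))
  expect_equal(out$states$states, direct$states)

  # explosive model flags divergence and stops early
  modelx <- model0; modelx$w_out[] <- 1e7
  outx <- closed_loop_generate(step_fn, modelx, rep(0.1, 10), 0.5, 50)
  expect_true(outx$diverged)
  expect_lt(length(outx$generated), 50)

  # ESN trained on a constant signal stays near it
  cfit <- rc_fit(esn, rep(1, 120) + rnorm(120, 0, 0.001),
                 c(rep(1, 119) + rnorm(119, 0, 0.001), 1),
                 washout = 20, standardize = FALSE)
  sim <- simulate(cfit, nsim = 200)
  expect_false(sim$diverged)
  expect_true(all(abs(sim$generated - 1) < 0.05))
})

test_that("rc_fit composes reservoir, scaling and readout consistently", {
  task <- task_lorenz(300, seed = NA)
  esn <- esn_reservoir(30, seed = 2)
  fit <- rc_fit(esn, task$u, task$y, washout = 30)
  expect_s3_class(fit, "rc_model")
  expect_equal(dim(fitted(fit)), c(300L, 1L))
  expect_equal(residuals(fit), fit$y - fit$fitted)
  expect_equal(ncol(coef(fit)), 31L)  # 30 states + intercept

  # training-set skill is high for this easy task
  sm <- summary(fit)
  expect_lt(sm$train_nmse, 0.1)

  # open-loop predict continues from the final training state:
  # predicting the training input again after a reset is consistent
  p <- predict(fit, task$u[1:20])
  expect_equal(dim(p), c(20L, 1L))
  expect_true(all(is.finite(p)))

  # zero-variance target guard comes from scaling fallback, not an error
  fit2 <- rc_fit(esn, task$u, rep(5, 300), washout = 10)
  expect_true(all(abs(fitted(fit2) - 5) < 1e-6))
})
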