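#' Normalized mean square error
#'
#' \eqn{\sum (pred - obs)^2 / \sum (obs - \bar{obs})^2}: 0 for a perfect
#' prediction, 1 for the constant mean predictor.
#'
#' @param pred,obs Numeric vectors of equal length >= 2.
#' @return Scalar NMSE.
#' @export
nmse <- function(pred, obs) {
  pred <- as.numeric(pred); obs <- as.numeric(obs)
  if (length(pred) != length(obs)) stop("lengths differ")
  if (length(obs) < 2L) stop("need at least 2 observations")
  denom <- sum((obs - mean(obs))^2)
  if (denom == 0) stop("zero-variance observations")
  sum((pred - obs)^2) / denom
}

#' Pearson correlation skill
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return Pearson correlation coefficient.
#' @export
correlation_skill <- function(pred, obs) {
  pred <- as.numeric(pred); obs <- as.numeric(obs)
  if (length(pred) != length(obs)) stop("lengths differ")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("zero-variance input to correlation")
  }
  stats::cor(pred, obs)
}

#' Echo-state-property distance curve
#'
#' Runs the same reservoir from two initial conditions under the identical
#' input and returns the Euclidean distance between the two state
#' trajectories at each step. If the reservoir has the echo state property
#' the distance converges towards zero; under different input sequences it
#' does not.
#'
#' @param run_fn Function \code{(inputs, init) -> state_trajectory}, e.g. a
#'   closure over \code{\link{run_reservoir}}.
#' @param input Input sequence fed to both runs.
#' @param init_a,init_b Two initial states of equal dimension.
#' @return Numeric vector \code{d_t} of per-step distances.
#' @export
esp_distance <- function(run_fn, input, init_a, init_b) {
  if (length(init_a) != length(init_b)) stop("initial states differ in dimension")
  A <- run_fn(input, init_a)$states
  B <- run_fn(input, init_b)$states
  sqrt(rowSums((A - B)^2))
}

#' Summary pass/fail of an ESP distance curve
#'
#' Convergence criterion: the median of the last 10\% of the distance curve
#' is below \code{ratio} times the median of the first 10\%.
#'
#' @param d Distance curve from \code{\link{esp_distance}}.
#' @param ratio Convergence threshold (default 1e-3).
#' @return Logical.
#' @export
esp_converged <- function(d, ratio = 1e-3) {
  n <- length(d)
  k <- max(1L, floor(n / 10))
  stats::median(d[seq.int(n - k + 1L, n)]) <
    ratio * stats::median(d[seq_len(k)])
}

#' Forgetting curve and memory capacity
#'
#' For each lag k = 0..max_lag, trains a ridge readout on the training
#' states to reproduce the input k steps ago and evaluates the Pearson
#' correlation between readout output and true lagged input on the test
#' set. The baseline curve is the lag-k autocorrelation of the test input
#' (what recall skill the input alone provides). Memory capacity is
#' \eqn{\sum_{k \ge 1} r(k)^2}.
#'
#' @param train_states,test_states State matrices or
#'   \code{"state_trajectory"} objects (T x C).
#' @param train_u,test_u Scalar input sequences aligned with the states.
#' @param max_lag Largest lag (default 40).
#' @param lambda,washout,intercept Readout settings (defaults 0.05, 0,
#'   \code{FALSE}).
#' @return List of class \code{"forgetting_curve"} with \code{lag},
#'   \code{r}, \code{baseline} (autocorrelation), and
#'   \code{memory_capacity}.
#' @export
forgetting_curve <- function(train_states, test_states, train_u, test_u,
                             max_lag = 40L, lambda = 0.05, washout = 0L,
                             intercept = FALSE) {
  Str <- if (inherits(train_states, "state_trajectory")) train_states$states else as.matrix(train_states)
  Ste <- if (inherits(test_states, "state_trajectory")) test_states$states else as.matrix(test_states)
  train_u <- as.numeric(train_u); test_u <- as.numeric(test_u)
  if (nrow(Str) != length(train_u) || nrow(Ste) != length(test_u)) {
    stop("states and inputs misaligned")
  }
  if (max_lag >= nrow(Str) / 4) stop("max_lag must be < T/4")
  lags <- 0:max_lag
  r <- numeric(length(lags))
  baseline <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    rows_tr <- seq.int(k + 1L, nrow(Str))
    rows_te <- seq.int(k + 1L, nrow(Ste))
    fit <- train_ridge(Str[rows_tr, , drop = FALSE], train_u[rows_tr - k],
                       lambda = lambda, washout = washout,
                       intercept = intercept)
    pred <- drop(readout_predict(fit, Ste[rows_te, , drop = FALSE]))
    obs <- test_u[rows_te - k]
    r[i] <- suppressWarnings(stats::cor(pred, obs))
    baseline[i] <- suppressWarnings(stats::cor(test_u[rows_te],
                                               test_u[rows_te - k]))
  }
  r[is.na(r)] <- 0
  baseline[is.na(baseline)] <- 0
  structure(list(lag = lags, r = r, baseline = baseline,
                 memory_capacity = sum(r[lags >= 1L]^2)),
            class = "forgetting_curve")
}

#' @export
print.forgetting_curve <- function(x, ...) {
  cat("Forgetting curve: lags 0..", max(x$lag), "\n", sep = "")
  cat("  r(0) =", round(x$r[1L], 3),
      "| memory capacity =", round(x$memory_capacity, 3), "\n")
  invisible(x)
}

#' @export
plot.forgetting_curve <- function(x, ...) {
  graphics::plot(x$lag, x$r, type = "b", col = "red", ylim = range(0, 1, x$r),
                 xlab = "lag (steps)", ylab = "recall correlation r(k)",
                 main = "Forgetting curve", ...)
  graphics::lines(x$lag, x$baseline, type = "b", col = "blue", lty = 3)
  graphics::legend("topright", c("reservoir recall", "input autocorrelation"),
                   col = c("red", "blue"), lty = c(1, 3), bty = "n")
  invisible(x)
}
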