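#' Task signal container
#'
#' Paired input/target sequences for a benchmark task, index-aligned after
#' any horizon shifting.
#'
#' @param u Input sequence (vector or matrix).
#' @param y Target sequence, same length.
#' @param name Task name.
#' @param horizon Prediction horizon in steps (0 for emulation tasks).
#' @param params Named list of generator parameters.
#' @param seed RNG seed used (NA for deterministic generators).
#' @keywords internal
task_signal <- function(u, y, name, horizon = 0L, params = list(), seed = NA) {
  U <- if (is.matrix(u)) u else matrix(as.numeric(u), ncol = 1L)
  Y <- if (is.matrix(y)) y else matrix(as.numeric(y), ncol = 1L)
  if (nrow(U) != nrow(Y)) stop("u and y lengths differ after alignment")
  if (!all(is.finite(U)) || !all(is.finite(Y))) stop("non-finite task signal")
  structure(list(u = drop(U), y = drop(Y), name = name,
                 horizon = as.integer(horizon), params = params, seed = seed),
            class = "task_signal")
}

#' @export
print.task_signal <- function(x, ...) {
  cat("Task signal:", x$name, "| length", NROW(x$u),
      "| horizon", x$horizon, "\n")
  invisible(x)
}

# one fixed-step RK4 update of dx/dt = f(x)
rk4_step <- function(f, x, dt) {
  k1 <- f(x)
  k2 <- f(x + dt / 2 * k1)
  k3 <- f(x + dt / 2 * k2)
  k4 <- f(x + dt * k3)
  x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Lorenz-attractor prediction task
#'
#' Integrates the Lorenz system with fixed-step 4th-order Runge-Kutta,
#' subsamples one observed component, z-scores it, and pairs each value with
#' the value \code{horizon} observation steps ahead as the target.
#'
#' @param n Number of observation steps returned.
#' @param dt Integration step (default 0.02; with the default subsampling of
#'   5 the observation interval is 0.1 time units, a standard benchmark
#'   sampling at which one-step prediction is a genuine task rather than
#'   near-persistence).
#' @param sigma,rho,beta Lorenz parameters (defaults 10, 28, 8/3).
#' @param init Initial state; default \code{c(1, 1, 1)}.
#' @param observe Observed component, 1 (x), 2 (y) or 3 (z).
#' @param horizon Steps ahead for the target (default 1).
#' @param subsample Integration steps per observation (default 5).
#' @param transient Observation steps discarded before returning (default
#'   100, to land on the attractor).
#' @param standardize Z-score the observed component (default \code{TRUE}).
#' @param seed Recorded in the signal's metadata; the generator itself is
#'   deterministic.
#' @return A \code{"task_signal"}.
#' @export
task_lorenz <- function(n, dt = 0.02, sigma = 10, rho = 28, beta = 8 / 3,
                        init = c(1, 1, 1), observe = 1L, horizon = 1L,
                        subsample = 5L, transient = 100L, standardize = TRUE,
                        seed = NA) {
  f <- function(s) c(sigma * (s[2] - s[1]),
                     s[1] * (rho - s[3]) - s[2],
                     s[1] * s[2] - beta * s[3])
  n_obs <- n + horizon + transient
  x <- as.numeric(init)
  obs <- numeric(n_obs)
  for (i in seq_len(n_obs)) {
    for (j in seq_len(subsample)) x <- rk4_step(f, x, dt)
    obs[i] <- x[observe]
  }
  if (transient > 0L) obs <- obs[-seq_len(transient)]
  if (standardize && stats::sd(obs) > 0) {
    obs <- (obs - mean(obs)) / stats::sd(obs)
  }
  u <- obs[seq_len(n)]
  y <- obs[seq_len(n) + horizon]
  task_signal(u, y, "lorenz", horizon,
              params = list(dt = dt, sigma = sigma, rho = rho, beta = beta,
                            observe = observe, subsample = subsample),
              seed = seed)
}

#' NARMA emulation task
#'
#' Nonlinear autoregressive moving-average benchmark driven by an input in
#' [0, 0.5]. Order 2 uses
#' \eqn{y_{t+1} = 0.4 y_t + 0.4 y_t y_{t-1} + 0.6 u_t^3 + 0.1};
#' orders 3-10 use
#' \eqn{y_{t+1} = \alpha y_t + \beta y_t \sum_{i=0}^{n-1} y_{t-i}
#' + \gamma u_{t-n+1} u_t + \delta} with defaults
#' \eqn{\alpha = 0.3, \beta = 0.05, \gamma = 1.5, \delta = 0.1}. History is
#' initialised at zero. The task is emulation: the target at index t is the
#' NARMA output driven by the inputs up to t.
#'
#' @param order NARMA order (2, 3, 4, 5 or 10).
#' @param u Driving input in [0, 0.5]; if \code{NULL}, an i.i.d.
#'   Uniform[0, 0.5] input of length \code{n} is drawn with \code{seed}.
#' @param n Length when \code{u} is generated internally.
#' @param alpha,beta,gamma,delta Coefficients for orders >= 3.
#' @param seed Seed for the internally generated input.
#' @return A \code{"task_signal"} with \code{y[t]} the NARMA response to
#'   \code{u[1:t]}.
#' @export
task_narma <- function(order = 2L, u = NULL, n = 1000L, alpha = 0.3,
                       beta = 0.05, gamma = 1.5, delta = 0.1, seed = 1L) {
  if (!order %in% c(2L, 3L, 4L, 5L, 10L)) stop("unsupported NARMA order")
  if (is.null(u)) {
    set.seed(seed)
    u <- stats::runif(n, 0, 0.5)
  } else {
    seed <- NA
  }
  if (any(u < 0 | u > 0.5)) stop("NARMA input must lie in [0, 0.5]")
  T_len <- length(u)
  y <- numeric(T_len)
  hist_len <- max(order, 2L)
  for (t in seq_len(T_len - 1L)) {
    yt <- y[t]
    if (order == 2L) {
      ytm1 <- if (t >= 2L) y[t - 1L] else 0
      y[t + 1L] <- 0.4 * yt + 0.4 * yt * ytm1 + 0.6 * u[t]^3 + 0.1
    } else {
      idx <- (t - order + 1L):t
      ysum <- sum(y[idx[idx >= 1L]])
      ulag <- if (t - order + 1L >= 1L) u[t - order + 1L] else 0
      y[t + 1L] <- alpha * yt + beta * yt * ysum + gamma * ulag * u[t] + delta
    }
    if (abs(y[t + 1L]) > 1e3) stop("unstable NARMA; rescale input")
  }
  task_signal(u, y, paste0("narma", order), 0L,
              params = list(order = order, alpha = alpha, beta = beta,
                            gamma = gamma, delta = delta),
              seed = seed)
}

#' Mackey-Glass closed-loop generation task
#'
#' Integrates the Mackey-Glass delay differential equation
#' \eqn{dx/dt = \beta x(t-\tau) / (1 + x(t-\tau)^p) - \gamma x(t)} with
#' fixed-step RK4 and linear interpolation of the delayed value, then samples
#' at unit intervals. Defaults (\eqn{\beta = 0.2, \gamma = 0.1, p = 10,
#' \tau = 17}) give the classic chaotic regime. Input and target are the
#' series and its one-step-ahead value, for closed-loop training.
#'
#' @param n Number of unit-interval samples returned.
#' @param dt Internal integration step (default 0.1).
#' @param tau_delay Delay \eqn{\tau} (default 17).
#' @param beta_mg,gamma_mg Production/decay rates (defaults 0.2, 0.1).
#' @param exponent Hill exponent \eqn{p} (default 10).
#' @param history Constant pre-history value on \eqn{[-\tau, 0]}
#'   (default 1.2).
#' @param sample_step Spacing of returned samples in time units (default 1).
#' @param transient Samples discarded before returning (default 100).
#' @return A \code{"task_signal"} with horizon 1.
#' @export
task_mackey_glass <- function(n, dt = 0.1, tau_delay = 17, beta_mg = 0.2,
                              gamma_mg = 0.1, exponent = 10, history = 1.2,
                              sample_step = 1.0, transient = 100L) {
  if (tau_delay <= 0) stop("tau_delay must be > 0")
  n_samp <- n + 1L + transient
  total_time <- n_samp * sample_step
  n_steps <- ceiling(total_time / dt)
  delay_steps <- tau_delay / dt
  # buffer holds x on the integration grid; index 1 is t = -tau
  n_hist <- ceiling(delay_steps) + 1L
  x <- c(rep(history, n_hist), numeric(n_steps))
  delayed <- function(i_now) {
    # linear interpolation of x(t - tau) on the grid
    pos <- i_now - delay_steps
    lo <- floor(pos); frac <- pos - lo
    x[lo] * (1 - frac) + x[lo + 1L] * frac
  }
  for (i in seq_len(n_steps)) {
    idx <- n_hist + i - 1L
    xd0 <- delayed(idx)          # x(t - tau)
    xd1 <- delayed(idx + 0.5)    # x(t + dt/2 - tau)
    xd2 <- delayed(idx + 1)      # x(t + dt - tau)
    xt <- x[idx]
    f <- function(xx, xd) beta_mg * xd / (1 + xd^exponent) - gamma_mg * xx
    k1 <- f(xt, xd0)
    k2 <- f(xt + dt / 2 * k1, xd1)
    k3 <- f(xt + dt / 2 * k2, xd1)
    k4 <- f(xt + dt * k3, xd2)
    x[idx + 1L] <- xt + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  grid_per_samp <- sample_step / dt
  samp_idx <- n_hist + round(seq_len(n_samp) * grid_per_samp)
  s <- x[samp_idx]
  if (transient > 0L) s <- s[-seq_len(transient)]
  task_signal(s[seq_len(n)], s[seq_len(n) + 1L], "mackey_glass", 1L,
              params = list(dt = dt, tau_delay = tau_delay, beta_mg = beta_mg,
                            gamma_mg = gamma_mg, exponent = exponent,
                            history = history, sample_step = sample_step))
}

#' Uniform random input signal
#'
#' I.i.d. Uniform[lo, hi] input, used e.g. as a random temperature sequence
#' for memory-capacity and echo-state-property tests. The target is the
#' input itself (lag/horizon handling is done by the evaluation functions).
#'
#' @param n Length.
#' @param lo,hi Range (default 0, 1).
#' @param seed RNG seed.
#' @return A \code{"task_signal"}.
#' @export
task_uniform <- function(n, lo = 0, hi = 1, seed = 1L) {
  if (lo >= hi) stop("lo must be < hi")
  set.seed(seed)
  u <- stats::runif(n, lo, hi)
  task_signal(u, u, "uniform", 0L, params = list(lo = lo, hi = hi),
              seed = seed)
}
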