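#' Fit a reservoir-computing model
#'
#' The central fitting function: drives one reservoir (or several, which are
#' species-multiplexed) with the input signal, discards a washout transient,
#' and trains a ridge-regression readout to map reservoir states to the
#' target signal. Only the readout is trained; the reservoir dynamics stay
#' fixed, which is what makes the scheme reservoir computing.
#'
#' @param reservoir A \code{"reservoir"} object or a list of them. A list is
#'   multiplexed: each reservoir is run independently on the same input and
#'   their state trajectories are concatenated column-wise, so the effective
#'   reservoir size is the sum of the individual state dimensions.
#' @param u Input signal: numeric vector or T x input_dim matrix.
#' @param y Target signal: numeric vector or T x output_dim matrix, row
#'   aligned with \code{u}.
#' @param lambda Ridge penalty (default 0.05).
#' @param washout Initial steps excluded from readout training (default 50).
#' @param intercept Include a bias term in the readout (default \code{TRUE}).
#' @param standardize Z-score input and target with training statistics
#'   (stored in the model; predictions are returned on the original scale).
#'   Default \code{TRUE}.
#' @return Object of class \code{"rc_model"}; see
#'   \code{\link{predict.rc_model}}, \code{\link{simulate.rc_model}}.
#' @examples
#' task <- task_lorenz(n = 400, seed = 1)
#' res <- esn_reservoir(N = 50, seed = 1)
#' fit <- rc_fit(res, task$u, task$y, washout = 50)
#' summary(fit)
#' @export
rc_fit <- function(reservoir, u, y, lambda = 0.05, washout = 50L,
                   intercept = TRUE, standardize = TRUE) {
  reservoirs <- if (inherits(reservoir, "reservoir")) list(reservoir) else reservoir
  if (!all(vapply(reservoirs, inherits, logical(1), "reservoir"))) {
    stop("reservoir must be a reservoir object or a list of them")
  }
  U <- if (is.matrix(u)) u else matrix(as.numeric(u), ncol = 1L)
  Y <- if (is.matrix(y)) y else matrix(as.numeric(y), ncol = 1L)
  if (nrow(U) != nrow(Y)) stop("u and y lengths differ")

  if (standardize) {
    u_center <- colMeans(U); u_scale <- apply(U, 2L, stats::sd)
    y_center <- colMeans(Y); y_scale <- apply(Y, 2L, stats::sd)
    u_scale[u_scale == 0] <- 1; y_scale[y_scale == 0] <- 1
  } else {
    u_center <- rep(0, ncol(U)); u_scale <- rep(1, ncol(U))
    y_center <- rep(0, ncol(Y)); y_scale <- rep(1, ncol(Y))
  }
  Us <- sweep(sweep(U, 2L, u_center), 2L, u_scale, "/")
  Ys <- sweep(sweep(Y, 2L, y_center), 2L, y_scale, "/")

  trajs <- lapply(reservoirs, run_reservoir, inputs = Us)
  traj <- multiplex_states(trajs)
  readout <- train_ridge(traj, Ys, lambda = lambda, washout = washout,
                         intercept = intercept)
  fitted_s <- readout_predict(readout, traj)
  fitted <- sweep(sweep(fitted_s, 2L, y_scale, "*"), 2L, y_center, "+")
  structure(
    list(reservoirs = reservoirs, readout = readout, trajectory = traj,
         u = U, y = Y,
         scaling = list(u_center = u_center, u_scale = u_scale,
                        y_center = y_center, y_scale = y_scale),
         fitted = fitted, washout = washout, lambda = lambda,
         final_states = lapply(trajs, `[[`, "final_state"),
         call = match.call()),
    class = "rc_model")
}

#' @export
print.rc_model <- function(x, ...) {
  dims <- vapply(x$reservoirs, function(r) length(r$state), integer(1))
  cat("Reservoir-computing model\n")
  cat("  reservoirs:", length(x$reservoirs),
      "| total reservoir size:", sum(dims), "\n")
  cat("  readout: ridge (lambda =", x$lambda, "), washout =", x$washout, "\n")
  cat("  training length:", nrow(x$u), "steps\n")
  invisible(x)
}

#' @export
summary.rc_model <- function(object, ...) {
  keep <- seq.int(object$washout + 1L, nrow(object$y))
  obs <- object$y[keep, 1L]
  prd <- object$fitted[keep, 1L]
  out <- list(model = object,
              train_nmse = nmse(prd, obs),
              train_rho = correlation_skill(prd, obs),
              n_train = length(keep))
  class(out) <- "summary.rc_model"
  out
}

#' @export
print.summary.rc_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training skill (post-washout, n = %d): NMSE = %.4g, rho = %.4g\n",
              x$n_train, x$train_nmse, x$train_rho))
  invisible(x)
}

#' @export
coef.rc_model <- function(object, ...) object$readout$w_out

#' @export
residuals.rc_model <- function(object, ...) object$y - object$fitted

#' @export
fitted.rc_model <- function(object, ...) object$fitted

#' Predict from a fitted reservoir-computing model
#'
#' Continues each reservoir from its state at the end of training, drives it
#' with the new input, and applies the trained readout (open loop).
#'
#' @param object An \code{"rc_model"}.
#' @param u New input signal (vector or matrix on the original scale).
#' @param ... Unused.
#' @return Matrix of predictions on the original target scale.
#' @export
predict.rc_model <- function(object, u, ...) {
  U <- if (is.matrix(u)) u else matrix(as.numeric(u), ncol = 1L)
  sc <- object$scaling
  Us <- sweep(sweep(U, 2L, sc$u_center), 2L, sc$u_scale, "/")
  trajs <- mapply(function(r, s) run_reservoir(r, Us, init = s),
                  object$reservoirs, object$final_states, SIMPLIFY = FALSE)
  traj <- multiplex_states(trajs)
  Z <- readout_predict(object$readout, traj)
  sweep(sweep(Z, 2L, sc$y_scale, "*"), 2L, sc$y_center, "+")
}

#' Closed-loop generation from a fitted model
#'
#' For a model trained to predict the next input value from the reservoir
#' state, runs the reservoir autonomously: the readout output is fed back as
#' the next input. Divergence (output magnitude above 1e6) stops the run
#' early and is flagged rather than raised.
#'
#' @param object An \code{"rc_model"} with output_dim equal to input_dim.
#' @param nsim Number of steps to generate.
#' @param seed Unused (the model is deterministic); kept for the generic.
#' @param init_input First input, default the last training input.
#' @param ... Unused.
#' @return List with \code{generated} (original input scale), \code{states},
#'   \code{diverged}.
#' @export
simulate.rc_model <- function(object, nsim = 100L, seed = NULL,
                              init_input = NULL, ...) {
  sc <- object$scaling
  if (length(sc$u_center) != length(sc$y_center)) {
    stop("closed loop requires output_dim == input_dim")
  }
  dims <- vapply(object$reservoirs, function(r) length(r$state), integer(1))
  offs <- cumsum(c(0L, dims))
  # the fed-back value arrives on the standardized *target* scale; convert it
  # to the standardized *input* scale before driving the reservoirs
  step_fn <- function(x, z) {
    u <- (z * sc$y_scale + sc$y_center - sc$u_center) / sc$u_scale
    unlist(lapply(seq_along(object$reservoirs), function(i) {
      xi <- x[seq.int(offs[i] + 1L, offs[i + 1L])]
      r <- object$reservoirs[[i]]
      run_reservoir(r, matrix(u, nrow = 1L), init = xi)$final_state
    }))
  }
  if (is.null(init_input)) init_input <- object$u[nrow(object$u), ]
  z0 <- (as.numeric(init_input) - sc$y_center) / sc$y_scale
  x0 <- unlist(object$final_states)
  res <- closed_loop_generate(step_fn, object$readout, x0, z0, nsim)
  gen <- res$generated * sc$y_scale[1L] + sc$y_center[1L]
  list(generated = gen, states = res$states, diverged = res$diverged)
}

#' @export
plot.rc_model <- function(x, n = 200L, ...) {
  keep <- seq.int(x$washout + 1L, nrow(x$y))
  keep <- keep[seq_len(min(n, length(keep)))]
  graphics::plot(keep, x$y[keep, 1L], type = "l", col = "grey30",
                 xlab = "time step", ylab = "signal",
                 main = "Observed (grey) vs fitted (red)", ...)
  graphics::lines(keep, x$fitted[keep, 1L], col = "red")
  invisible(x)
}
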