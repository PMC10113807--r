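#' Train a linear readout by ridge regression
#'
#' Solves \eqn{W_{out} = (S^\top S + \lambda I)^{-1} S^\top Y} on the state
#' rows after the washout, where \code{S} optionally includes a bias column.
#' The washout discards the reservoir's initial transient so the readout is
#' fitted only on states that have forgotten the arbitrary initial condition.
#'
#' @param states A \code{"state_trajectory"} or T x F numeric matrix.
#' @param targets Numeric vector or T x output_dim matrix, row-aligned with
#'   the states.
#' @param lambda Ridge penalty, >= 0 (default 0.05).
#' @param washout Leading rows discarded before fitting (default 0).
#' @param intercept Include a bias column (default \code{TRUE}).
#' @return Object of class \code{"ridge_readout"} with \code{w_out}
#'   (output_dim x F(+1) matrix, bias first when present), \code{lambda},
#'   \code{washout}, \code{intercept}, \code{feature_dim}.
#' @export
train_ridge <- function(states, targets, lambda = 0.05, washout = 0L,
                        intercept = TRUE) {
  S <- if (inherits(states, "state_trajectory")) states$states else as.matrix(states)
  Y <- if (is.matrix(targets)) targets else matrix(as.numeric(targets), ncol = 1L)
  if (nrow(S) != nrow(Y)) stop("states and targets lengths differ")
  if (lambda < 0) stop("lambda must be >= 0")
  if (washout >= nrow(S)) stop("washout leaves no training rows")
  keep <- seq.int(washout + 1L, nrow(S))
  S <- S[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  if (intercept) S <- cbind(1, S)
  G <- crossprod(S) + lambda * diag(ncol(S))
  W <- tryCatch(solve(G, crossprod(S, Y)),
                error = function(e) stop("singular; increase lambda"))
  if (lambda == 0 && rcond(G) < 1e-14) stop("singular; increase lambda")
  structure(list(w_out = t(W), lambda = lambda, washout = washout,
                 intercept = intercept, feature_dim = ncol(S)),
            class = "ridge_readout")
}

#' Apply a trained readout to reservoir states
#'
#' @param model A \code{"ridge_readout"}.
#' @param states A \code{"state_trajectory"} or T x F matrix (without bias
#'   column; it is added automatically if the model has an intercept).
#' @return T x output_dim matrix of outputs \eqn{z_t = W_{out} X_t}.
#' @export
readout_predict <- function(model, states) {
  S <- if (inherits(states, "state_trajectory")) states$states else as.matrix(states)
  if (model$intercept) S <- cbind(1, S)
  if (ncol(S) != model$feature_dim) {
    stop("feature dimension mismatch: model expects ",
         model$feature_dim - model$intercept, " state columns, got ",
         ncol(S) - model$intercept)
  }
  S %*% t(model$w_out)
}

#' Closed-loop autonomous generation
#'
#' Feeds the readout output back as the next input:
#' \eqn{u_{t+1} = z_t = W_{out} X_t}, \eqn{X_{t+1} =
#' \mathrm{step}(X_t, u_{t+1})}. Used after training the readout for
#' one-step-ahead prediction of the input signal itself, so the reservoir
#' runs autonomously and generates its own attractor. Stops early and sets a
#' divergence flag if the output magnitude exceeds 1e6.
#'
#' @param step_fn Function \code{(state, u) -> state}, one reservoir update.
#' @param model A \code{"ridge_readout"} trained to predict the next input
#'   from the state.
#' @param init_state Initial reservoir state.
#' @param init_input First input fed to the reservoir.
#' @param n_steps Number of autonomous steps.
#' @return List with \code{generated} (numeric vector of outputs),
#'   \code{states} (a \code{"state_trajectory"}), and \code{diverged}
#'   (logical).
#' @export
closed_loop_generate <- function(step_fn, model, init_state, init_input,
                                 n_steps) {
  x <- as.numeric(init_state)
  u <- as.numeric(init_input)
  gen <- numeric(n_steps)
  states <- matrix(NA_real_, nrow = n_steps, ncol = length(x))
  diverged <- FALSE
  t_stop <- n_steps
  for (t in seq_len(n_steps)) {
    x <- step_fn(x, u)
    if (!all(is.finite(x)) || any(abs(x) > 1e6)) {
      diverged <- TRUE; t_stop <- t - 1L; break
    }
    states[t, ] <- x
    z <- drop(readout_predict(model, matrix(x, nrow = 1L)))
    if (!all(is.finite(z)) || any(abs(z) > 1e6)) {
      diverged <- TRUE; t_stop <- t; break
    }
    gen[t] <- z[1L]
    u <- z
  }
  keep <- seq_len(t_stop)
  list(generated = gen[keep],
       states = structure(list(states = states[keep, , drop = FALSE],
                               final_state = x),
                          class = "state_trajectory"),
       diverged = diverged)
}
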