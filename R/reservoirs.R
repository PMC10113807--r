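#' Random input-weight matrix
#'
#' Input weights connecting the input signal to the reservoir state. Entries
#' are i.i.d. Uniform[-1, 1] scaled by \code{scale}; a fraction
#' \code{sparsity} of entries (exact count \code{round(sparsity * length)})
#' is then set to exactly zero, chosen at random. Reproducible by seed.
#'
#' @param state_dim Number of reservoir state variables (rows).
#' @param input_dim Input dimension (columns), default 1.
#' @param scale Scaling of the uniform entries; default 0.3.
#' @param sparsity Fraction of entries forced to zero, in [0, 1]; default 0.
#' @param seed Integer RNG seed.
#' @return Object of class \code{"input_weights"} with fields
#'   \code{matrix}, \code{scale}, \code{sparsity}, \code{seed}.
#' @export
make_input_weights <- function(state_dim, input_dim = 1L, scale = 0.3,
                               sparsity = 0, seed = 1L) {
  if (sparsity < 0 || sparsity > 1) stop("sparsity must be in [0, 1]")
  if (scale <= 0) stop("scale must be > 0")
  n <- state_dim * input_dim
  set.seed(seed)
  W <- matrix(stats::runif(n, -1, 1) * scale, nrow = state_dim, ncol = input_dim)
  nzero <- round(sparsity * n)
  if (nzero > 0) W[sample.int(n, nzero)] <- 0
  structure(list(matrix = W, scale = scale, sparsity = sparsity, seed = seed),
            class = "input_weights")
}

#' Ecological reservoir from a time series (simplex-projection reservoir)
#'
#' Builds a reservoir whose internal dynamics are the empirical dynamics of a
#' single species' time series, reconstructed by time-delay embedding. One
#' step of the reservoir applies simplex projection to the current state
#' (scenario exploration) and injects the input through the input weights:
#' either \code{X' = W_in u + f_simp(X)} (\code{variant =
#' "project_then_add"}, the default) or \code{X' = f_simp(X + W_in u)}
#' (\code{variant = "add_then_project"}).
#'
#' @param series Numeric time series from which the reservoir dynamics are
#'   reconstructed (used as the simplex library).
#' @param E Embedding dimension; if \code{NULL} it is chosen by
#'   \code{\link{select_embedding_dimension}}.
#' @param E_max Upper bound for automatic dimension selection.
#' @param input_dim Input dimension.
#' @param input_scale,sparsity,seed Passed to \code{\link{make_input_weights}}
#'   (state_dim = E).
#' @param variant Order of input injection and simplex projection.
#' @param init Initial E-dimensional state; default is the last embedded
#'   vector of the library.
#' @return Object of class \code{c("erc_reservoir", "reservoir")}.
#' @examples
#' x <- simulate_community(community_params(S = 1, seed = 1), n = 200)[, 1]
#' res <- erc_reservoir(x, E = 3, seed = 2)
#' traj <- run_reservoir(res, runif(50, -1, 1))
#' dim(traj$states)  # 50 x 3
#' @export
erc_reservoir <- function(series, E = NULL, E_max = 10L, input_dim = 1L,
                          input_scale = 0.3, sparsity = 0, seed = 1L,
                          variant = c("project_then_add", "add_then_project"),
                          init = NULL) {
  variant <- match.arg(variant)
  if (is.null(E)) {
    E <- select_embedding_dimension(series, E_max = E_max, tau = 1L)$E
  }
  emb <- embed_series(series, E, tau = 1L)
  w_in <- make_input_weights(E, input_dim, scale = input_scale,
                             sparsity = sparsity, seed = seed)
  if (is.null(init)) init <- emb$library[nrow(emb$library), ]
  if (length(init) != E) stop("init must have length E")
  structure(list(embedding = emb, w_in = w_in, state = as.numeric(init),
                 variant = variant),
            class = c("erc_reservoir", "reservoir"))
}

#' @export
print.erc_reservoir <- function(x, ...) {
  cat("Ecological (simplex-projection) reservoir\n")
  cat("  E =", x$embedding$E, "| library rows:", nrow(x$embedding$library),
      "| variant:", x$variant, "\n")
  invisible(x)
}

#' One update of an ecological reservoir state
#'
#' @param reservoir An \code{"erc_reservoir"}.
#' @param u Input vector for this step (length \code{input_dim}).
#' @param state State to update; default the reservoir's stored state.
#' @return The new E-dimensional state.
#' @export
erc_step <- function(reservoir, u, state = reservoir$state) {
  Win_u <- drop(reservoir$w_in$matrix %*% as.numeric(u))
  if (reservoir$variant == "project_then_add") {
    Win_u + simplex_state_update(reservoir$embedding, state)
  } else {
    simplex_state_update(reservoir$embedding, state + Win_u)
  }
}

#' Two-species Lotka-Volterra map
#'
#' One iterate of the discrete-time two-species competition model
#' \eqn{x' = x (r_x - r_x x + \beta_{xy} y)},
#' \eqn{y' = y (r_y - r_y y + \beta_{yx} x)}: logistic self-limitation with
#' the same growth rate on the linear and squared terms, plus interspecific
#' interaction. Extinction is absorbing (a species at 0 stays at 0).
#'
#' @param state Numeric length-2 vector \code{c(x, y)}.
#' @param params List with \code{r_x}, \code{r_y}, \code{beta_xy},
#'   \code{beta_yx}; see \code{\link{lv_params}}.
#' @return Length-2 vector, the next state.
#' @export
lv_map_step <- function(state, params) {
  x <- state[1L]; y <- state[2L]
  c(x * (params$r_x - params$r_x * x + params$beta_xy * y),
    y * (params$r_y - params$r_y * y + params$beta_yx * x))
}

#' Parameters of the two-species Lotka-Volterra toy reservoir
#'
#' Defaults are the grid-searched values used throughout:
#' \eqn{r_x = 3.0}, \eqn{r_y = 2.7}, \eqn{\beta_{xy} = -0.2},
#' \eqn{\beta_{yx} = 0.2}.
#'
#' @param r_x,r_y Per-species growth rates.
#' @param beta_xy Effect of species y on species x.
#' @param beta_yx Effect of species x on species y.
#' @export
lv_params <- function(r_x = 3.0, r_y = 2.7, beta_xy = -0.2, beta_yx = 0.2) {
  p <- list(r_x = r_x, r_y = r_y, beta_xy = beta_xy, beta_yx = beta_yx)
  if (!all(vapply(p, is.finite, logical(1)))) stop("LV parameters must be finite")
  structure(p, class = "lv_params")
}

#' Lotka-Volterra toy reservoir (reservoir size 2)
#'
#' A minimal explicit-equation ecological reservoir: the state is the
#' two-species abundance vector and one step is
#' \eqn{X_{t+1} = W_{in} u_t + g(X_t)} with \eqn{g} the LV map and identity
#' outer activation, so the update can be read as population dynamics under
#' addition/removal of individuals.
#'
#' @param params \code{\link{lv_params}}.
#' @param input_dim,input_scale,sparsity,seed Input-weight settings.
#' @param init Initial abundances, default \code{c(0.5, 0.5)}.
#' @return Object of class \code{c("lv_reservoir", "reservoir")}.
#' @export
lv_reservoir <- function(params = lv_params(), input_dim = 1L,
                         input_scale = 0.3, sparsity = 0, seed = 1L,
                         init = c(0.5, 0.5)) {
  w_in <- make_input_weights(2L, input_dim, scale = input_scale,
                             sparsity = sparsity, seed = seed)
  structure(list(params = params, w_in = w_in, state = as.numeric(init)),
            class = c("lv_reservoir", "reservoir"))
}

#' Echo state network reservoir
#'
#' Random recurrent network baseline: \eqn{X_{t+1} = f(W_{in} u_t + W X_t)}.
#' Recurrent weights are i.i.d. Uniform[-1, 1] with the given density and
#' rescaled so the spectral radius (largest absolute eigenvalue) equals the
#' requested value.
#'
#' @param N Number of reservoir units.
#' @param input_dim Input dimension.
#' @param spectral_radius Target spectral radius (default 0.95).
#' @param density Fraction of nonzero recurrent weights in (0, 1].
#' @param input_scale,sparsity Input-weight settings.
#' @param seed RNG seed (recurrent matrix and input weights).
#' @param activation \code{"tanh"} (default) or \code{"identity"}.
#' @param init Initial state, default zeros.
#' @return Object of class \code{c("esn_reservoir", "reservoir")}.
#' @export
esn_reservoir <- function(N, input_dim = 1L, spectral_radius = 0.95,
                          density = 0.1, input_scale = 0.3, sparsity = 0,
                          seed = 1L, activation = c("tanh", "identity"),
                          init = NULL) {
  activation <- match.arg(activation)
  if (N < 1L) stop("N must be >= 1")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (spectral_radius <= 0) stop("spectral_radius must be > 0")
  W <- NULL
  s <- seed
  repeat {
    set.seed(s)
    W <- matrix(stats::runif(N * N, -1, 1), N, N)
    mask <- matrix(stats::runif(N * N) < density, N, N)
    W[!mask] <- 0
    rad <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (rad > 0) break
    message("all-zero recurrent draw at seed ", s, "; redrawing with seed ",
            s + 1L)
    s <- s + 1L
  }
  W <- W * (spectral_radius / rad)
  w_in <- make_input_weights(N, input_dim, scale = input_scale,
                             sparsity = sparsity, seed = seed + 10000L)
  if (is.null(init)) init <- rep(0, N)
  structure(list(N = N, W = W, w_in = w_in, activation = activation,
                 spectral_radius = spectral_radius, density = density,
                 seed = seed, state = as.numeric(init)),
            class = c("esn_reservoir", "reservoir"))
}

#' Run a reservoir over an input sequence
#'
#' Iterates the reservoir map over the rows of \code{inputs} and records the
#' state after each input is consumed. Aborts with an error naming the step
#' if any state coordinate exceeds 1e6 in magnitude (divergence guard).
#'
#' @param reservoir A \code{"reservoir"} object (\code{erc_reservoir},
#'   \code{lv_reservoir} or \code{esn_reservoir}).
#' @param inputs Numeric vector (scalar input) or T x input_dim matrix.
#' @param init Optional initial state overriding the reservoir's.
#' @param ... Unused.
#' @return Object of class \code{"state_trajectory"}: list with
#'   \code{states} (T x state_dim matrix) and \code{final_state}.
#' @export
run_reservoir <- function(reservoir, inputs, init = NULL, ...) {
  UseMethod("run_reservoir")
}

run_loop <- function(step_fn, inputs, init, dim_names = NULL) {
  U <- if (is.matrix(inputs)) inputs else matrix(as.numeric(inputs), ncol = 1L)
  T_len <- nrow(U)
  states <- matrix(NA_real_, nrow = T_len, ncol = length(init))
  x <- as.numeric(init)
  for (t in seq_len(T_len)) {
    x <- step_fn(x, U[t, ])
    if (!all(is.finite(x)) || any(abs(x) > 1e6)) {
      stop("diverged at step ", t)
    }
    states[t, ] <- x
  }
  structure(list(states = states, final_state = x),
            class = "state_trajectory")
}

#' @export
run_reservoir.erc_reservoir <- function(reservoir, inputs, init = NULL, ...) {
  if (is.null(init)) init <- reservoir$state
  run_loop(function(x, u) erc_step(reservoir, u, state = x), inputs, init)
}

#' @export
run_reservoir.lv_reservoir <- function(reservoir, inputs, init = NULL, ...) {
  if (is.null(init)) init <- reservoir$state
  p <- reservoir$params
  Win <- reservoir$w_in$matrix
  run_loop(function(x, u) drop(Win %*% u) + lv_map_step(x, p), inputs, init)
}

#' @export
run_reservoir.esn_reservoir <- function(reservoir, inputs, init = NULL, ...) {
  if (is.null(init)) init <- reservoir$state
  W <- reservoir$W
  Win <- reservoir$w_in$matrix
  f <- if (reservoir$activation == "tanh") tanh else identity
  run_loop(function(x, u) f(drop(Win %*% u) + drop(W %*% x)), inputs, init)
}

#' Species-multiplex reservoir trajectories
#'
#' Column-wise concatenation of state trajectories from reservoirs driven by
#' the same input: the multiplexed reservoir size is the sum of the
#' individual state dimensions.
#'
#' @param trajectories List of \code{"state_trajectory"} objects with equal
#'   length T.
#' @return A \code{"state_trajectory"} whose states matrix has
#'   \code{sum(state_dim_i)} columns, in list order.
#' @export
multiplex_states <- function(trajectories) {
  stopifnot(length(trajectories) >= 1L)
  Ts <- vapply(trajectories, function(tr) nrow(tr$states), integer(1))
  if (length(unique(Ts)) != 1L) stop("trajectories have mismatched lengths")
  structure(
    list(states = do.call(cbind, lapply(trajectories, `[[`, "states")),
         final_state = unlist(lapply(trajectories, `[[`, "final_state"))),
    class = "state_trajectory")
}
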