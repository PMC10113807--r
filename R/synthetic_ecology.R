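#' Parameters for a synthetic multi-species community
#'
#' Discrete-time S-species community with logistic self-limitation and
#' pairwise interactions, the S-species generalisation of the two-species
#' Lotka-Volterra toy model, plus additive process noise. Defaults draw
#' growth rates from Uniform[2.4, 3.2], spanning noisy-equilibrium through
#' period-2/chaotic-edge logistic regimes, and sparse interactions from
#' Uniform[-0.3, 0.3] at connectance 0.3. This mixture produces sustained,
#' nonlinear, interaction- and noise-driven fluctuations whose reconstructed
#' dynamics are predominantly mean-reverting — the regime in which
#' simplex-projection reservoirs show the echo state property.
#'
#' @param S Number of species.
#' @param r Growth rates (length S); default drawn from Uniform[2.4, 3.2].
#' @param B S x S interaction matrix with zero diagonal; default sparse
#'   random.
#' @param connectance Fraction of nonzero off-diagonal interactions used
#'   when \code{B} is drawn (default 0.3).
#' @param process_noise_sd SD of additive process noise (default 0.02).
#' @param obs_noise_sd SD of additive observation noise (default 0).
#' @param burn_in Steps discarded before returning (default 200).
#' @param seed RNG seed (draws r, B and all noise).
#' @export
community_params <- function(S, r = NULL, B = NULL, connectance = 0.3,
                             process_noise_sd = 0.02, obs_noise_sd = 0,
                             burn_in = 200L, seed = 1L) {
  if (S < 1L) stop("S must be >= 1")
  set.seed(seed)
  if (is.null(r)) r <- stats::runif(S, 2.4, 3.2)
  if (is.null(B)) {
    B <- matrix(stats::runif(S * S, -0.3, 0.3), S, S)
    mask <- matrix(stats::runif(S * S) < connectance, S, S)
    B[!mask] <- 0
    diag(B) <- 0
  }
  if (length(r) != S || !all(dim(B) == S)) stop("r/B dimensions must match S")
  if (any(diag(B) != 0)) stop("B must have zero diagonal")
  structure(list(S = S, r = r, B = B, process_noise_sd = process_noise_sd,
                 obs_noise_sd = obs_noise_sd, burn_in = as.integer(burn_in),
                 seed = seed),
            class = "community_params")
}

#' Simulate a synthetic multi-species community time series
#'
#' Iterates
#' \eqn{x_{i,t+1} = \max(0, x_{i,t}(r_i - r_i x_{i,t} +
#' \sum_{j \ne i} B_{ij} x_{j,t}) + \epsilon_{i,t})} with
#' \eqn{\epsilon \sim N(0, \sigma_{proc})}, discards the burn-in, and
#' optionally adds observation noise. Abundances are truncated at zero
#' (extinction is absorbing in the deterministic part). A warning is issued
#' if every species goes extinct.
#'
#' @param params A \code{\link{community_params}}.
#' @param n Number of time steps returned (after burn-in).
#' @param init Initial abundances, default Uniform[0.2, 0.8].
#' @return An n x S matrix of abundances (column per species).
#' @export
simulate_community <- function(params, n, init = NULL) {
  stopifnot(inherits(params, "community_params"), n >= 1L)
  S <- params$S
  set.seed(params$seed + 1L)
  if (is.null(init)) init <- stats::runif(S, 0.2, 0.8)
  total <- n + params$burn_in
  X <- matrix(NA_real_, nrow = total, ncol = S)
  x <- as.numeric(init)
  r <- params$r; B <- params$B
  for (t in seq_len(total)) {
    inter <- drop(B %*% x)
    eps <- if (params$process_noise_sd > 0) {
      stats::rnorm(S, 0, params$process_noise_sd)
    } else 0
    x <- pmax(0, x * (r - r * x + inter) + eps)
    X[t, ] <- x
  }
  X <- X[seq.int(params$burn_in + 1L, total), , drop = FALSE]
  if (all(X[nrow(X), ] == 0)) warning("all species extinct")
  if (params$obs_noise_sd > 0) {
    X <- pmax(X + matrix(stats::rnorm(length(X), 0, params$obs_noise_sd),
                         nrow = nrow(X)), 0)
  }
  colnames(X) <- paste0("sp", seq_len(S))
  X
}

#' Parameters of the temperature-driven population surrogate
#'
#' A documented surrogate for a temperature-driven unicellular population
#' observed several times per input step: the chamber temperature follows a
#' first-order lag toward the set temperature, the population follows a
#' Ricker map with temperature-dependent growth rate and carrying capacity
#' (both peaked, piecewise-linear responses), and the observed count is a
#' noisy reading with Poisson-like (variance proportional to mean) error.
#' Growth rates below 1 keep the map contracting, so trajectories started
#' from different population sizes synchronise under a common temperature
#' sequence.
#'
#' @param K_peak Carrying capacity at the thermal optimum (cells per frame).
#' @param r_peak Per-substep growth rate at the optimum (default 0.5; keep
#'   below 2 for a stable, contracting map).
#' @param T_opt Thermal optimum in deg C (default 30).
#' @param T_range Temperatures (deg C) at which K and r fall to
#'   \code{floor_frac} of their peaks (default \code{c(10, 40)}).
#' @param floor_frac Fraction of the peak retained at the range edges
#'   (default 0.2; keeps K positive over the input range).
#' @param thermal_lag First-order inertia coefficient in (0, 1]: fraction of
#'   the gap to the set temperature closed per substep (default 0.35).
#' @param substeps_per_input Observations per input step (default 5).
#' @param obs_noise_sd Observation noise scale; the reading SD is
#'   \code{obs_noise_sd * sqrt(p)} (0 = noise-free).
#' @param seed RNG seed.
#' @export
driven_population_params <- function(K_peak = 100, r_peak = 0.5, T_opt = 30,
                                     T_range = c(10, 40), floor_frac = 0.2,
                                     thermal_lag = 0.35,
                                     substeps_per_input = 5L,
                                     obs_noise_sd = 0, seed = 1L) {
  if (thermal_lag <= 0 || thermal_lag > 1) stop("thermal_lag must be in (0, 1]")
  if (substeps_per_input < 1L) stop("substeps_per_input must be >= 1")
  if (floor_frac <= 0) stop("floor_frac must be > 0 (K must stay positive)")
  structure(list(K_peak = K_peak, r_peak = r_peak, T_opt = T_opt,
                 T_range = T_range, floor_frac = floor_frac,
                 thermal_lag = thermal_lag,
                 substeps_per_input = as.integer(substeps_per_input),
                 obs_noise_sd = obs_noise_sd, seed = seed),
            class = "driven_population_params")
}

# peaked piecewise-linear thermal response: value 1 at T_opt falling
# linearly to floor_frac at the range edges (and clamped beyond)
thermal_response <- function(temp, T_opt, T_range, floor_frac) {
  lo <- T_range[1L]; hi <- T_range[2L]
  f <- ifelse(temp <= T_opt,
              floor_frac + (1 - floor_frac) * (temp - lo) / (T_opt - lo),
              floor_frac + (1 - floor_frac) * (hi - temp) / (hi - T_opt))
  pmin(1, pmax(floor_frac, f))
}

#' Built-in nutrient-condition presets
#'
#' Three parameter presets ("low", "med", "high" nutrient) differing in
#' carrying-capacity and growth-rate scale, standing in for different medium
#' concentrations. Distinct presets produce distinguishable dynamics under
#' the same temperature input.
#'
#' @param condition One of "low", "med", "high".
#' @param ... Overrides passed to \code{\link{driven_population_params}}.
#' @export
nutrient_preset <- function(condition = c("low", "med", "high"), ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
                 low = list(K_peak = 50, r_peak = 0.35, T_opt = 27),
                 med = list(K_peak = 100, r_peak = 0.5, T_opt = 30),
                 high = list(K_peak = 200, r_peak = 0.7, T_opt = 33))
  do.call(driven_population_params, utils::modifyList(base, list(...)))
}

#' Simulate a temperature-driven population run
#'
#' Produces one run record: the coarse input temperature sequence (one value
#' per input step), the fine-grained chamber temperature (first-order lag
#' toward the current set point, one value per substep), and the observed
#' population counts (\code{substeps_per_input} observations per input
#' step). The population update per substep is the Ricker map
#' \eqn{p_{s+1} = p_s \exp(r(T_s)(1 - p_s / K(T_s)))}.
#'
#' @param input_temps Coarse temperature sequence (deg C), e.g. 256 values.
#' @param params A \code{\link{driven_population_params}}.
#' @param init_p Initial population (default \code{0.2 * K_peak}).
#' @param init_temp Initial chamber temperature (default first input).
#' @param condition,replicate Labels carried into the record.
#' @return Object of class \code{"run_record"}: list with
#'   \code{input_temps}, \code{sensor_temps}, \code{counts} (both of length
#'   \code{substeps_per_input * length(input_temps)}),
#'   \code{substeps_per_input}, \code{condition}, \code{replicate}.
#' @export
simulate_driven_population <- function(input_temps, params,
                                       init_p = NULL, init_temp = NULL,
                                       condition = "med", replicate = 1L) {
  stopifnot(inherits(params, "driven_population_params"),
            length(input_temps) >= 1L)
  m <- params$substeps_per_input
  n_fine <- m * length(input_temps)
  Kfun <- function(temp) params$K_peak *
    thermal_response(temp, params$T_opt, params$T_range, params$floor_frac)
  rfun <- function(temp) params$r_peak *
    thermal_response(temp, params$T_opt, params$T_range, params$floor_frac)
  if (any(Kfun(input_temps) <= 0)) stop("carrying capacity must stay positive")
  set.seed(params$seed)
  p <- if (is.null(init_p)) 0.2 * params$K_peak else init_p
  temp <- if (is.null(init_temp)) input_temps[1L] else init_temp
  sensor <- numeric(n_fine)
  counts <- numeric(n_fine)
  for (s in seq_len(n_fine)) {
    setpt <- input_temps[ceiling(s / m)]
    temp <- temp + params$thermal_lag * (setpt - temp)
    p <- p * exp(rfun(temp) * (1 - p / Kfun(temp)))
    obs <- if (params$obs_noise_sd > 0) {
      max(0, p + stats::rnorm(1, 0, params$obs_noise_sd * sqrt(max(p, 0))))
    } else p
    sensor[s] <- temp
    counts[s] <- obs
  }
  structure(list(condition = condition, replicate = as.integer(replicate),
                 input_temps = as.numeric(input_temps),
                 sensor_temps = sensor, counts = counts,
                 substeps_per_input = m, params = params),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat("Run record:", x$condition, "nutrient, replicate", x$replicate, "\n")
  cat("  coarse steps:", length(x$input_temps), "| substeps:",
      x$substeps_per_input, "| fine observations:", length(x$counts), "\n")
  invisible(x)
}
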