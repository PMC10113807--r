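#' Time-delay embedding of a scalar time series
#'
#' Reconstructs the state space of a dynamical system from a single observed
#' series by forming lagged coordinate vectors (Takens-type state space
#' reconstruction). Each library row is the vector
#' \eqn{(x_t, x_{t-\tau}, \ldots, x_{t-(E-1)\tau})} (most recent coordinate
#' first) and its target is the next observed value \eqn{x_{t+1}}, so the
#' library doubles as a one-step forecast database for simplex projection.
#'
#' @param series Numeric vector, the observed time series (finite values).
#' @param E Embedding dimension, integer >= 1.
#' @param tau Lag between coordinates in time steps, integer >= 1.
#' @return An object of class \code{"delay_embedding"}: a list with
#'   \code{library} (rows x E matrix), \code{targets} (next-step value per
#'   row), \code{time_labels} (index of the most recent coordinate of each
#'   row in the original series), \code{E}, \code{tau}, and
#'   \code{source_length}. Row count is
#'   \code{length(series) - 1 - (E - 1) * tau}.
#' @examples
#' emb <- embed_series(sin(1:50), E = 3, tau = 1)
#' nrow(emb$library)  # 50 - 1 - 2 = 47
#' @export
embed_series <- function(series, E, tau = 1L) {
  series <- as.numeric(series)
  if (anyNA(series) || !all(is.finite(series))) {
    stop("invalid series: non-finite values")
  }
  E <- as.integer(E); tau <- as.integer(tau)
  if (E < 1L) stop("E must be >= 1")
  if (tau < 1L) stop("tau must be >= 1")
  n <- length(series)
  if (n < (E - 1L) * tau + 2L) {
    stop("insufficient length: need at least ", (E - 1L) * tau + 2L,
         " points for E = ", E, ", tau = ", tau)
  }
  # time labels t of the most recent coordinate: rows exist where all lags
  # are in range and x_{t+1} is observed
  t_idx <- seq.int((E - 1L) * tau + 1L, n - 1L)
  lib <- matrix(NA_real_, nrow = length(t_idx), ncol = E)
  for (j in seq_len(E)) {
    lib[, j] <- series[t_idx - (j - 1L) * tau]
  }
  structure(
    list(library = lib,
         targets = series[t_idx + 1L],
         time_labels = t_idx,
         E = E, tau = tau,
         source_length = n),
    class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat("Delay embedding: E =", x$E, ", tau =", x$tau, "\n")
  cat("  library rows:", nrow(x$library),
      "(source length", x$source_length, ")\n")
  invisible(x)
}

#' k-nearest-neighbour search in an embedding library
#'
#' Euclidean nearest neighbours of a query state among the library rows,
#' optionally excluding rows (e.g. the query's own row for leave-one-out
#' forecasts). Ties in distance are broken by smaller time label so results
#' are reproducible.
#'
#' @param embedding A \code{"delay_embedding"}.
#' @param query Numeric vector of length \code{E}.
#' @param k Number of neighbours.
#' @param exclude Integer vector of row indices (into the library) to exclude.
#' @return A list with \code{id} (library row indices) and \code{dist},
#'   sorted ascending by (distance, time label).
#' @export
knn_search <- function(embedding, query, k, exclude = integer(0)) {
  stopifnot(inherits(embedding, "delay_embedding"))
  query <- as.numeric(query)
  if (length(query) != embedding$E) stop("query must have length E")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(embedding$library)
  eligible <- setdiff(seq_len(n), exclude)
  if (k > length(eligible)) stop("not enough neighbours: k = ", k,
                                 ", eligible rows = ", length(eligible))
  d <- sqrt(rowSums((embedding$library[eligible, , drop = FALSE] -
                       rep(query, each = length(eligible)))^2))
  ord <- order(d, embedding$time_labels[eligible])[seq_len(k)]
  list(id = eligible[ord], dist = d[ord])
}

# exponential simplex weights over neighbour distances; uniform over
# zero-distance neighbours when the nearest distance is exactly 0
simplex_weights <- function(d) {
  dmin <- d[1L]
  if (dmin == 0) {
    w <- as.numeric(d == 0)
  } else {
    w <- exp(-d / dmin)
  }
  w <- w / sum(w)
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-10)
  w
}

#' One-step simplex-projection forecast
#'
#' Predicts the next value of the series from a query state as the weighted
#' average of the next-step values of its \code{E + 1} nearest library
#' neighbours, with weights \eqn{w_i = \exp(-d_i / d_{\min})} normalised to
#' sum to one. If the nearest distance is exactly zero, weight is spread
#' uniformly over the zero-distance neighbours.
#'
#' @inheritParams knn_search
#' @return Scalar forecast; a convex combination of neighbour targets.
#' @export
simplex_forecast <- function(embedding, query, exclude = integer(0)) {
  k <- embedding$E + 1L
  n_eligible <- nrow(embedding$library) - length(unique(exclude))
  if (n_eligible < k) stop("library too small: need ", k, " eligible rows")
  nn <- knn_search(embedding, query, k, exclude)
  w <- simplex_weights(nn$dist)
  sum(w * embedding$targets[nn$id])
}

#' Simplex-projection update of a full reservoir state
#'
#' Applies the simplex map to an embedded state vector: the first coordinate
#' of the output is the simplex forecast of the next value and the remaining
#' coordinates are the previous values shifted down the lag register. For
#' \code{tau = 1} the state is the plain E-vector and coordinates 2..E of the
#' output equal coordinates 1..(E-1) of the input. For \code{tau > 1} the
#' state must be the full lag register of length \code{(E - 1) * tau + 1}
#' (most recent value first); the forecast query is the register sampled at
#' the lag positions, the new value is pushed onto the front and the oldest
#' value drops off.
#'
#' @param embedding A \code{"delay_embedding"}.
#' @param state Numeric vector: length \code{E} when \code{tau = 1},
#'   otherwise the full lag register.
#' @param exclude Row indices excluded from the neighbour search.
#' @return Updated state vector of the same length.
#' @export
simplex_state_update <- function(embedding, state, exclude = integer(0)) {
  E <- embedding$E; tau <- embedding$tau
  state <- as.numeric(state)
  if (tau == 1L) {
    if (length(state) != E) stop("state must have length E for tau = 1")
    pred <- simplex_forecast(embedding, state, exclude)
    c(pred, state[seq_len(E - 1L)])[seq_len(E)]
  } else {
    reg_len <- (E - 1L) * tau + 1L
    if (length(state) != reg_len) {
      stop("state must be the full lag register (length ", reg_len,
           ") for tau > 1")
    }
    query <- state[seq.int(1L, by = tau, length.out = E)]
    pred <- simplex_forecast(embedding, query, exclude)
    c(pred, state[seq_len(reg_len - 1L)])
  }
}

#' Choose an embedding dimension by leave-one-out simplex forecast skill
#'
#' For each candidate dimension \code{E} in \code{1:E_max}, every library
#' point is forecast by simplex projection with its own row excluded, and
#' forecast skill is the Pearson correlation between predictions and observed
#' next-step values. The optimal dimension maximises skill; ties go to the
#' smallest \code{E}.
#'
#' @param series Numeric time series.
#' @param E_max Largest dimension to try (default 10).
#' @param tau Lag (default 1).
#' @param criterion Skill criterion, \code{"rho"} (Pearson correlation,
#'   default) or \code{"mae"} (negative mean absolute error).
#' @return List with \code{E} (selected dimension) and \code{skill}
#'   (named vector of skill per candidate dimension).
#' @export
select_embedding_dimension <- function(series, E_max = 10L, tau = 1L,
                                       criterion = c("rho", "mae")) {
  criterion <- match.arg(criterion)
  series <- as.numeric(series)
  n <- length(series)
  E_feasible <- E_max
  while (E_feasible >= 1L && n < (E_feasible - 1L) * tau + 2L + E_feasible + 1L) {
    E_feasible <- E_feasible - 1L
  }
  if (E_feasible < 1L) stop("insufficient length for any embedding dimension")
  skills <- rep(NA_real_, E_feasible)
  for (E in seq_len(E_feasible)) {
    emb <- embed_series(series, E, tau)
    preds <- loo_simplex(emb)
    skills[E] <- if (criterion == "rho") {
      suppressWarnings(stats::cor(preds, emb$targets))
    } else {
      -mean(abs(preds - emb$targets))
    }
  }
  skills[is.na(skills)] <- -Inf
  names(skills) <- paste0("E", seq_along(skills))
  list(E = which.max(skills), skill = skills)
}

# leave-one-out simplex forecast of every library row (vectorised over the
# pairwise distance matrix; each row excludes only itself)
loo_simplex <- function(emb) {
  lib <- emb$library
  n <- nrow(lib)
  k <- emb$E + 1L
  if (n - 1L < k) return(rep(NA_real_, n))
  dmat <- as.matrix(stats::dist(lib))
  diag(dmat) <- Inf
  preds <- numeric(n)
  tl <- emb$time_labels
  for (i in seq_len(n)) {
    ord <- order(dmat[i, ], tl)[seq_len(k)]
    w <- simplex_weights(dmat[i, ord])
    preds[i] <- sum(w * emb$targets[ord])
  }
  preds
}
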