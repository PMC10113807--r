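#' Detrend raw cell counts into a stationary population-density index
#'
#' Fits a slow trend to the count series with a penalized regression spline
#' (GAM) and returns the relative residual
#' \code{(count - trend) / pmax(trend, eps)}: a stationary, approximately
#' mean-zero index of population response that can be used as a reservoir
#' state.
#'
#' @param counts Non-negative count series, length >= 20.
#' @param k Spline basis dimension for the trend (default 10; larger values
#'   track faster trends).
#' @param eps Floor for the trend in the denominator; default
#'   \code{1e-6 * mean(counts)}.
#' @return Numeric vector of relative residuals, same length as
#'   \code{counts}, with the fitted trend attached as attribute
#'   \code{"trend"}.
#' @export
preprocess_counts <- function(counts, k = 10L, eps = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 20L) stop("need at least 20 observations")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero counts")
  if (is.null(eps)) eps <- 1e-6 * mean(counts)
  tt <- seq_along(counts)
  fit <- mgcv::gam(counts ~ s(tt, k = k))
  trend <- as.numeric(stats::fitted(fit))
  res <- (counts - trend) / pmax(trend, eps)
  attr(res, "trend") <- trend
  res
}

#' Time-multiplex a fine-grained sequence
#'
#' Reshapes a sequence observed \code{substeps} times per input step into a
#' T x substeps matrix: row t holds the consecutive fine samples of input
#' interval t in time order, so element (t, s) is fine sample
#' \code{(t - 1) * substeps + s}.
#'
#' @param index Fine-grained numeric sequence.
#' @param substeps Observations per input step.
#' @return T x substeps matrix with T = length(index) / substeps.
#' @export
time_multiplex <- function(index, substeps) {
  index <- as.numeric(index)
  if (length(index) %% substeps != 0L) {
    stop("sequence length not divisible by substeps")
  }
  matrix(index, ncol = substeps, byrow = TRUE)
}

#' Space-multiplex reservoir matrices from several runs
#'
#' Column-wise concatenation of per-run (time-multiplexed) state matrices,
#' with provenance labels per column so the multiplexing can be inverted.
#'
#' @param matrices List of T x k_i matrices with equal T.
#' @param labels Optional data frame (one row per matrix) with e.g.
#'   condition and replicate; expanded to one row per column.
#' @return Object of class \code{"multiplexed_matrix"}: list with
#'   \code{matrix} (T x sum(k_i)) and \code{column_labels} (data frame with
#'   run, substep and any provided labels).
#' @export
space_multiplex <- function(matrices, labels = NULL) {
  stopifnot(length(matrices) >= 1L)
  Ts <- vapply(matrices, nrow, integer(1))
  if (length(unique(Ts)) != 1L) stop("matrices have mismatched row counts")
  ks <- vapply(matrices, ncol, integer(1))
  col_labels <- data.frame(
    run = rep(seq_along(matrices), ks),
    substep = unlist(lapply(ks, seq_len)))
  if (!is.null(labels)) {
    col_labels <- cbind(col_labels, labels[col_labels$run, , drop = FALSE])
    rownames(col_labels) <- NULL
  }
  structure(list(matrix = do.call(cbind, matrices),
                 column_labels = col_labels),
            class = "multiplexed_matrix")
}

#' @export
print.multiplexed_matrix <- function(x, ...) {
  cat("Multiplexed reservoir matrix:", nrow(x$matrix), "x", ncol(x$matrix),
      "(", length(unique(x$column_labels$run)), "runs )\n")
  invisible(x)
}

#' Build the multiplexed reservoir matrix of a set of runs
#'
#' Convenience chain for run records: preprocess each run's counts into a
#' density index, time-multiplex it at the run's substep count, and
#' space-multiplex across runs.
#'
#' @param runs List of \code{"run_record"} objects with equal coarse length.
#' @param k Trend basis dimension passed to \code{\link{preprocess_counts}}.
#' @return A \code{"multiplexed_matrix"} with condition/replicate labels.
#' @export
multiplex_runs <- function(runs, k = 10L) {
  mats <- lapply(runs, function(r) {
    time_multiplex(preprocess_counts(r$counts, k = k), r$substeps_per_input)
  })
  labels <- data.frame(
    condition = vapply(runs, `[[`, character(1), "condition"),
    replicate = vapply(runs, `[[`, integer(1), "replicate"))
  space_multiplex(mats, labels)
}

#' Lagged-input recall task ("thermometer")
#'
#' Trains a readout (no intercept by default, matching the 1 x C weight
#' matrix convention) on the training reservoir matrix to reproduce the
#' input \code{lag} steps ago, evaluates recall correlation on the test
#' runs, and computes the full forgetting curve over lags.
#'
#' @param train,test \code{"multiplexed_matrix"} objects (or plain
#'   matrices).
#' @param train_u,test_u Coarse input sequences aligned with the matrix
#'   rows.
#' @param lag Recall lag in input steps (default 1).
#' @param max_lag Largest lag of the forgetting curve (default 10).
#' @param lambda,intercept Readout settings (defaults 0.05, \code{FALSE}).
#' @return List with \code{r} (test recall correlation at \code{lag}),
#'   \code{predictions}, \code{observed}, \code{weights} (1 x C),
#'   and \code{curve} (a \code{"forgetting_curve"}).
#' @export
recall_task <- function(train, test, train_u, test_u, lag = 1L,
                        max_lag = 10L, lambda = 0.05, intercept = FALSE) {
  Str <- if (inherits(train, "multiplexed_matrix")) train$matrix else as.matrix(train)
  Ste <- if (inherits(test, "multiplexed_matrix")) test$matrix else as.matrix(test)
  train_u <- as.numeric(train_u); test_u <- as.numeric(test_u)
  rows_tr <- seq.int(lag + 1L, nrow(Str))
  rows_te <- seq.int(lag + 1L, nrow(Ste))
  fit <- train_ridge(Str[rows_tr, , drop = FALSE], train_u[rows_tr - lag],
                     lambda = lambda, intercept = intercept)
  pred <- drop(readout_predict(fit, Ste[rows_te, , drop = FALSE]))
  obs <- test_u[rows_te - lag]
  curve <- forgetting_curve(Str, Ste, train_u, test_u, max_lag = max_lag,
                            lambda = lambda, intercept = intercept)
  list(r = correlation_skill(pred, obs), predictions = pred, observed = obs,
       weights = fit$w_out, curve = curve)
}

#' Horizon-sweep prediction task with a ridge baseline
#'
#' For each horizon h, trains a readout on the reservoir matrix to predict
#' the target h steps ahead and compares its test NMSE with a ridge
#' regression of the same target on the raw input value alone (the linear
#' baseline): where the reservoir curve lies below the baseline curve, the
#' reservoir's processing of the input adds predictive information.
#'
#' @param states A \code{"multiplexed_matrix"} or T x C matrix.
#' @param u Raw coarse input sequence (baseline regressor).
#' @param target Target series aligned with the coarse steps.
#' @param horizons Integer vector of horizons (default 0:15).
#' @param train_frac Fraction of rows used for training in the temporal
#'   split (default 0.7).
#' @param lambda,intercept Readout settings (defaults 0.05, \code{TRUE} for
#'   this task).
#' @return Data frame with columns \code{horizon}, \code{nmse_reservoir},
#'   \code{nmse_baseline}.
#' @export
horizon_prediction_task <- function(states, u, target, horizons = 0:15,
                                    train_frac = 0.7, lambda = 0.05,
                                    intercept = TRUE) {
  S <- if (inherits(states, "multiplexed_matrix")) states$matrix else as.matrix(states)
  u <- as.numeric(u); target <- as.numeric(target)
  if (nrow(S) != length(target) || length(u) != length(target)) {
    stop("states, input and target misaligned")
  }
  out <- data.frame(horizon = horizons, nmse_reservoir = NA_real_,
                    nmse_baseline = NA_real_)
  T_len <- nrow(S)
  for (i in seq_along(horizons)) {
    h <- horizons[i]
    rows <- seq_len(T_len - h)
    y <- target[rows + h]
    n_train <- floor(train_frac * length(rows))
    tr <- rows[seq_len(n_train)]
    te <- rows[seq.int(n_train + 1L, length(rows))]
    fit_res <- train_ridge(S[tr, , drop = FALSE], y[seq_len(n_train)],
                           lambda = lambda, intercept = intercept)
    pred_res <- drop(readout_predict(fit_res, S[te, , drop = FALSE]))
    fit_base <- train_ridge(matrix(u[tr], ncol = 1L), y[seq_len(n_train)],
                            lambda = lambda, intercept = intercept)
    pred_base <- drop(readout_predict(fit_base, matrix(u[te], ncol = 1L)))
    obs <- y[seq.int(n_train + 1L, length(rows))]
    out$nmse_reservoir[i] <- nmse(pred_res, obs)
    out$nmse_baseline[i] <- nmse(pred_base, obs)
  }
  out
}
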