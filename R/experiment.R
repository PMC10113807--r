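#' Run a configured reservoir-computing experiment
#'
#' Executes the full chain for one configuration: generate the task signal,
#' build the reservoir(s), fit the readout on the training portion, evaluate
#' on the held-out portion, and (optionally) write artifacts — the exact
#' config, the readout weights and a JSON report — into the output
#' directory. Deterministic given the config, so two invocations produce
#' identical reports.
#'
#' Config layout (YAML):
#' \preformatted{
#' seed: 1
#' task:       {name: lorenz|narma|mackey_glass|uniform, n: 500, ...}
#' reservoir:  {type: erc_community|esn|lv, n_species: 10, E: ..., ...}
#' readout:    {lambda: 0.05, washout: 50, intercept: true}
#' train_frac: 0.7
#' esp_test:   true        # optional ESP summary
#' output_dir: path        # optional; no files written when absent
#' }
#'
#' @param config Config list (see \code{\link{read_experiment_config}}) or a
#'   path to a YAML file.
#' @return List of class \code{"experiment_report"}: task/reservoir
#'   descriptors, test NMSE and correlation, optional ESP summary, and the
#'   seeds used.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- validate_experiment_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  task <- stage("task", make_task(config$task, config$seed))
  reservoirs <- stage("reservoir",
                      make_reservoirs(config$reservoir, config$seed))

  ro <- config$readout
  lambda <- ro$lambda %||% 0.05
  washout <- ro$washout %||% 50L
  intercept <- ro$intercept %||% TRUE
  train_frac <- config$train_frac %||% 0.7

  T_len <- NROW(task$u)
  n_train <- floor(train_frac * T_len)
  u_tr <- task$u[seq_len(n_train)]
  y_tr <- task$y[seq_len(n_train)]
  u_te <- task$u[seq.int(n_train + 1L, T_len)]
  y_te <- task$y[seq.int(n_train + 1L, T_len)]

  fit <- stage("train", rc_fit(reservoirs, u_tr, y_tr, lambda = lambda,
                               washout = washout, intercept = intercept))
  pred <- stage("evaluate", drop(predict(fit, u_te)))

  report <- list(
    task = list(name = task$name, length = T_len, horizon = task$horizon),
    reservoir = list(type = config$reservoir$type,
                     n_reservoirs = length(fit$reservoirs),
                     total_size = sum(vapply(fit$reservoirs,
                                             function(r) length(r$state),
                                             integer(1)))),
    readout = list(lambda = lambda, washout = washout, intercept = intercept),
    test = list(n = length(y_te),
                nmse = nmse(pred, y_te),
                correlation = correlation_skill(pred, y_te)),
    seed = config$seed)

  if (isTRUE(config$esp_test)) {
    r1 <- fit$reservoirs[[1L]]
    dim1 <- length(r1$state)
    set.seed(config$seed + 999L)
    init_a <- stats::runif(dim1, 0.1, 0.9)
    init_b <- stats::runif(dim1, 0.1, 0.9)
    d <- esp_distance(function(inp, ini) run_reservoir(r1, inp, init = ini),
                      scale(u_tr)[, 1L], init_a, init_b)
    report$esp <- list(converged = esp_converged(d),
                       d_first = d[1L], d_last = d[length(d)])
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(config$output_dir, "config.yaml"))
    utils::write.csv(as.data.frame(coef(fit)),
                     file.path(config$output_dir, "readout_weights.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "experiment_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment:", x$task$name, "| reservoir:", x$reservoir$type,
      "( size", x$reservoir$total_size, ")\n")
  cat(sprintf("  test (n = %d): NMSE = %.4g, rho = %.4g\n",
              x$test$n, x$test$nmse, x$test$correlation))
  if (!is.null(x$esp)) {
    cat("  ESP converged:", x$esp$converged, "\n")
  }
  invisible(x)
}

# build the task signal named in the config block
make_task <- function(tk, seed) {
  n <- tk$n %||% 500L
  switch(tk$name,
    lorenz = task_lorenz(n, horizon = tk$horizon %||% 1L,
                         observe = tk$observe %||% 1L),
    narma = task_narma(order = tk$order %||% 2L, n = n, seed = seed),
    mackey_glass = task_mackey_glass(n),
    uniform = task_uniform(n, lo = tk$lo %||% 0, hi = tk$hi %||% 1,
                           seed = seed),
    stop("unknown task: ", tk$name))
}

# build the reservoir list named in the config block
make_reservoirs <- function(rv, seed) {
  switch(rv$type,
    erc_community = {
      n_sp <- rv$n_species %||% 10L
      len <- rv$series_length %||% 300L
      X <- simulate_community(
        community_params(S = n_sp, seed = seed,
                         process_noise_sd = rv$process_noise_sd %||% 0.01),
        n = len)
      lapply(seq_len(n_sp), function(i) {
        erc_reservoir(X[, i], E = rv$E, E_max = rv$E_max %||% 10L,
                      input_scale = rv$input_scale %||% 0.3,
                      seed = seed + i)
      })
    },
    esn = list(esn_reservoir(rv$N %||% 200L,
                             spectral_radius = rv$spectral_radius %||% 0.95,
                             density = rv$density %||% 0.1,
                             input_scale = rv$input_scale %||% 0.3,
                             seed = seed)),
    lv = list(lv_reservoir(lv_params(), input_scale = rv$input_scale %||% 0.3,
                           seed = seed)),
    stop("unknown reservoir type: ", rv$type))
}
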