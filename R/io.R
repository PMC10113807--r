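#' Write a time-series object to CSV
#'
#' Three schemas are supported: \code{"wide_community"} (column \code{time}
#' plus one column per species), \code{"run_record"} (columns
#' \code{time_min}, \code{input_temp_C} repeated per substep,
#' \code{sensor_temp_C}, \code{cell_count}; condition/replicate/substeps go
#' to a YAML sidecar \code{<path>.meta.yaml}), and \code{"task_signal"}
#' (columns \code{u}, \code{y}; name/horizon/params to the sidecar).
#'
#' @param x Matrix (wide_community), \code{"run_record"} or
#'   \code{"task_signal"}.
#' @param path Output CSV path.
#' @param schema One of \code{"wide_community"}, \code{"run_record"},
#'   \code{"task_signal"}.
#' @export
write_timeseries_csv <- function(x, path,
                                 schema = c("wide_community", "run_record",
                                            "task_signal")) {
  schema <- match.arg(schema)
  if (schema == "wide_community") {
    X <- as.matrix(x)
    df <- data.frame(time = seq_len(nrow(X)), X, check.names = FALSE)
  } else if (schema == "run_record") {
    stopifnot(inherits(x, "run_record"))
    m <- x$substeps_per_input
    df <- data.frame(time_min = seq_along(x$counts),
                     input_temp_C = rep(x$input_temps, each = m),
                     sensor_temp_C = x$sensor_temps,
                     cell_count = x$counts)
    yaml::write_yaml(list(condition = x$condition, replicate = x$replicate,
                          substeps_per_input = m),
                     paste0(path, ".meta.yaml"))
  } else {
    stopifnot(inherits(x, "task_signal"))
    df <- data.frame(u = x$u, y = x$y)
    yaml::write_yaml(list(name = x$name, horizon = x$horizon,
                          params = x$params, seed = x$seed),
                     paste0(path, ".meta.yaml"))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a time-series CSV written by \code{\link{write_timeseries_csv}}
#'
#' Validates the header against the schema (a missing column is named in
#' the error), checks finiteness and, for the run-record schema, the
#' uniform time step and the substep/coarse-length consistency.
#'
#' @param path CSV path.
#' @param schema See \code{\link{write_timeseries_csv}}.
#' @return A species matrix, \code{"run_record"}, or \code{"task_signal"}.
#' @export
read_timeseries_csv <- function(path,
                                schema = c("wide_community", "run_record",
                                           "task_signal")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- switch(schema,
                 wide_community = "time",
                 run_record = c("time_min", "input_temp_C", "sensor_temp_C",
                                "cell_count"),
                 task_signal = c("u", "y"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema mismatch: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  num <- df[vapply(df, is.numeric, logical(1))]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite values in ", path)
  }
  if (schema == "wide_community") {
    tstep <- diff(df$time)
    if (length(tstep) && any(abs(tstep - tstep[1L]) > 1e-9)) {
      stop("non-uniform time step")
    }
    as.matrix(df[setdiff(names(df), "time")])
  } else if (schema == "run_record") {
    tstep <- diff(df$time_min)
    if (any(abs(tstep - tstep[1L]) > 1e-9)) stop("non-uniform time step")
    meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
    m <- meta$substeps_per_input
    if (nrow(df) %% m != 0L) stop("fine length not divisible by substeps")
    input_temps <- df$input_temp_C[seq(1L, nrow(df), by = m)]
    if (!all(df$input_temp_C == rep(input_temps, each = m))) {
      stop("input_temp_C is not constant within input steps")
    }
    structure(list(condition = meta$condition,
                   replicate = as.integer(meta$replicate),
                   input_temps = input_temps,
                   sensor_temps = df$sensor_temp_C,
                   counts = df$cell_count,
                   substeps_per_input = as.integer(m)),
              class = "run_record")
  } else {
    meta_path <- paste0(path, ".meta.yaml")
    meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else
      list(name = "unknown", horizon = 0L, params = list(), seed = NA)
    task_signal(df$u, df$y, meta$name, meta$horizon, meta$params,
                if (is.null(meta$seed)) NA else meta$seed)
  }
}

#' Read and validate an experiment configuration
#'
#' YAML key-value configuration describing one experiment: a \code{task}
#' block, a \code{reservoir} block, a \code{readout} block and an output
#' directory. Every stochastic component must carry an explicit seed.
#'
#' @param path YAML file path.
#' @return Named list (validated).
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
}

#' @rdname read_experiment_config
#' @param cfg Configuration list (as from \code{yaml::read_yaml}).
#' @export
validate_experiment_config <- function(cfg) {
  for (block in c("task", "reservoir", "readout")) {
    if (is.null(cfg[[block]])) stop("config missing block: ", block)
  }
  if (is.null(cfg$task$name)) stop("config missing task$name")
  if (is.null(cfg$reservoir$type)) stop("config missing reservoir$type")
  if (is.null(cfg$seed)) stop("validation error: config must set an explicit seed")
  cfg
}
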