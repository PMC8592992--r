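# Configuration parsing and file I/O: YAML run configs, CSV traces/episodes/
# results, JSON metadata sidecars.

.MODEL_KEYS <- c("lambda_v", "lambda_s", "v0", "s0", "n_particles",
                 "prior_mean", "prior_var", "lesion", "lesion_value",
                 "ess_ratio_threshold")

#' Serialize learner parameters to a plain config list
#'
#' @param params A [model_params()] object.
#' @return Named list with exactly the keys `lambda_v`, `lambda_s`, `v0`,
#'   `s0`, `n_particles`, `prior_mean`, `prior_var`, `lesion`,
#'   `lesion_value`, `ess_ratio_threshold`.
#' @export
model_params_to_config <- function(params) {
  stopifnot(inherits(params, "model_params"))
  out <- unclass(params)[.MODEL_KEYS]
  if (is.na(out$lesion_value)) out$lesion_value <- NULL
  out
}

#' Build learner parameters from a plain config list
#'
#' Unknown keys raise an error naming the key.
#'
#' @param config Named list using the keys documented in
#'   [model_params_to_config()]. Missing keys take the [model_params()]
#'   defaults.
#' @return A validated [model_params()] object.
#' @export
model_params_from_config <- function(config) {
  unknown <- setdiff(names(config), .MODEL_KEYS)
  if (length(unknown) > 0) {
    stop("unknown model parameter key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(model_params, config)
}

.RUN_KEYS <- c("experiment", "task_file", "model", "n_sims", "n_particles",
               "seed", "out_dir", "full", "quiet", "n_trials", "probe_trial")

#' Parse and validate a run configuration
#'
#' Reads a YAML file (or takes an equivalent named list) describing a run:
#' either a registered `experiment` key or a `task_file` of outcomes to
#' filter, an optional `model` block of learner parameters, and run options
#' (`n_sims`, `n_particles`, `seed`, `out_dir`, `full`, `quiet`). All
#' defaults are resolved so the returned object is complete; unknown or
#' out-of-range keys raise an error naming the offending key.
#'
#' @param config Path to a YAML file, or a named list.
#' @return An object of class `run_config` with all defaults filled in.
#' @export
#' @examples
#' cfg <- parse_config(list(experiment = "fig2", n_sims = 10))
parse_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .RUN_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$experiment) && is.null(config$task_file)) {
    stop("config needs either 'experiment' or 'task_file'")
  }
  model <- if (is.null(config$model)) NULL else {
    model_params_from_config(config$model)
  }
  out <- list(
    experiment = config$experiment,
    task_file = config$task_file,
    model = model,
    n_sims = config$n_sims,
    n_particles = if (is.null(config$n_particles)) 100L
                  else as.integer(config$n_particles),
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    out_dir = if (is.null(config$out_dir)) "." else config$out_dir,
    full = isTRUE(config$full),
    quiet = isTRUE(config$quiet),
    n_trials = config$n_trials,
    probe_trial = config$probe_trial)
  if (!is.null(out$experiment)) {
    # validates the registry key and replication counts
    ec <- experiment_config(out$experiment, n_sims = out$n_sims,
                            n_particles = out$n_particles, seed = out$seed,
                            full = out$full, n_trials = out$n_trials,
                            probe_trial = out$probe_trial)
    out$n_sims <- ec$n_sims
    out$n_trials <- ec$n_trials
  }
  structure(out, class = "run_config")
}

#' Write a resolved run configuration to YAML
#'
#' Round-trips through [parse_config()]: re-parsing the written file yields
#' an identical configuration.
#'
#' @param config A `run_config` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  if (!is.null(out$model)) out$model <- model_params_to_config(out$model)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write an outcome series to CSV
#'
#' Headered CSV with columns `trial`, `outcome` and, when available,
#' `x_true`, `v_true`, `s_true`.
#'
#' @param series A `generated_series` from [generate_series()], a numeric
#'   vector of outcomes, or a single-cue [task_episode()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcome_series <- function(series, path) {
  if (inherits(series, "generated_series")) {
    df <- data.frame(trial = seq_along(series$o), outcome = series$o,
                     x_true = series$x, v_true = series$noise$v,
                     s_true = series$noise$s)
  } else if (inherits(series, "task_episode")) {
    stopifnot(!is.matrix(series$outcomes))
    df <- data.frame(trial = seq_along(series$outcomes),
                     outcome = series$outcomes, x_true = series$rate_true)
  } else {
    df <- data.frame(trial = seq_along(series), outcome = as.numeric(series))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an outcome series from CSV
#'
#' @param path CSV with at least a numeric `outcome` column (a bare
#'   single-column file of numbers is also accepted).
#' @return Numeric vector of outcomes.
#' @export
read_outcome_series <- function(path) {
  if (!file.exists(path)) stop("outcome file not found: ", path)
  df <- utils::read.csv(path)
  col <- if ("outcome" %in% names(df)) df$outcome else df[[1]]
  if (!is.numeric(col)) stop("outcome column is not numeric in ", path)
  col
}

#' Write a filter trace to CSV
#'
#' @param trace A `filter_trace` from [run_filter()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a task episode to CSV (long format) with a metadata sidecar
#'
#' One row per trial and channel/option: `trial`, `channel`, `outcome`,
#' `rate_true`, `phase`, `correct_option`. Generation metadata is written to
#' `<path>.meta.json`.
#'
#' @param episode A [task_episode()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_episode <- function(episode, path) {
  stopifnot(inherits(episode, "task_episode"))
  o <- episode$outcomes
  r <- episode$rate_true
  if (!is.matrix(o)) {
    o <- matrix(o, ncol = 1, dimnames = list(NULL, "outcome"))
    r <- matrix(r, ncol = 1)
  }
  n <- nrow(o)
  K <- ncol(o)
  chan <- if (!is.null(colnames(o))) colnames(o) else paste0("channel", 1:K)
  df <- data.frame(trial = rep(seq_len(n), K),
                   channel = rep(chan, each = n),
                   outcome = as.vector(o), rate_true = as.vector(r),
                   phase = rep(episode$phase, K),
                   correct_option = if (is.null(episode$correct_option)) {
                     NA_integer_
                   } else rep(episode$correct_option, K))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(episode$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write an experiment result to CSV with a metadata sidecar
#'
#' The tidy per-replication table goes to `path`; the resolved configuration
#' (including the seed, sufficient to regenerate the result exactly) goes to
#' `<path>.meta.json`.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  utils::write.csv(result$result, path, row.names = FALSE)
  meta <- c(result$config,
            list(package_version = as.character(utils::packageVersion("volstoch"))))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
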