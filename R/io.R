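#' Read and write trace files
#'
#' Trace files are delimited text (CSV) with a header row and columns
#' `time_s`, `stim_deg`, `left_deg`, `right_deg`.
#'
#' @param path File path.
#' @param profile Optional [stimulus_profile()] to attach to the trace on
#'   read.
#' @return `read_trace_csv()` returns a trace tibble; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
read_trace_csv <- function(path, profile = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "stim_deg", "left_deg", "right_deg")
  if (!all(need %in% names(x))) {
    abort(sprintf("trace file must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (!is.null(profile)) attr(x, "profile") <- profile
  x
}

#' @rdname read_trace_csv
#' @param trace A trace tibble.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(
    dplyr::select(trace, "time_s", "stim_deg", "left_deg", "right_deg"),
    path
  )
  invisible(path)
}

#' Read and write per-cycle amplitude tables
#'
#' Cycle tables are CSV with columns `cycle_index`, `t_start_s`,
#' `t_end_s`, `pp_deg`, `valid`, `reason`.
#'
#' @param path File path.
#' @return A cycle-table tibble / `path` invisibly.
#' @export
read_cycle_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(reason = readr::col_character()))
}

#' @rdname read_cycle_csv
#' @param cycle_table A cycle-table tibble.
#' @export
write_cycle_csv <- function(cycle_table, path) {
  readr::write_csv(
    dplyr::select(cycle_table, "cycle_index", "t_start_s", "t_end_s",
                  "pp_deg", "valid", "reason"),
    path
  )
  invisible(path)
}

#' Read a cohort configuration file
#'
#' YAML key-value file naming the stimulus profile, cohort size,
#' initial-amplitude distribution, plasticity parameters and seed, e.g.:
#'
#' ```yaml
#' profile: 1
#' duration: 1800
#' n_animals: 10
#' mean_deg: 7.4
#' sd_deg: 5.4
#' slope_m: -0.59
#' setpoint_x0: 6.4
#' residual_sd: 1.8
#' seed: 1
#' ```
#'
#' (The cohort-size key is `n_animals` because a bare `n` is a boolean
#' token in YAML.)
#'
#' @param path YAML file path.
#' @return A list with elements `profile` ([stimulus_profile()]),
#'   `params` ([plasticity_params()]), `n`, `mean_deg`, `sd_deg`, `seed`,
#'   plus any extra keys under `extra`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("profile", "n_animals", "mean_deg", "sd_deg", "slope_m",
            "setpoint_x0")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    abort(sprintf("config missing keys: %s.", paste(miss, collapse = ", ")))
  }
  list(
    profile = stimulus_profile(y$profile,
                               duration = y$duration %||% 1800),
    params = plasticity_params(y$slope_m, y$setpoint_x0,
                               residual_sd = y$residual_sd %||% 0),
    n = y$n_animals, mean_deg = y$mean_deg, sd_deg = y$sd_deg,
    seed = y$seed %||% NULL,
    extra = y[setdiff(names(y),
                      c(need, "duration", "residual_sd", "seed"))]
  )
}

#' Read and write grayscale TIFF stacks
#'
#' 8-bit grayscale stacks, one frame per plane, as arrays
#' `height x width x n` with intensities in 8-bit levels (0-255).
#'
#' @param path File path.
#' @return `read_tiff_stack()` returns the array; `write_tiff_stack()`
#'   returns `path` invisibly.
#' @export
read_tiff_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # drop extra channels
    p * 255
  })
  simplify2array(planes)
}

#' @rdname read_tiff_stack
#' @param stack Numeric array `height x width x n` in 8-bit levels.
#' @export
write_tiff_stack <- function(stack, path) {
  if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack), 1)
  planes <- lapply(seq_len(dim(stack)[3]),
                   function(i) stack[, , i] / 255)
  tiff::writeTIFF(planes, path, bits.per.sample = 8)
  invisible(path)
}

#' Write an analysis results file
#'
#' JSON with per-animal summaries, the pooled regression and a version /
#' seed stamp, so re-running with the same configuration is reproducible
#' and traceable.
#'
#' @param summaries Per-animal summary tibble (see [analyze_cohort()]).
#' @param fit An `okr_setpoint_fit` from [regress_change()].
#' @param path Output path.
#' @param seed Optional seed to stamp into the file.
#' @param config Optional configuration list to hash into the file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(summaries, fit, path, seed = NULL,
                               config = NULL) {
  payload <- list(
    package = "okrplast",
    version = as.character(utils::packageVersion("okrplast")),
    seed = seed,
    config_hash = if (!is.null(config)) {
      rlang::hash(config)
    } else {
      NULL
    },
    regression = list(
      slope = fit$slope,
      intercept = fit$intercept,
      r_squared = fit$r_squared,
      x_zero_intercept = fit$x_zero_intercept,
      n = fit$n
    ),
    animals = dplyr::select(
      summaries,
      dplyr::any_of(c("animal_id", "group", "paradigm", "immediate_deg",
                      "entrained_deg", "delta_deg", "n_valid"))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
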