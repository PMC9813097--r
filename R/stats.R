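#' Immediate and entrained response of one animal
#'
#' The immediate response I is the mean peak-to-peak amplitude of the first
#' `n_edge` valid cycles, the entrained response E that of the last
#' `n_edge` valid cycles; invalid cycles are skipped and the window
#' extended (skip-and-extend).
#'
#' @param cycle_table A cycle table from [cycle_amplitudes()] /
#'   [process_recording()].
#' @param n_edge Number of valid cycles averaged at each end (default 5).
#' @return A one-row tibble: `immediate_deg`, `entrained_deg`, `delta_deg`
#'   (= E - I), `n_valid`.
#' @examples
#' ct <- tibble::tibble(cycle_index = 1:10, t_start_s = 0:9, t_end_s = 1:10,
#'                      pp_deg = 1:10, valid = TRUE, reason = NA)
#' immediate_entrained(ct) # I = 3, E = 8
#' @export
immediate_entrained <- function(cycle_table, n_edge = 5) {
  ok <- cycle_table$valid & !is.na(cycle_table$pp_deg)
  pp <- cycle_table$pp_deg[ok][order(cycle_table$cycle_index[ok])]
  if (length(pp) < 2 * n_edge) {
    abort(sprintf("too few valid cycles (%d < %d).", length(pp), 2 * n_edge))
  }
  i_mean <- mean(head(pp, n_edge))
  e_mean <- mean(tail(pp, n_edge))
  tibble::tibble(
    immediate_deg = i_mean,
    entrained_deg = e_mean,
    delta_deg = e_mean - i_mean,
    n_valid = length(pp)
  )
}

#' Per-animal summaries for a simulated cohort
#'
#' Runs each animal's trace through [process_recording()] and
#' [immediate_entrained()].
#'
#' @param cohort A nested cohort tibble from [simulate_cohort()] or
#'   [simulate_group()] (list-column `trace`).
#' @param n_edge Edge-window size passed to [immediate_entrained()].
#' @param ... Passed to [process_recording()].
#' @return The cohort tibble without the `trace` column, with added
#'   columns `immediate_deg`, `entrained_deg`, `delta_deg`, `n_valid` and a
#'   list-column `cycles` of cycle tables.
#' @export
analyze_cohort <- function(cohort, n_edge = 5, ...) {
  cycles <- purrr::map(cohort$trace, process_recording, ...)
  summaries <- purrr::map(cycles, immediate_entrained, n_edge = n_edge)
  out <- dplyr::select(cohort, -"trace")
  dplyr::bind_cols(out, dplyr::bind_rows(summaries),
                   tibble::tibble(cycles = cycles))
}

#' Setpoint regression of amplitude change on initial amplitude
#'
#' Ordinary least squares of the training-induced amplitude change
#' Delta = E - I on the immediate amplitude I, pooled across stimulus
#' paradigms. The homeostatic setpoint is the x-axis zero-intercept
#' `x0 = -intercept / slope`, the initial amplitude at which training
#' induces no net change; it is reported as `NA` when |slope| falls below
#' `slope_tol` (a near-flat fit has no meaningful zero crossing).
#'
#' @param summaries A tibble with columns `immediate_deg` and `delta_deg`
#'   (e.g. from [analyze_cohort()]), one row per animal.
#' @param slope_tol Minimum |slope| for a defined setpoint.
#' @return An object of class `okr_setpoint_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `x_zero_intercept`, `n`, `fit` (the
#'   underlying `lm`), and `data`.
#' @examples
#' s <- tibble::tibble(immediate_deg = c(2, 4, 8),
#'                     delta_deg = -0.5 * (c(2, 4, 8) - 6))
#' fit <- regress_change(s)
#' fit$slope            # -0.5
#' fit$x_zero_intercept # 6
#' @export
regress_change <- function(summaries, slope_tol = 1e-6) {
  if (nrow(summaries) < 3) abort("need at least 3 animals.")
  if (sd(summaries$immediate_deg) < 1e-12) {
    abort("degenerate cohort: all immediate amplitudes identical.")
  }
  fit <- lm(delta_deg ~ immediate_deg, data = summaries)
  b <- coef(fit)
  slope <- unname(b[["immediate_deg"]])
  intercept <- unname(b[["(Intercept)"]])
  r2 <- summary(fit)$r.squared
  x0 <- if (abs(slope) > slope_tol) -intercept / slope else NA_real_
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         x_zero_intercept = x0, n = nrow(summaries), fit = fit,
         data = summaries),
    class = "okr_setpoint_fit"
  )
}

#' @export
print.okr_setpoint_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<okr_setpoint_fit> n = %d animals\n",
           "  slope            %8.3f\n",
           "  R-squared        %8.3f\n",
           "  setpoint (x0)    %8.3f deg%s\n"),
    x$n, x$slope, x$r_squared,
    ifelse(is.na(x$x_zero_intercept), NA, x$x_zero_intercept),
    if (is.na(x$x_zero_intercept)) " (undefined: |slope| ~ 0)" else ""
  ))
  invisible(x)
}

#' @describeIn regress_change One row per model term (estimate, std.error,
#'   statistic, p.value), broom style.
#' @param x An `okr_setpoint_fit`.
#' @param ... Unused.
#' @export
tidy.okr_setpoint_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @describeIn regress_change One-row model summary including the setpoint.
#' @export
glance.okr_setpoint_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    x_zero_intercept = x$x_zero_intercept, n = x$n
  )
}

#' 95% confidence band of the setpoint regression
#'
#' @param fit An `okr_setpoint_fit`.
#' @param at Immediate amplitudes at which to evaluate the band (default: a
#'   regular grid over the data range).
#' @param level Confidence level.
#' @return A tibble: `immediate_deg`, `fit_deg`, `lwr_deg`, `upr_deg`.
#' @export
confidence_band <- function(fit, at = NULL, level = 0.95) {
  stopifnot(inherits(fit, "okr_setpoint_fit"))
  at <- at %||% seq(min(fit$data$immediate_deg), max(fit$data$immediate_deg),
                    length.out = 50)
  p <- predict(fit$fit, newdata = tibble::tibble(immediate_deg = at),
               interval = "confidence", level = level)
  tibble::tibble(immediate_deg = at, fit_deg = p[, "fit"],
                 lwr_deg = p[, "lwr"], upr_deg = p[, "upr"])
}

#' Amplitude variability before and after training
#'
#' Standard deviation of the immediate (I) and entrained (E) response
#' amplitudes per stimulus paradigm, plus the pooled values. Homogenization
#' of the population by training appears as SD(E) < SD(I); the comparison
#' is reported, not asserted.
#'
#' @param summaries Per-animal summaries with `paradigm`, `immediate_deg`,
#'   `entrained_deg`.
#' @return A tibble: `paradigm` (`"pooled"` for the pooled row), `n`,
#'   `sd_immediate_deg`, `sd_entrained_deg`.
#' @export
variability_metrics <- function(summaries) {
  per <- summaries |>
    dplyr::group_by(paradigm = as.character(.data$paradigm)) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd_immediate_deg = sd(.data$immediate_deg),
      sd_entrained_deg = sd(.data$entrained_deg),
      .groups = "drop"
    )
  pooled <- summaries |>
    dplyr::summarise(
      paradigm = "pooled",
      n = dplyr::n(),
      sd_immediate_deg = sd(.data$immediate_deg),
      sd_entrained_deg = sd(.data$entrained_deg)
    )
  dplyr::bind_rows(per, pooled)
}

#' Population per-cycle average amplitude
#'
#' Mean peak-to-peak amplitude per cycle index across animals, using only
#' valid cycles; a cycle index with no contributing animal is a gap (`NA`),
#' not zero. Animals whose cycles are all invalid are dropped with a
#' warning.
#'
#' @param cycle_tables Either a list of cycle tables or a tibble with a
#'   `cycles` list-column (as from [analyze_cohort()]).
#' @return A tibble: `cycle_index`, `mean_pp_deg`, `sd_pp_deg`,
#'   `n_animals`.
#' @export
population_cycle_average <- function(cycle_tables) {
  if (is.data.frame(cycle_tables)) cycle_tables <- cycle_tables$cycles
  all_invalid <- purrr::map_lgl(cycle_tables,
                                ~ !any(.x$valid & !is.na(.x$pp_deg)))
  if (any(all_invalid)) {
    warn(sprintf("%d animal(s) with no valid cycles excluded.",
                 sum(all_invalid)))
    cycle_tables <- cycle_tables[!all_invalid]
  }
  if (!length(cycle_tables)) abort("no animals with valid cycles.")
  long <- purrr::imap(cycle_tables, function(ct, i) {
    dplyr::mutate(ct[ct$valid & !is.na(ct$pp_deg), ], animal = i)
  })
  idx_max <- max(purrr::map_int(cycle_tables,
                                ~ max(.x$cycle_index, na.rm = TRUE)))
  dplyr::bind_rows(long) |>
    dplyr::group_by(.data$cycle_index) |>
    dplyr::summarise(
      mean_pp_deg = mean(.data$pp_deg),
      sd_pp_deg = sd(.data$pp_deg),
      n_animals = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(cycle_index = seq_len(idx_max)) |>
    dplyr::mutate(n_animals = dplyr::coalesce(.data$n_animals, 0L))
}
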