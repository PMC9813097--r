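#' Seeded parameter-recovery replicates for one experimental group
#'
#' Runs the full measurement pipeline end to end, `n_reps` times: simulate
#' the group's cohort under its homeostatic plasticity rule
#' ([simulate_group()]), preprocess every trace into per-cycle amplitudes
#' ([analyze_cohort()]), and fit the pooled setpoint regression
#' ([regress_change()]). Used to check that the analysis recovers the
#' generating slope and setpoint at the published cohort sizes.
#'
#' @param group One of `"old"`, `"young"`, `"cf"`.
#' @param n_reps Number of seeded replicates (>= 1).
#' @param seed Integer base seed; replicate r uses `seed + r - 1`.
#' @param design,params Optional overrides passed to [simulate_group()].
#' @param ... Further arguments to [simulate_group()] (noise settings,
#'   `duration`).
#' @return A tibble with one row per replicate: `replicate`, `seed`,
#'   `slope`, `r_squared`, `x_zero_intercept`, `n_animals`.
#' @export
recover_group <- function(group = c("old", "young", "cf"), n_reps = 20,
                          seed = 1, design = NULL, params = NULL, ...) {
  group <- match.arg(group)
  stopifnot(n_reps >= 1)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    s <- seed + r - 1
    cohort <- simulate_group(group, seed = s, design = design,
                             params = params, ...)
    fit <- regress_change(analyze_cohort(cohort))
    tibble::tibble(
      replicate = r, seed = s,
      slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared,
      x_zero_intercept = fit$x_zero_intercept,
      n_animals = fit$n
    )
  })
}

#' Summarise recovery replicates
#'
#' The slope is averaged directly across replicates (mean and Monte-Carlo
#' standard error = SD / sqrt(replicates)). The setpoint is the x-axis
#' zero-intercept of the replicate-averaged regression line,
#' `x0 = -mean(intercept) / mean(slope)`: the per-replicate ratio
#' `-b0/b1` is heavy-tailed (a single near-flat replicate can make its
#' plain mean arbitrarily large), whereas the ratio of the averaged
#' coefficients is a consistent, stable average of the fitted lines. Its
#' Monte-Carlo SE is estimated by a leave-one-replicate-out jackknife.
#'
#' @param reps A replicate tibble from [recover_group()].
#' @return A one-row tibble: `n_reps`, `slope_mean`, `slope_mcse`,
#'   `x0` (setpoint of the averaged fit), `x0_mcse` (jackknife),
#'   `r2_mean`.
#' @export
summarize_recovery <- function(reps) {
  n <- nrow(reps)
  x0_hat <- -mean(reps$intercept) / mean(reps$slope)
  jk <- vapply(seq_len(n), function(i) {
    -mean(reps$intercept[-i]) / mean(reps$slope[-i])
  }, numeric(1))
  x0_mcse <- sqrt((n - 1) / n * sum((jk - mean(jk))^2))
  tibble::tibble(
    n_reps = n,
    slope_mean = mean(reps$slope),
    slope_mcse = sd(reps$slope) / sqrt(n),
    x0 = x0_hat,
    x0_mcse = x0_mcse,
    r2_mean = mean(reps$r_squared)
  )
}

#' Entrained-amplitude experiment for one paradigm
#'
#' Pushes a pre-training amplitude distribution through the homeostatic
#' rule and the full measurement pipeline, `n_reps` times, and reports the
#' cohort-mean entrained response E (mean peak-to-peak amplitude of the
#' last five valid cycles, averaged across animals).
#'
#' @param paradigm Stimulus paradigm id (1-4).
#' @param n Animals per replicate.
#' @param mean_deg,sd_deg Pre-training amplitude distribution, deg.
#' @param params A [plasticity_params()].
#' @param n_reps Number of seeded replicates.
#' @param seed Integer base seed.
#' @param duration Session duration, s.
#' @param ... Passed to [simulate_cohort()] / [animal_spec()].
#' @return A tibble with one row per replicate: `replicate`, `seed`,
#'   `mean_immediate_deg`, `mean_entrained_deg`, `n_animals`.
#' @export
entrained_mean_experiment <- function(paradigm, n, mean_deg, sd_deg, params,
                                      n_reps = 20, seed = 1,
                                      duration = 1800, ...) {
  profile <- stimulus_profile(paradigm, duration = duration)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    s <- seed + r - 1
    cohort <- simulate_cohort(n, mean_deg, sd_deg, profile, params,
                              seed = s, ...)
    summaries <- analyze_cohort(cohort)
    tibble::tibble(
      replicate = r, seed = s,
      mean_immediate_deg = mean(summaries$immediate_deg),
      mean_entrained_deg = mean(summaries$entrained_deg),
      n_animals = n
    )
  })
}
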