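#' Homeostatic plasticity rule parameters
#'
#' The generator's ground truth is the linear relationship between the
#' training-induced amplitude change and the initial amplitude,
#' `Delta = m * (I - x0)`: a cohort's regression of Delta on I has slope
#' `slope_m` and x-axis zero-intercept (setpoint) `setpoint_x0`. Within a
#' session of `K` cycles the change is spread over cycles as a geometric
#' relaxation towards the setpoint with per-cycle retention
#' `rho = 1 - (1 + slope_m)^(1/K)`, so the cumulative session-end change
#' reproduces the linear rule exactly while giving the early rapid
#' amplitude decrease its graded time course.
#'
#' @param slope_m Dimensionless regression slope of amplitude change vs
#'   initial amplitude; must satisfy -1 < slope_m <= 0.
#' @param setpoint_x0 Amplitude (deg, >= 0) at which training induces no
#'   net change (the homeostatic setpoint).
#' @param residual_sd Animal-level residual scatter of the amplitude change
#'   about the regression line, deg (>= 0). Implemented as a per-animal
#'   perturbation of the setpoint with SD `residual_sd / |slope_m|`, which
#'   yields exactly this residual SD on Delta.
#' @return An object of class `plasticity_params`.
#' @examples
#' plasticity_params(-0.59, 6.4)
#' @export
plasticity_params <- function(slope_m, setpoint_x0, residual_sd = 0) {
  if (!(slope_m > -1 && slope_m <= 0)) {
    abort("`slope_m` must satisfy -1 < slope_m <= 0.")
  }
  if (setpoint_x0 < 0) abort("`setpoint_x0` must be >= 0.")
  if (residual_sd < 0) abort("`residual_sd` must be >= 0.")
  structure(
    list(slope_m = slope_m, setpoint_x0 = setpoint_x0,
         residual_sd = residual_sd),
    class = "plasticity_params"
  )
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf(
    "<plasticity_params> slope %g, setpoint %g deg, residual SD %g deg\n",
    x$slope_m, x$setpoint_x0, x$residual_sd
  ))
  invisible(x)
}

#' Per-cycle retention rate of the relaxation towards the setpoint
#'
#' `rho = 1 - (1 + slope_m)^(1/K)`; lies in `[0, 1)` for admissible
#' parameters. With `rho` applied once per cycle, the deviation from the
#' setpoint shrinks by the factor `(1 + slope_m)` over the whole session.
#'
#' @param params A [plasticity_params()].
#' @param n_cycles Number of complete cycles K in the session (>= 1).
#' @return The retention rate, a number in `[0, 1)`.
#' @export
retention_rate <- function(params, n_cycles) {
  stopifnot(inherits(params, "plasticity_params"), n_cycles >= 1)
  1 - (1 + params$slope_m)^(1 / n_cycles)
}

#' Per-cycle amplitude sequence under the homeostatic rule
#'
#' Starting from the latent initial amplitude `initial` (A_0 = I), cycle k
#' expresses `A_k = A_{k-1} + rho * (x0 - A_k-1) + eps_k`. In the
#' noise-free case this has the closed form
#' `A_k = x0 + (I - x0) * (1 - rho)^k`, so the session-end amplitude is
#' `(1 + m) * I - m * x0`.
#'
#' @param initial Latent initial peak-to-peak amplitude I, deg (> 0).
#' @param params A [plasticity_params()]; `setpoint` may override the
#'   params' setpoint (used internally for animal-level residual scatter).
#' @param n_cycles Number of cycles K.
#' @param gain_noise_sd Per-cycle additive amplitude noise SD, deg.
#' @param setpoint Optional setpoint override, deg.
#' @param closed_form If `TRUE`, evaluate the noise-free closed form
#'   (requires `gain_noise_sd = 0`) instead of iterating the update.
#' @return Numeric vector of K cycle amplitudes (floored at 0, the
#'   physical lower bound).
#' @examples
#' a <- amplitude_series(3.8, plasticity_params(-0.59, 6.4), 90)
#' tail(a, 1) # 5.334 = (1 - 0.59) * 3.8 + 0.59 * 6.4
#' @export
amplitude_series <- function(initial, params, n_cycles, gain_noise_sd = 0,
                             setpoint = NULL, closed_form = FALSE) {
  stopifnot(initial > 0, n_cycles >= 1)
  x0 <- setpoint %||% params$setpoint_x0
  rho <- retention_rate(params, n_cycles)
  if (closed_form) {
    stopifnot(gain_noise_sd == 0)
    a <- x0 + (initial - x0) * (1 - rho)^(seq_len(n_cycles))
  } else {
    a <- numeric(n_cycles)
    prev <- initial
    eps <- if (gain_noise_sd > 0) rnorm(n_cycles, 0, gain_noise_sd) else
      numeric(n_cycles)
    for (k in seq_len(n_cycles)) {
      prev <- prev + rho * (x0 - prev) + eps[k]
      a[k] <- prev
    }
  }
  pmax(a, 0)
}

#' Published group-level plasticity parameters
#'
#' Default generator parameters for the three experimental groups:
#' regression slope and setpoint as reported for old (stage 55-56) and
#' young (stage 50-51) tadpoles and for old animals after climbing-fiber
#' (CF) transection. Residual SDs reproduce the reported R-squared of the
#' pooled regression where one was reported (old 0.765, young 0.378); the
#' CF group's residual is set proportional to the old group's residual
#' relative to its initial-amplitude spread.
#'
#' @param group One of `"old"`, `"young"`, `"cf"`.
#' @return A [plasticity_params()].
#' @export
okr_group_params <- function(group = c("old", "young", "cf")) {
  group <- match.arg(group)
  switch(group,
    old   = plasticity_params(-0.59, 6.4,  residual_sd = 1.8),
    young = plasticity_params(-0.48, 0.6,  residual_sd = 3.5),
    cf    = plasticity_params(-0.29, 0.94, residual_sd = 1.0)
  )
}

#' Cohort designs of the three experimental groups
#'
#' Per-paradigm sample sizes and pre-training amplitude distributions
#' (mean and SD of the initial peak-to-peak OKR amplitude, deg) used by the
#' cohort generator. Old-cohort distributions are the reported pre-training
#' values per stimulus paradigm; the young cohort reuses them (its
#' per-paradigm pre-training distributions were reported only as similarly
#' variable); the CF-transected group was trained with paradigms 3 and 4
#' only.
#'
#' @param group One of `"old"`, `"young"`, `"cf"`.
#' @return A tibble with columns `paradigm`, `n`, `mean_deg`, `sd_deg`.
#' @export
okr_cohort_design <- function(group = c("old", "young", "cf")) {
  group <- match.arg(group)
  base <- tibble::tibble(
    paradigm = 1:4,
    mean_deg = c(7.4, 13.4, 9.7, 3.8),
    sd_deg   = c(5.4, 4.5, 5.0, 1.8)
  )
  switch(group,
    old   = dplyr::mutate(base, n = c(7L, 10L, 10L, 10L), .after = "paradigm"),
    young = dplyr::mutate(base, n = c(8L, 7L, 7L, 6L), .after = "paradigm"),
    cf    = tibble::tibble(
      paradigm = 3:4, n = c(8L, 7L),
      mean_deg = c(7.5, 5.3), sd_deg = c(3.7, 1.8)
    )
  )
}
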