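#' Stimulus motion profiles
#'
#' A stimulus profile describes one session of bidirectional large-field
#' visual motion: a triangular position waveform of constant absolute
#' velocity `speed` that reverses direction every half cycle. The four
#' standard paradigms combine two velocities (4 or 8 deg/s) with two cycle
#' durations (20 or 10 s):
#'
#' | id | speed (deg/s) | period (s) | excursion (deg, peak-to-peak) |
#' |----|---------------|------------|-------------------------------|
#' | 1  | 4             | 20         | 40                            |
#' | 2  | 8             | 20         | 80                            |
#' | 3  | 8             | 10         | 40                            |
#' | 4  | 4             | 10         | 20                            |
#'
#' The peak-to-peak positional excursion of a half cycle is
#' `speed * period / 2`.
#'
#' @param id Integer 1-4 selecting a standard paradigm, or `NULL` to give
#'   `speed` and `period` directly.
#' @param speed Angular speed of the stimulus pattern, deg/s (> 0).
#' @param period Full cycle duration, s (> 0).
#' @param duration Total stimulation time, s (default 1800 = 30 min).
#' @return An object of class `stimulus_profile`: a list with fields
#'   `id`, `speed`, `period`, `duration` and `excursion` (peak-to-peak, deg).
#' @examples
#' stimulus_profile(1)
#' stimulus_profile(speed = 4, period = 20)$excursion # 40
#' @export
stimulus_profile <- function(id = NULL, speed = NULL, period = NULL,
                             duration = 1800) {
  if (!is.null(id)) {
    if (!id %in% 1:4) {
      abort("`id` must be one of 1, 2, 3, 4.")
    }
    speed <- c(4, 8, 8, 4)[id]
    period <- c(20, 20, 10, 10)[id]
  } else {
    if (is.null(speed) || is.null(period)) {
      abort("Give either a profile `id` or both `speed` and `period`.")
    }
    id <- NA_integer_
  }
  if (speed <= 0) abort("`speed` must be > 0.")
  if (period <= 0) abort("`period` must be > 0.")
  if (duration <= 0) abort("`duration` must be > 0 (empty trace).")
  structure(
    list(
      id = as.integer(id),
      speed = speed,
      period = period,
      duration = duration,
      excursion = speed * period / 2
    ),
    class = "stimulus_profile"
  )
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat(sprintf(
    "<stimulus_profile %s> %g deg/s, %g s period, %g s duration (%g deg p-p excursion)\n",
    ifelse(is.na(x$id), "custom", x$id), x$speed, x$period, x$duration,
    x$excursion
  ))
  invisible(x)
}

#' Evaluate triangular stimulus position at arbitrary times
#'
#' The waveform starts at its positive extremum (+excursion/2) at t = 0,
#' moves at constant `-speed` to the negative extremum at period/2 and back,
#' so |d(position)/dt| = `speed` everywhere between extrema.
#'
#' @param t Numeric vector of times, s.
#' @param profile A [stimulus_profile()].
#' @return Positions in degrees.
#' @export
stimulus_position <- function(t, profile) {
  ph <- (t %% profile$period) / profile$period
  unit <- ifelse(ph < 0.5, 1 - 4 * ph, -3 + 4 * ph)
  (profile$excursion / 2) * unit
}

#' Times at which the stimulus is at its positive extremum
#'
#' Cycle boundaries of the analysis: one full cycle runs from one positive
#' extremum to the next (duration = period).
#'
#' @inheritParams stimulus_position
#' @return Numeric vector of extremum times in `[0, duration]`, s.
#' @export
stimulus_extrema <- function(profile) {
  seq(0, profile$duration, by = profile$period)
}

#' Number of complete stimulus cycles in a session
#'
#' @inheritParams stimulus_position
#' @return Integer count.
#' @export
n_cycles <- function(profile) {
  as.integer(floor(profile$duration / profile$period + 1e-9))
}

#' Sample a stimulus position trace on a uniform grid
#'
#' @param profile A [stimulus_profile()].
#' @param rate Sampling rate, Hz.
#' @return A tibble with columns `time_s` and `stim_deg`.
#' @examples
#' stim <- make_stimulus(stimulus_profile(1))
#' max(stim$stim_deg) - min(stim$stim_deg) # 40
#' @export
make_stimulus <- function(profile, rate = 200) {
  stopifnot(inherits(profile, "stimulus_profile"))
  t <- seq(0, profile$duration, by = 1 / rate)
  tibble::tibble(time_s = t, stim_deg = stimulus_position(t, profile))
}
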