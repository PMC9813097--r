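#' Per-animal simulation settings
#'
#' @param initial_amplitude Latent initial peak-to-peak eye amplitude I at
#'   training onset, deg (> 0).
#' @param gain_noise_sd Per-cycle amplitude noise SD, deg.
#' @param fast_phase_rate Rate of injected fast phases (rapid resetting eye
#'   movements), events/min.
#' @param timestamp_jitter_sd SD of Gaussian jitter of frame timestamps
#'   about the nominal 1/frame_rate spacing, s.
#' @param eye_noise_sd Per-frame, per-eye independent angular noise SD, deg
#'   (tracker noise; the two eyes are conjugate up to this noise).
#' @param frame_rate Nominal video frame rate, Hz.
#' @param seed Optional integer seed for reproducible single-animal
#'   simulation.
#' @return An object of class `animal_spec`.
#' @export
animal_spec <- function(initial_amplitude, gain_noise_sd = 0.1,
                        fast_phase_rate = 0.2, timestamp_jitter_sd = 0.003,
                        eye_noise_sd = 0.05, frame_rate = 30, seed = NULL) {
  if (initial_amplitude <= 0) abort("`initial_amplitude` must be > 0.")
  if (gain_noise_sd < 0 || fast_phase_rate < 0 || timestamp_jitter_sd < 0 ||
      eye_noise_sd < 0) {
    abort("noise parameters and rates must be >= 0.")
  }
  structure(
    list(initial_amplitude = initial_amplitude,
         gain_noise_sd = gain_noise_sd,
         fast_phase_rate = fast_phase_rate,
         timestamp_jitter_sd = timestamp_jitter_sd,
         eye_noise_sd = eye_noise_sd,
         frame_rate = frame_rate,
         seed = seed),
    class = "animal_spec"
  )
}

# Half-sine fast-phase pulses added to the conjugate eye position:
# each event deflects the eye by 5-15 deg and returns within 100 ms.
fast_phase_pulse <- function(t, events) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(events))) {
    idx <- which(t >= events$time[i] & t <= events$time[i] + 0.1)
    if (length(idx)) {
      out[idx] <- out[idx] +
        events$amp[i] * sin(pi * (t[idx] - events$time[i]) / 0.1)
    }
  }
  out
}

#' Simulate one animal's eye-movement recording
#'
#' Produces an irregularly sampled (~30 fps) recording of stimulus position
#' and left/right eye angles over one training session. The eye response is
#' a triangular wave phase-locked to the stimulus whose per-cycle
#' peak-to-peak amplitude follows the homeostatic relaxation rule of
#' [amplitude_series()]; the two eyes are conjugate up to small independent
#' noise, and injected fast phases appear as brief high-velocity conjugate
#' deflections.
#'
#' @param spec An [animal_spec()].
#' @param profile A [stimulus_profile()].
#' @param params A [plasticity_params()]. Animal-level residual scatter
#'   (`residual_sd`) perturbs this animal's setpoint.
#' @param seed Optional seed (defaults to `spec$seed`).
#' @return A tibble with columns `time_s`, `stim_deg`, `left_deg`,
#'   `right_deg` and attributes `profile` (the stimulus profile) and
#'   `truth` (a list with the latent initial amplitude, the realised
#'   per-animal setpoint and the per-cycle amplitude sequence).
#' @export
simulate_animal <- function(spec, profile, params, seed = NULL) {
  stopifnot(inherits(spec, "animal_spec"),
            inherits(profile, "stimulus_profile"),
            inherits(params, "plasticity_params"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)

  k_total <- n_cycles(profile)
  if (k_total < 1) abort("session shorter than one stimulus cycle.")

  # Animal-level residual scatter: the relaxation target is x0 + eta with
  # eta ~ N(0, residual_sd / |m|), so the session change carries an
  # additive N(0, residual_sd) residual about the cohort rule. The target
  # is deliberately unbounded (a negative target relaxes the amplitude
  # towards its physical floor of zero).
  setpoint_i <- params$setpoint_x0
  if (params$residual_sd > 0 && abs(params$slope_m) > 1e-12) {
    setpoint_i <- setpoint_i +
      rnorm(1, 0, params$residual_sd / abs(params$slope_m))
  }
  amps <- amplitude_series(spec$initial_amplitude, params, k_total,
                           gain_noise_sd = spec$gain_noise_sd,
                           setpoint = setpoint_i)

  n_frames <- floor(profile$duration * spec$frame_rate) + 1
  t <- seq(0, profile$duration, length.out = n_frames)
  if (spec$timestamp_jitter_sd > 0) {
    t <- t + rnorm(n_frames, 0, spec$timestamp_jitter_sd)
    t <- sort(pmin(pmax(t, 0), profile$duration))
    # guard against exact ties after clamping
    while (any(d0 <- diff(t) <= 0)) t[which(d0) + 1] <- t[which(d0)] + 1e-6
  }

  ph <- (t %% profile$period) / profile$period
  unit <- ifelse(ph < 0.5, 1 - 4 * ph, -3 + 4 * ph)
  cyc <- pmin(floor(t / profile$period) + 1, k_total)
  eye <- (amps[cyc] / 2) * unit

  n_ev <- rpois(1, spec$fast_phase_rate * profile$duration / 60)
  if (n_ev > 0) {
    events <- data.frame(
      time = runif(n_ev, 0, profile$duration - 0.1),
      amp = sample(c(-1, 1), n_ev, replace = TRUE) * runif(n_ev, 5, 15)
    )
    eye <- eye + fast_phase_pulse(t, events)
  }

  left <- eye + rnorm(n_frames, 0, spec$eye_noise_sd)
  right <- eye + rnorm(n_frames, 0, spec$eye_noise_sd)

  out <- tibble::tibble(
    time_s = t,
    stim_deg = stimulus_position(t, profile),
    left_deg = left,
    right_deg = right
  )
  attr(out, "profile") <- profile
  attr(out, "truth") <- list(
    initial = spec$initial_amplitude,
    setpoint = setpoint_i,
    amplitudes = amps
  )
  out
}

#' Simulate a cohort of animals
#'
#' Draws latent initial amplitudes from a normal distribution truncated
#' below at `floor_deg`, simulates each animal with [simulate_animal()],
#' and returns a nested tibble carrying both the traces and the generator
#' ground truth for recovery tests.
#'
#' @param n Number of animals (>= 1).
#' @param mean_deg,sd_deg Mean and SD of the initial-amplitude
#'   distribution, deg.
#' @param profile A [stimulus_profile()].
#' @param params A [plasticity_params()].
#' @param seed Optional integer seed; fixed seeds give identical cohorts.
#' @param floor_deg Truncation floor of the initial-amplitude draw, deg.
#' @param ... Further arguments passed to [animal_spec()] (noise settings).
#' @return A tibble with one row per animal: `animal_id`, `paradigm`,
#'   `initial_deg` (latent I), `setpoint_deg` (realised per-animal
#'   setpoint), `expected_entrained_deg` (closed-form session-end
#'   amplitude), and a list-column `trace` of recordings.
#' @export
simulate_cohort <- function(n, mean_deg, sd_deg, profile, params,
                            seed = NULL, floor_deg = 0.5, ...) {
  if (n < 1) abort("`n` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  draw_truncated <- function(n) {
    x <- rnorm(n, mean_deg, sd_deg)
    while (any(bad <- x < floor_deg)) {
      x[bad] <- rnorm(sum(bad), mean_deg, sd_deg)
    }
    x
  }
  initial <- draw_truncated(n)
  rows <- purrr::map(seq_len(n), function(i) {
    tr <- simulate_animal(animal_spec(initial[i], ...), profile, params)
    truth <- attr(tr, "truth")
    tibble::tibble(
      animal_id = i,
      paradigm = profile$id,
      initial_deg = truth$initial,
      setpoint_deg = truth$setpoint,
      expected_entrained_deg =
        (1 + params$slope_m) * truth$initial +
        (-params$slope_m) * truth$setpoint,
      trace = list(tr)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a multi-paradigm experimental group
#'
#' Builds a full cohort for one experimental group from its design table
#' ([okr_cohort_design()]) and plasticity parameters ([okr_group_params()]),
#' concatenating per-paradigm sub-cohorts.
#'
#' @param group One of `"old"`, `"young"`, `"cf"`.
#' @param seed Integer seed.
#' @param design Optional design override (tibble as from
#'   [okr_cohort_design()]).
#' @param params Optional [plasticity_params()] override.
#' @param duration Session duration, s.
#' @param ... Passed to [simulate_cohort()] / [animal_spec()].
#' @return A nested tibble as from [simulate_cohort()], with unique
#'   `animal_id` across paradigms and a `group` column.
#' @export
simulate_group <- function(group = c("old", "young", "cf"), seed = NULL,
                           design = NULL, params = NULL, duration = 1800,
                           ...) {
  group <- match.arg(group)
  design <- design %||% okr_cohort_design(group)
  params <- params %||% okr_group_params(group)
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::pmap(design, function(paradigm, n, mean_deg, sd_deg) {
    profile <- stimulus_profile(paradigm, duration = duration)
    simulate_cohort(n, mean_deg, sd_deg, profile, params, ...)
  })
  out <- dplyr::bind_rows(out)
  out$animal_id <- seq_len(nrow(out))
  dplyr::mutate(out, group = group, .before = 1)
}
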