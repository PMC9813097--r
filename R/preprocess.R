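#' Resample and low-pass filter a raw recording
#'
#' Irregularly sampled stimulus and eye traces are linearly interpolated
#' onto a uniform grid at `rate` and low-pass filtered with a zero-phase
#' Butterworth filter (an order-`order` design applied forward-backward,
#' so the net magnitude response is the squared one-pass response and the
#' phase is zero). Edge transients are suppressed by odd-reflection padding
#' before filtering.
#'
#' @param trace A tibble with strictly increasing `time_s` plus any of the
#'   series columns `stim_deg`, `left_deg`, `right_deg`, `eye_deg`.
#' @param rate Target sampling rate, Hz (default 200).
#' @param cutoff Low-pass cutoff, Hz (default 4).
#' @param order Butterworth order of the one-pass design (default 4).
#' @return A uniformly sampled tibble with the same columns; the `profile`
#'   attribute (if any) is carried over, and the original timestamps are
#'   kept in attribute `raw_time_s` for gap bookkeeping.
#' @export
resample_filter <- function(trace, rate = 200, cutoff = 4, order = 4) {
  t <- trace$time_s
  if (length(t) < 2) abort("need at least 2 samples.")
  if (any(diff(t) <= 0)) abort("timestamps must be strictly increasing.")
  if (diff(range(t)) <= 1 / cutoff) {
    abort("recording shorter than one filter time constant.")
  }
  grid <- seq(t[1], t[length(t)], by = 1 / rate)
  filt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  series <- intersect(c("stim_deg", "left_deg", "right_deg", "eye_deg"),
                      names(trace))
  out <- tibble::tibble(time_s = grid)
  for (nm in series) {
    y <- approx(t, trace[[nm]], xout = grid, rule = 2)$y
    out[[nm]] <- zero_phase_filter(filt, y)
  }
  attr(out, "profile") <- attr(trace, "profile")
  attr(out, "raw_time_s") <- t
  out
}

# Zero-phase filtering with odd-reflection padding at both ends, which
# removes the startup transient of plain forward-backward filtering.
zero_phase_filter <- function(filt, y) {
  n <- length(y)
  pad <- min(n - 1, 3 * ceiling(length(filt$b) * 50))
  pre <- 2 * y[1] - y[seq(pad + 1, 2)]
  post <- 2 * y[n] - y[seq(n - 1, n - pad)]
  z <- c(pre, y, post)
  z <- iir_pass(filt$b, filt$a, z)
  z <- rev(iir_pass(filt$b, filt$a, rev(z)))
  z[(pad + 1):(pad + n)]
}

# One forward IIR pass (direct form: MA by convolution, AR recursively),
# via the C implementations in stats::filter. a[1] must be 1 (as returned
# by signal::butter).
iir_pass <- function(b, a, x) {
  v <- stats::filter(c(rep(0, length(b) - 1), x), b,
                     method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(length(b) - 1)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Segment a uniform recording into stimulus cycles
#'
#' Cycle boundaries are the analytically known positive extrema of the
#' stimulus command (one cycle = positive extremum to the next, duration =
#' one period), not detected from the recorded stimulus. Leading/trailing
#' partial segments are flagged `reason = "edge"`.
#'
#' @param trace A uniformly sampled recording (as from [resample_filter()]).
#' @param profile A [stimulus_profile()]; defaults to the trace's
#'   `profile` attribute.
#' @return A tibble of cycle windows: `cycle_index`, `t_start_s`,
#'   `t_end_s`, `valid` (TRUE for full cycles at this stage), `reason`
#'   (`NA` or `"edge"`).
#' @export
segment_cycles <- function(trace, profile = NULL) {
  profile <- profile %||% attr(trace, "profile")
  if (is.null(profile)) abort("stimulus profile unknown.")
  t0 <- trace$time_s[1]
  t1 <- trace$time_s[nrow(trace)]
  tol <- 1.5 * (trace$time_s[2] - trace$time_s[1]) # one-sample slack
  bounds <- stimulus_extrema(profile)
  bounds <- bounds[bounds >= t0 - tol & bounds <= t1 + tol]
  if (length(bounds) < 2) abort("no full cycles: duration < one period.")
  cycles <- tibble::tibble(
    cycle_index = seq_len(length(bounds) - 1),
    t_start_s = bounds[-length(bounds)],
    t_end_s = bounds[-1]
  )
  full <- cycles$t_start_s >= t0 - tol & cycles$t_end_s <= t1 + tol
  if (!any(full)) abort("no full cycles: duration < one period.")
  dplyr::mutate(cycles,
    valid = full,
    reason = ifelse(full, NA_character_, "edge")
  )
}

#' Average the two eyes into a conjugate response
#'
#' Sample-wise mean of `left_deg` and `right_deg` in the shared sign
#' convention. If one eye is entirely missing the other is returned with a
#' warning; anticorrelated eyes (negative correlation, suggesting a sign-
#' convention error) also raise a warning.
#'
#' @param trace A recording tibble with `left_deg` and/or `right_deg`.
#' @return The tibble with an added `eye_deg` column.
#' @export
conjugate_average <- function(trace) {
  has_l <- "left_deg" %in% names(trace) && !all(is.na(trace$left_deg))
  has_r <- "right_deg" %in% names(trace) && !all(is.na(trace$right_deg))
  if (!has_l && !has_r) abort("both eye traces missing.")
  if (has_l && has_r) {
    cc <- suppressWarnings(cor(trace$left_deg, trace$right_deg))
    if (is.finite(cc) && cc < 0) {
      warn("left and right eye traces are anticorrelated; check the sign convention.")
    }
    eye <- (trace$left_deg + trace$right_deg) / 2
  } else {
    warn(sprintf("only the %s eye present; using it as the conjugate trace.",
                 if (has_l) "left" else "right"))
    eye <- if (has_l) trace$left_deg else trace$right_deg
  }
  dplyr::mutate(trace, eye_deg = eye)
}

#' Flag artifact-contaminated cycles
#'
#' A cycle is invalidated when the peak absolute eye velocity within it
#' exceeds `max(threshold_abs, factor * speed)` - an automated surrogate
#' for manual exclusion of cycles with fast phases or jerking movements.
#' Cycles overlapping long acquisition gaps (from the raw timestamps) are
#' invalidated with `reason = "missing"`.
#'
#' @param trace A uniform recording with an `eye_deg` column.
#' @param cycles Cycle windows from [segment_cycles()].
#' @param speed Stimulus speed, deg/s; defaults to the trace profile's.
#' @param factor Velocity threshold as a multiple of stimulus speed.
#' @param threshold_abs Absolute velocity threshold floor, deg/s.
#' @param max_gap_s Raw-timestamp gaps longer than this invalidate
#'   overlapping cycles, s.
#' @param min_valid Minimum number of valid cycles required.
#' @return `cycles` with updated `valid`/`reason`.
#' @export
detect_artifact_cycles <- function(trace, cycles, speed = NULL, factor = 3,
                                   threshold_abs = 20, max_gap_s = 0.5,
                                   min_valid = 10) {
  speed <- speed %||% attr(trace, "profile")$speed
  if (is.null(speed)) abort("stimulus speed unknown.")
  thr <- max(threshold_abs, factor * speed)
  t <- trace$time_s
  dt <- diff(t)
  if (max(dt) - min(dt) < 1e-9) dt <- dt[1] # uniform grid fast path
  vel <- abs(c(0, diff(trace$eye_deg) / dt))
  rng <- cycle_sample_ranges(t, cycles)
  vmax <- vapply(seq_len(nrow(cycles)), function(i) {
    if (rng$lo[i] > rng$hi[i]) return(Inf)
    max(vel[rng$lo[i]:rng$hi[i]])
  }, numeric(1))
  fast <- cycles$valid & vmax > thr
  cycles$valid[fast] <- FALSE
  cycles$reason[fast] <- "fast_phase"

  raw_t <- attr(trace, "raw_time_s")
  if (!is.null(raw_t) && length(raw_t) > 1) {
    gaps <- which(diff(raw_t) > max_gap_s)
    for (g in gaps) {
      hit <- cycles$t_start_s < raw_t[g + 1] & cycles$t_end_s > raw_t[g]
      cycles$valid[hit] <- FALSE
      cycles$reason[hit] <- "missing"
    }
  }
  if (sum(cycles$valid) < min_valid) {
    abort(sprintf("insufficient valid cycles (%d < %d).",
                  sum(cycles$valid), min_valid))
  }
  cycles
}

#' Per-cycle peak-to-peak amplitudes
#'
#' `pp_deg` is max - min of the conjugate eye trace within each cycle
#' window.
#'
#' @param trace A uniform recording with an `eye_deg` column.
#' @param cycles Cycle windows (with validity flags).
#' @return A cycle table: `cycle_index`, `t_start_s`, `t_end_s`, `pp_deg`,
#'   `valid`, `reason`.
#' @export
cycle_amplitudes <- function(trace, cycles) {
  t <- trace$time_s
  eye <- trace$eye_deg
  rng <- cycle_sample_ranges(t, cycles)
  pp <- vapply(seq_len(nrow(cycles)), function(i) {
    if (rng$lo[i] > rng$hi[i]) return(NA_real_)
    s <- eye[rng$lo[i]:rng$hi[i]]
    max(s) - min(s)
  }, numeric(1))
  dplyr::mutate(cycles, pp_deg = pp, .before = "valid")
}

# First/last sample index of each cycle window [t_start, t_end), exploiting
# that `t` is sorted and windows are contiguous.
cycle_sample_ranges <- function(t, cycles) {
  eps <- 1e-12
  list(
    lo = findInterval(cycles$t_start_s - eps, t) + 1L,
    hi = findInterval(cycles$t_end_s - eps, t)
  )
}

#' Raw recording to per-cycle amplitude table
#'
#' Runs the full preprocessing chain: [resample_filter()],
#' [conjugate_average()], [segment_cycles()], [detect_artifact_cycles()],
#' [cycle_amplitudes()].
#'
#' @param trace A raw recording tibble (`time_s`, `stim_deg`, `left_deg`,
#'   `right_deg`) with a `profile` attribute (or pass `profile`).
#' @param profile Optional [stimulus_profile()] override.
#' @param rate,cutoff Resampling rate and filter cutoff, Hz.
#' @param ... Passed to [detect_artifact_cycles()].
#' @return A cycle table as from [cycle_amplitudes()].
#' @export
process_recording <- function(trace, profile = NULL, rate = 200, cutoff = 4,
                              ...) {
  profile <- profile %||% attr(trace, "profile")
  # Averaging the eyes first is exactly equivalent to averaging after the
  # (linear) interpolation and filtering, and halves the filtering work;
  # the analytic cycle segmentation never consults the recorded stimulus.
  conj <- conjugate_average(trace)
  u <- resample_filter(conj[, c("time_s", "eye_deg")],
                       rate = rate, cutoff = cutoff)
  attr(u, "profile") <- profile
  cycles <- segment_cycles(u, profile)
  cycles <- detect_artifact_cycles(u, cycles, speed = profile$speed, ...)
  cycle_amplitudes(u, cycles)
}
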