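# Independent brute-force oracles used across the suite.

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments (doubled smaller tail, capped at 1).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments of the pooled ranks.
oracle_mann_whitney_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(length(r), nx)
  u_all <- apply(cmb, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Triangle-wave peak-to-peak attenuation through a zero-phase (squared-
# magnitude) digital filter: sum the Fourier series of the triangle at the
# apex, weighting each odd harmonic by |H(f_k)|^2 from signal::freqz.
oracle_triangle_attenuation <- function(filt, fundamental_hz, rate,
                                        n_harmonics = 399) {
  k <- seq(1, n_harmonics, by = 2)
  f <- k * fundamental_hz
  f <- f[f < rate / 2]
  k <- k[seq_along(f)]
  h <- signal::freqz(filt$b, filt$a, n = f, Fs = rate)
  gain2 <- Mod(h$h)^2
  coefs <- 1 / k^2 # apex-aligned harmonic amplitudes, up to a common factor
  1 - sum(coefs * gain2) / sum(coefs)
}

# Magnitude-squared response of the zero-phase filter at one frequency.
# (freqz treats a scalar n as a point count, so pass a length-2 vector.)
oracle_gain2 <- function(filt, f_hz, rate) {
  h <- signal::freqz(filt$b, filt$a, n = c(f_hz, f_hz), Fs = rate)
  Mod(h$h[1])^2
}

# A rasterised filled ellipse mask (row/col raster, y-axis down), rotated
# `angle_deg` counterclockwise with y up.
oracle_ellipse_mask <- function(nrow, ncol, center, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  xs <- seq_len(ncol)
  ys <- seq_len(nrow)
  dx <- outer(rep(1, nrow), xs - center[1])
  dy <- outer(-(ys - center[2]), rep(1, ncol))
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  u^2 + v^2 <= 1
}

# Quick noise-free animal settings (individual noise terms overridable).
quiet_spec <- function(initial, ...) {
  args <- modifyList(
    list(initial_amplitude = initial, gain_noise_sd = 0,
         fast_phase_rate = 0, timestamp_jitter_sd = 0, eye_noise_sd = 0),
    list(...)
  )
  do.call(animal_spec, args)
}
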