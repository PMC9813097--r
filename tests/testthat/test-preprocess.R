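test_that("resampling then filtering a constant is the identity", {
  tr <- tibble::tibble(
    time_s = sort(runif(200, 0, 20)),
    stim_deg = 5, left_deg = 5, right_deg = 5
  )
  u <- resample_filter(tr)
  expect_equal(diff(u$time_s), rep(1 / 200, nrow(u) - 1))
  expect_equal(u$stim_deg, rep(5, nrow(u)), tolerance = 1e-9)
  expect_equal(u$left_deg, rep(5, nrow(u)), tolerance = 1e-9)
})

test_that("filter is zero-phase and has the designed band edges", {
  p <- stimulus_profile(1, duration = 120)
  raw <- make_stimulus(p, rate = 200) # on-grid apexes: no resampling clip
  tr <- tibble::tibble(time_s = raw$time_s, stim_deg = raw$stim_deg,
                       left_deg = raw$stim_deg, right_deg = raw$stim_deg)
  u <- resample_filter(tr)
  stim_ref <- stimulus_position(u$time_s, p)

  # zero-phase: cross-correlation between filtered and analytic stimulus
  # peaks at zero lag
  cc <- ccf(u$stim_deg, stim_ref, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # passband: 0.05 Hz triangle peak-to-peak attenuation < 2 %, and matched
  # by the harmonic-sum oracle
  filt <- signal::butter(4, 4 / 100, type = "low")
  att_oracle <- oracle_triangle_attenuation(filt, 0.05, 200)
  att <- 1 - diff(range(u$stim_deg)) / p$excursion
  expect_lt(att, 0.02)
  expect_lt(att_oracle, 0.02)
  expect_lt(abs(att - att_oracle), 2e-3)

  # stopband: a 10 Hz sinusoid leaves < 1 % residual
  t10 <- seq(0, 30, by = 1 / 200)
  tr10 <- tibble::tibble(time_s = t10, stim_deg = sin(2 * pi * 10 * t10),
                         left_deg = 0, right_deg = 0)
  u10 <- resample_filter(tr10)
  mid <- u10$time_s > 5 & u10$time_s < 25
  expect_lt(max(abs(u10$stim_deg[mid])), 0.01)
  expect_lt(oracle_gain2(filt, 10, 200), 0.01)
})

test_that("resample_filter rejects bad input", {
  bad <- tibble::tibble(time_s = c(0, 2, 1), stim_deg = 1:3,
                        left_deg = 1:3, right_deg = 1:3)
  expect_error(resample_filter(bad), "increasing")
  expect_error(
    resample_filter(tibble::tibble(time_s = 1, stim_deg = 1,
                                   left_deg = 1, right_deg = 1)),
    "2 samples"
  )
})

test_that("cycle segmentation uses analytic extrema", {
  p <- stimulus_profile(1) # 1800 s, 20 s period
  tr <- simulate_animal(quiet_spec(7), p, plasticity_params(-0.5, 6),
                        seed = 1)
  u <- resample_filter(conjugate_average(tr)[, c("time_s", "eye_deg")])
  attr(u, "profile") <- p
  cycles <- segment_cycles(u, p)
  expect_equal(sum(cycles$valid), 90)
  # boundaries coincide with stimulus extrema to within one sample
  expect_true(all(abs(cycles$t_start_s %% p$period) < 1.5 / 200 |
                    abs(cycles$t_start_s %% p$period - p$period) < 1.5 / 200))
  # durations equal one period
  expect_equal(unique(cycles$t_end_s - cycles$t_start_s), p$period)

  short <- stimulus_profile(1, duration = 15)
  tr_s <- make_stimulus(short, rate = 200)
  tr_s <- tibble::tibble(time_s = tr_s$time_s, eye_deg = tr_s$stim_deg)
  expect_error(segment_cycles(tr_s, short), "no full cycles")
})

test_that("conjugate averaging follows the shared sign convention", {
  tr <- tibble::tibble(time_s = seq(0, 10, by = 0.1),
                       left_deg = sin(seq(0, 10, by = 0.1)))
  tr$right_deg <- tr$left_deg
  expect_equal(conjugate_average(tr)$eye_deg, tr$left_deg)
  tr$right_deg <- tr$left_deg + 2
  expect_equal(conjugate_average(tr)$eye_deg, tr$left_deg + 1)
  # anticorrelated eyes suggest a sign-convention error
  tr$right_deg <- -tr$left_deg + 0.01
  expect_warning(conjugate_average(tr), "anticorrelated")
  # single-eye fallback
  tr$right_deg <- NA_real_
  expect_warning(out <- conjugate_average(tr), "left eye")
  expect_equal(out$eye_deg, tr$left_deg)
  tr$left_deg <- NA_real_
  expect_error(suppressWarnings(conjugate_average(tr)), "missing")
})

test_that("velocity criterion flags fast-phase cycles", {
  p <- stimulus_profile(1, duration = 400)
  tr <- simulate_animal(quiet_spec(7), p, plasticity_params(0, 7), seed = 2)
  # clean recording: nothing flagged
  ct <- process_recording(tr)
  expect_equal(sum(!ct$valid), 0)
  # inject a 50 deg/s excursion into cycle 5 (threshold max(20, 3*4) = 20)
  tr2 <- tr
  hit <- tr2$time_s >= 85 & tr2$time_s <= 86
  bump <- 50 * (tr2$time_s[hit] - 85)
  tr2$left_deg[hit] <- tr2$left_deg[hit] + bump
  tr2$right_deg[hit] <- tr2$right_deg[hit] + bump
  ct2 <- process_recording(tr2)
  expect_false(ct2$valid[5])
  expect_equal(ct2$reason[5], "fast_phase")
  expect_true(all(ct2$valid[-5]))
  # all cycles contaminated -> error
  tr3 <- tr
  tr3$left_deg <- tr3$left_deg + 10 * sin(2 * pi * 3 * tr3$time_s)
  tr3$right_deg <- tr3$left_deg
  expect_error(process_recording(tr3), "insufficient valid cycles")
})

test_that("long acquisition gaps invalidate overlapping cycles", {
  p <- stimulus_profile(1, duration = 300)
  tr <- simulate_animal(quiet_spec(6), p, plasticity_params(0, 6), seed = 4)
  tr_gap <- tr[!(tr$time_s > 110 & tr$time_s < 112), ]
  attr(tr_gap, "profile") <- p
  ct <- process_recording(tr_gap)
  gap_cycle <- which(ct$t_start_s <= 111 & ct$t_end_s >= 111)
  expect_false(any(ct$valid[gap_cycle]))
  expect_true(all(ct$reason[gap_cycle] == "missing"))
})

test_that("peak-to-peak amplitude is exact on simple waveforms", {
  t <- seq(0, 40, by = 1 / 200)
  # triangular response spanning +-2 deg
  p <- stimulus_profile(1, duration = 40)
  tri <- tibble::tibble(time_s = t,
                        eye_deg = 4 / 40 * stimulus_position(t, p))
  attr(tri, "profile") <- p
  cyc <- segment_cycles(tri, p)
  expect_equal(cycle_amplitudes(tri, cyc)$pp_deg, c(4, 4), tolerance = 1e-9)
  # sinusoid of amplitude A has pp = 2A
  sine <- tibble::tibble(time_s = t, eye_deg = 3 * sin(2 * pi * t / 20))
  expect_equal(cycle_amplitudes(sine, cyc)$pp_deg, c(6, 6),
               tolerance = 1e-4)
})

test_that("measured amplitudes track the generator within 2 % on all profiles", {
  for (id in 1:4) {
    p <- stimulus_profile(id, duration = 600)
    tr <- simulate_animal(quiet_spec(7), p, plasticity_params(-0.59, 3),
                          seed = id)
    ct <- process_recording(tr)
    truth <- attr(tr, "truth")$amplitudes[ct$cycle_index]
    rel <- abs(ct$pp_deg - truth) / truth
    expect_lt(max(rel), 0.02)
  }
})
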