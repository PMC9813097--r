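make_ct <- function(pp, valid = TRUE) {
  n <- length(pp)
  tibble::tibble(
    cycle_index = seq_len(n), t_start_s = (seq_len(n) - 1) * 20,
    t_end_s = seq_len(n) * 20, pp_deg = pp,
    valid = rep_len(valid, n), reason = NA_character_
  )
}

test_that("immediate/entrained means use the first and last five valid cycles", {
  # constant amplitudes: I = E, delta = 0
  s <- immediate_entrained(make_ct(rep(4.2, 30)))
  expect_equal(s$immediate_deg, 4.2)
  expect_equal(s$delta_deg, 0)
  # arithmetic on 1..10
  s2 <- immediate_entrained(make_ct(1:10))
  expect_equal(s2$immediate_deg, 3)
  expect_equal(s2$entrained_deg, 8)
  # skip-and-extend when the first cycle is invalid
  ct <- make_ct(1:11)
  ct$valid[1] <- FALSE
  s3 <- immediate_entrained(ct)
  expect_equal(s3$immediate_deg, mean(2:6))
  # delta identity to machine precision
  expect_identical(s3$delta_deg, s3$entrained_deg - s3$immediate_deg)
  expect_error(immediate_entrained(make_ct(1:8)), "too few valid")
})

test_that("setpoint regression recovers an exact linear rule", {
  i <- c(2, 4, 5, 8, 11)
  s <- tibble::tibble(immediate_deg = i, delta_deg = -0.5 * (i - 6))
  fit <- suppressWarnings(regress_change(s)) # perfect fit: summary.lm warns
  expect_equal(fit$slope, -0.5)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$x_zero_intercept, 6)
  expect_equal(fit$n, 5)
  # broom-style accessors (perfect fit: lm's zero-residual warning is moot)
  td <- suppressWarnings(tidy(fit))
  expect_equal(unname(td$estimate[td$term == "immediate_deg"]), -0.5)
  gl <- glance(fit)
  expect_equal(gl$x_zero_intercept, 6)
})

test_that("flat and degenerate regressions are handled explicitly", {
  s <- tibble::tibble(immediate_deg = c(2, 5, 9), delta_deg = c(0, 0, 0))
  fit <- suppressWarnings(regress_change(s))
  expect_equal(fit$slope, 0)
  expect_true(is.na(fit$x_zero_intercept))
  expect_error(
    regress_change(tibble::tibble(immediate_deg = c(3, 3, 3),
                                  delta_deg = c(1, 0, 2))),
    "degenerate"
  )
  expect_error(
    regress_change(tibble::tibble(immediate_deg = c(1, 2),
                                  delta_deg = c(0, 1))),
    "at least 3"
  )
})

test_that("regression is equivariant under a change of amplitude units", {
  set.seed(42)
  i <- runif(20, 2, 14)
  s <- tibble::tibble(immediate_deg = i,
                      delta_deg = -0.59 * (i - 6.4) + rnorm(20, 0, 1))
  f1 <- regress_change(s)
  c_scale <- 3.7
  f2 <- regress_change(tibble::tibble(immediate_deg = c_scale * i,
                                      delta_deg = c_scale * s$delta_deg))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$x_zero_intercept, c_scale * f1$x_zero_intercept,
               tolerance = 1e-12)
})

test_that("confidence band brackets the fitted line", {
  set.seed(7)
  i <- runif(15, 2, 12)
  s <- tibble::tibble(immediate_deg = i,
                      delta_deg = -0.5 * (i - 6) + rnorm(15, 0, 0.8))
  band <- confidence_band(regress_change(s))
  expect_true(all(band$lwr_deg <= band$fit_deg))
  expect_true(all(band$upr_deg >= band$fit_deg))
})

test_that("training homogenizes amplitudes as the rule predicts", {
  # identical animals: zero SD before and after
  s0 <- tibble::tibble(paradigm = 1, immediate_deg = rep(5, 4),
                       entrained_deg = rep(6, 4))
  v0 <- variability_metrics(s0)
  expect_equal(v0$sd_immediate_deg[v0$paradigm == "pooled"], 0)
  expect_equal(v0$sd_entrained_deg[v0$paradigm == "pooled"], 0)

  # active rule: E = (1+m) I - m x0 (+ residual), so
  # SD(E) = sqrt((1+m)^2 SD(I)^2 + residual^2) < SD(I)
  set.seed(8)
  m <- -0.59; x0 <- 6.4; sd_i <- 5.4; res <- 1.8; n <- 400
  i <- rnorm(n, 7.4, sd_i)
  e <- (1 + m) * i - m * x0 + rnorm(n, 0, res)
  s1 <- tibble::tibble(paradigm = 1, immediate_deg = i, entrained_deg = e)
  v1 <- variability_metrics(s1)
  sd_e_pred <- sqrt((1 + m)^2 * sd_i^2 + res^2)
  expect_lt(v1$sd_entrained_deg[1], v1$sd_immediate_deg[1])
  expect_equal(v1$sd_entrained_deg[1], sd_e_pred, tolerance = 0.15)

  # slope 0: no contraction
  e2 <- i + rnorm(n, 0, 0.1)
  v2 <- variability_metrics(
    tibble::tibble(paradigm = 1, immediate_deg = i, entrained_deg = e2)
  )
  expect_equal(v2$sd_entrained_deg[1], v2$sd_immediate_deg[1],
               tolerance = 0.05)
})

test_that("population cycle average matches individuals and the closed form", {
  # identical animals: population curve equals the individual curve
  ct <- make_ct(10:1)
  pop <- population_cycle_average(list(ct, ct, ct))
  expect_equal(pop$mean_pp_deg, as.numeric(10:1))
  expect_true(all(pop$n_animals == 3))

  # noiseless decaying cohort matches the geometric relaxation closed form
  p <- stimulus_profile(1, duration = 400)
  params <- plasticity_params(-0.59, 6.4)
  cohort <- simulate_cohort(3, 11, 0.8, p, params, seed = 31,
                            gain_noise_sd = 0, fast_phase_rate = 0,
                            timestamp_jitter_sd = 0, eye_noise_sd = 0)
  res <- analyze_cohort(cohort)
  pop2 <- population_cycle_average(res)
  expected <- rowMeans(vapply(
    cohort$trace, function(tr) attr(tr, "truth")$amplitudes,
    numeric(n_cycles(p))
  ))
  expect_equal(pop2$mean_pp_deg, expected, tolerance = 0.02)

  # an animal with no valid cycles is excluded with a warning
  bad <- make_ct(10:1, valid = FALSE)
  expect_warning(pop3 <- population_cycle_average(list(ct, bad)),
                 "excluded")
  expect_true(all(pop3$n_animals == 1))

  # a cycle index with no contributors is a gap, not zero
  short <- make_ct(c(5, 5))
  pop4 <- population_cycle_average(list(short, make_ct(rep(5, 4))))
  expect_equal(pop4$n_animals, c(2L, 2L, 1L, 1L))
})

test_that("plots build without error", {
  set.seed(9)
  i <- runif(12, 2, 12)
  fit <- regress_change(
    tibble::tibble(immediate_deg = i,
                   delta_deg = -0.5 * (i - 6) + rnorm(12, 0, 0.5))
  )
  expect_s3_class(autoplot(fit), "ggplot")
  pop <- population_cycle_average(list(make_ct(10:1)))
  expect_s3_class(plot_population_average(pop, period_s = 20), "ggplot")
  tr <- tibble::tibble(time_s = seq(0, 10, 0.1),
                       stim_deg = sin(seq(0, 10, 0.1)),
                       left_deg = 0.5 * sin(seq(0, 10, 0.1)),
                       right_deg = 0.5 * sin(seq(0, 10, 0.1)))
  expect_s3_class(plot_trace(tr), "ggplot")
})
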