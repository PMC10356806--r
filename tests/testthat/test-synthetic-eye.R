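# The generator must reproduce its own closed-form kernel, honor the
# stimulation protocol, and be reproducible from its seed.

test_that("kernel closed form is honored by the generated trace", {
  p <- quiet_params(drive_amp = 4, drive_tau = 0.02, hold_velocity = 0,
                    led_durations = 1000, n_repeats_per_duration = 1)
  sim <- gen_opto_eye_trace(p)
  i <- which.min(abs(sim$trace$time_s - (sim$schedule$onset_s[1] + 0.1)))
  expect_equal(eye_magnitude(sim$trace$h_deg[i], sim$trace$v_deg[i]),
               4 * (1 - exp(-5)), tolerance = 1e-9)
  # direction projection preserves the sign convention
  expect_true(all(sim$trace$h_deg >= -1e-12))  # naso-temporal positive
  expect_true(all(sim$trace$v_deg <= 1e-12))   # downward negative
})

test_that("the full stimulation protocol yields 60 x 5 = 300 epochs", {
  p <- quiet_params(sample_rate = 100,
                    led_durations = c(50, 100, 200, 500, 1000),
                    n_repeats_per_duration = 60)
  sim <- gen_opto_eye_trace(p)
  expect_identical(nrow(sim$schedule), 300L)
  expect_identical(as.vector(table(sim$schedule$duration_ms)),
                   rep(60L, 5))
  # epochs are disjoint and ordered
  expect_true(all(diff(sim$schedule$onset_s) > 0))
  expect_true(all(sim$schedule$offset_s[-300] < sim$schedule$onset_s[-1]))
})

test_that("same seed reproduces the trace; different seeds do not", {
  p <- small_protocol(n = 2, seed = 11)
  a <- gen_opto_eye_trace(p)
  b <- gen_opto_eye_trace(p)
  expect_identical(a$trace, b$trace)
  p2 <- p
  p2$seed <- 12L
  c <- gen_opto_eye_trace(p2)
  expect_false(identical(a$trace, c$trace))
})

test_that("numerical velocity of a noiseless trace matches the analytic derivative", {
  p <- quiet_params(led_durations = 500, n_repeats_per_duration = 1)
  sim <- gen_opto_eye_trace(p)
  on <- sim$schedule$onset_s[1]
  t_rel <- sim$trace$time_s - on
  mag <- eye_magnitude(sim$trace$h_deg, sim$trace$v_deg)
  v_num <- central_diff_local(mag, 1 / p$sample_rate)
  v_ana <- opto_kernel_velocity(t_rel, p, 0.5)
  # kernel derivative is discontinuous at LED onset/offset: skip +-2 samples
  kinks <- c(on, on + 0.5)
  ok <- seq_along(t_rel) > 2 & seq_along(t_rel) < length(t_rel) - 1
  for (k in kinks) ok <- ok & abs(sim$trace$time_s - k) > 2.5 / p$sample_rate
  expect_lt(max(abs(v_num[ok] - v_ana[ok])), 0.05)
})

test_that("quick phases are the only source of supra-threshold speed", {
  quiet <- gen_opto_eye_trace(small_protocol(noise_sd = 0, saccade_rate = 0))
  vq <- compute_velocity(quiet$trace)
  expect_equal(sum(vq$speed_dps > 40), 0L)

  sac <- gen_opto_eye_trace(small_protocol(noise_sd = 0, saccade_rate = 0.5,
                                           seed = 3))
  expect_gt(length(sac$truth$saccade_times), 0)
  vs <- compute_velocity(sac$trace) |> remove_fast_phases(threshold = 40)
  expect_gt(sum(vs$speed_dps > 40), 0)
  # every true saccade lands inside a masked run
  for (ts in sac$truth$saccade_times) {
    in_sac <- vs$time_s >= ts & vs$time_s <= ts + sac$params$saccade_duration
    expect_true(all(vs$masked[in_sac]))
  }
  # well-separated saccades produce exactly one masked run each
  runs <- rle(vs$masked)
  if (all(diff(sac$truth$saccade_times) > 0.1)) {
    expect_identical(sum(runs$values), length(sac$truth$saccade_times))
  }
})

test_that("cohort generation matches the requested group sizes and jitter", {
  arch <- list(
    fast_large = quiet_params(sample_rate = 100, led_durations = 50,
                              n_repeats_per_duration = 1, inter_trial_gap = 0.5,
                              lead_in = 0.2),
    also_fast = quiet_params(sample_rate = 100, led_durations = 50,
                             n_repeats_per_duration = 1, inter_trial_gap = 0.5,
                             lead_in = 0.2),
    slow_small = quiet_params(sample_rate = 100, led_durations = 50,
                              n_repeats_per_duration = 1, inter_trial_gap = 0.5,
                              lead_in = 0.2, drive_amp = 1.2)
  )
  cohort <- gen_cohort(arch, n_animals = c(14, 15, 8), seed = 5)
  expect_identical(nrow(cohort), 37L)
  expect_identical(as.vector(table(cohort$group)[c("fast_large", "also_fast", "slow_small")]),
                   c(14L, 15L, 8L))

  # zero jitter: all animals in a group share kinematic parameters
  c0 <- gen_cohort(arch[1], n_animals = 3, jitter_sd = 0, seed = 5)
  amps <- purrr::map_dbl(c0$params, "drive_amp")
  expect_true(all(amps == amps[1]))

  # with jitter they differ but stay positive
  c1 <- gen_cohort(arch[1], n_animals = 3, jitter_sd = 0.2, seed = 5)
  amps1 <- purrr::map_dbl(c1$params, "drive_amp")
  expect_gt(stats::sd(amps1), 0)
  expect_true(all(amps1 > 0))

  expect_error(gen_cohort(list(), 3), class = "optokin_param_error")
  expect_error(gen_cohort(arch[1], 1), class = "optokin_param_error")
})

test_that("ground-truth manifest round-trips through the yaml writer", {
  arch <- list(g = quiet_params(sample_rate = 100, led_durations = 50,
                                n_repeats_per_duration = 1,
                                inter_trial_gap = 0.5, lead_in = 0.2))
  cohort <- gen_cohort(arch, n_animals = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_manifest(attr(cohort, "manifest"), path)
  back <- read_manifest(path)
  expect_equal(back, attr(cohort, "manifest"), tolerance = 1e-12)
})

test_that("invalid generator parameters are rejected", {
  expect_error(opto_eye_params(drive_tau = 0), class = "optokin_param_error")
  expect_error(opto_eye_params(drive_tau = -1), class = "optokin_param_error")
  expect_error(opto_eye_params(sample_rate = 0), class = "optokin_param_error")
  expect_error(opto_eye_params(intensity_scale = 0), class = "optokin_param_error")
  expect_error(opto_eye_params(intensity_scale = 1.5), class = "optokin_param_error")
  expect_error(opto_eye_params(direction = c(0, 0)), class = "optokin_param_error")
})

test_that("intensity scaling scales the whole kernel", {
  p <- quiet_params(led_durations = 500, n_repeats_per_duration = 1)
  p2 <- p
  p2$intensity_scale <- 0.2
  t_rel <- seq(0, 1.5, by = 0.01)
  expect_equal(opto_kernel_position(t_rel, p2, 0.5),
               0.2 * opto_kernel_position(t_rel, p, 0.5), tolerance = 1e-12)
})
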