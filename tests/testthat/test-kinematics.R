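# Calibration, velocity computation, quick-phase masking, cycle QC and
# averaging.

test_that("angular calibration recovers known rotations", {
  t <- (0:99) / 100
  raw0 <- tibble::tibble(time_s = t, pupil_h = 0, pupil_v = 0,
                         cr_h = 0, cr_v = 0)
  expect_equal(calibrate_position(raw0, Rp = 2)$h_deg, rep(0, 100))

  raw30 <- tibble::tibble(time_s = t, pupil_h = 1, pupil_v = 0,
                          cr_h = 0, cr_v = 0)
  cal <- calibrate_position(raw30, Rp = 2, offset = c(0, 0))
  expect_equal(cal$h_deg, rep(30, 100), tolerance = 1e-12)

  # forward-project a known rotation sequence, then invert
  theta <- 25 * sin(2 * pi * t)
  raw <- tibble::tibble(time_s = t,
                        pupil_h = 2 * sin(theta * pi / 180),
                        pupil_v = 2 * sin(-theta / 2 * pi / 180),
                        cr_h = 0, cr_v = 0)
  cal <- calibrate_position(raw, Rp = 2, offset = c(0, 0))
  expect_lt(max(abs(cal$h_deg - theta)), 1e-6)
  expect_lt(max(abs(cal$v_deg + theta / 2)), 1e-6)

  bad <- tibble::tibble(time_s = 0:4, pupil_h = c(0, 0, 3, 0, 0), pupil_v = 0,
                        cr_h = 0, cr_v = 0)
  expect_error(calibrate_position(bad, Rp = 2), "frame 3",
               class = "optokin_calibration_error")
})

test_that("velocity of constant, ramp and sinusoid traces is as expected", {
  t <- seq(0, 2, by = 1e-3)
  const <- tibble::tibble(time_s = t, h_deg = 3, v_deg = -4)
  vc <- compute_velocity(const)
  expect_lt(max(abs(vc$vel_h_dps)), 1e-8)
  expect_lt(max(abs(vc$vel_mag_dps)), 1e-8)
  expect_equal(vc$mag_deg, rep(5, length(t)))  # 3-4-5 magnitude

  ramp <- tibble::tibble(time_s = t, h_deg = 10 * t, v_deg = 0)
  vr <- compute_velocity(ramp)
  interior <- 200:(length(t) - 200)
  expect_lt(max(abs(vr$vel_h_dps[interior] - 10)), 1e-6)

  A <- 2; f <- 2
  sine <- tibble::tibble(time_s = t, h_deg = A * sin(2 * pi * f * t), v_deg = 0)
  vs <- compute_velocity(sine)
  expect_equal(max(abs(vs$vel_h_dps[interior])), 2 * pi * f * A,
               tolerance = 0.01)
})

test_that("velocity configuration errors are caught", {
  t <- seq(0, 1, by = 1e-3)
  tr <- tibble::tibble(time_s = t, h_deg = t, v_deg = 0)
  expect_error(compute_velocity(tr, cutoff_hz = 500),
               class = "optokin_config_error")
  expect_error(compute_velocity(tr[1:3, ]), "5 samples")
  expect_error(compute_velocity(dplyr::mutate(tr, time_s = time_s^2)),
               "uniform")
})

test_that("fast-phase masking is thresholded, padded and monotone", {
  sim <- gen_opto_eye_trace(small_protocol(saccade_rate = 1, seed = 21))
  prof <- compute_velocity(sim$trace)

  inf_mask <- remove_fast_phases(prof, threshold = Inf)
  expect_false(any(inf_mask$masked))

  expect_error(remove_fast_phases(prof, threshold = 0),
               class = "optokin_config_error")

  # monotone: raising the threshold never masks more samples
  masks <- purrr::map(c(20, 40, 80, 200), function(th) {
    remove_fast_phases(prof, threshold = th)$masked
  })
  for (k in 2:length(masks)) {
    expect_true(all(masks[[k - 1]] | !masks[[k]]))
  }

  # padding widens each run by the requested margin
  m0 <- remove_fast_phases(prof, threshold = 40, pad_ms = 0)$masked
  m10 <- remove_fast_phases(prof, threshold = 40, pad_ms = 10)$masked
  expect_gte(sum(m10), sum(m0))
  expect_true(all(m10[m0]))
})

test_that("cycle QC applies the steadiness and crossing criteria", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  schedule <- tibble::tibble(trial = 1L, onset_s = 1, offset_s = 1.5,
                             duration_ms = 500, kind = "LED", level = 1)
  step <- ifelse(t >= 1, 5 * pmin((t - 1) / 0.2, 1), 0)

  mk <- function(h) {
    compute_velocity(tibble::tibble(time_s = t, h_deg = h, v_deg = 0)) |>
      remove_fast_phases() |>
      extract_cycles(schedule)
  }

  # steady pre-window then a clear movement: included
  qc1 <- qc_cycles(mk(step))
  expect_true(qc1$included)
  expect_identical(qc1$reason, "ok")

  # 1-degree oscillation in the pre-window: excluded as unsteady
  wob <- step + ifelse(t < 1, sin(2 * pi * 10 * t), 0)
  qc2 <- qc_cycles(mk(wob))
  expect_false(qc2$included)
  expect_identical(qc2$reason, "unsteady")
  expect_gt(qc2$pre_sd_deg, 0.25)

  # flat everywhere: no threshold crossing (SD floor prevents self-crossing)
  qc3 <- qc_cycles(mk(rep(0.5, length(t))))
  expect_false(qc3$included)
  expect_identical(qc3$reason, "no_crossing")

  # cycle starting too close to trace start: short pre-window
  sched0 <- tibble::tibble(trial = 1L, onset_s = 0.005, offset_s = 0.5,
                           duration_ms = 495, kind = "LED", level = 1)
  cyc0 <- compute_velocity(tibble::tibble(time_s = t, h_deg = step, v_deg = 0)) |>
    remove_fast_phases() |>
    extract_cycles(sched0)
  qc0 <- qc_cycles(cyc0)
  expect_false(qc0$included)
  expect_identical(qc0$reason, "short_pre")
})

test_that("cycle averaging respects masks and reproduces identical cycles", {
  # hand-built cycles: 2 trials, 5 time points
  base <- tibble::tibble(
    rel_time_s = rep((0:4) / 1000, 2),
    trial = rep(1:2, each = 5),
    duration_ms = 100,
    h_deg = c(1, 2, 3, 4, 5, 1, 2, 9, 4, 5),
    v_deg = 0,
    mag_deg = abs(c(1, 2, 3, 4, 5, 1, 2, 9, 4, 5)),
    masked = c(rep(FALSE, 7), TRUE, FALSE, FALSE)
  )
  avg <- average_cycles(base)
  expect_equal(avg$h_deg, c(1, 2, 3, 4, 5))    # masked 9 excluded at t = 2 ms
  expect_equal(avg$n_cycles, c(2L, 2L, 1L, 2L, 2L))

  identical_cycles <- dplyr::mutate(base, h_deg = rep(1:5, 2), masked = FALSE)
  avg2 <- average_cycles(identical_cycles)
  expect_equal(avg2$h_deg, 1:5)

  expect_error(average_cycles(base[0, ]), class = "optokin_empty_error")
})

test_that("group averaging returns pointwise mean and SEM over animals", {
  d <- tidyr::expand_grid(animal_id = c("a", "b", "c"),
                          rel_time_s = (0:9) / 1000) |>
    dplyr::mutate(mag_deg = rep(c(1, 2, 3), each = 10))
  g <- average_animals(d, cols = "mag_deg")
  expect_equal(g$mag_deg, rep(2, 10))
  expect_equal(g$mag_deg_sem, rep(1 / sqrt(3), 10))
  expect_error(average_animals(d[d$animal_id == "a", ], cols = "mag_deg"),
               "2 animals")
})

test_that("normalization pins the trace to 1 at onset + 100 ms", {
  sim <- gen_opto_eye_trace(quiet_params(led_durations = 1000,
                                         n_repeats_per_duration = 1))
  r <- animal_mean_response(sim, 1000)
  norm <- normalize_position(r$mean)
  i <- which.min(abs(norm$rel_time_s - 0.1))
  expect_equal(norm$mag_norm[i], 1)

  flat <- fake_mean_profile((0:199) / 1000, rep(0, 200))
  expect_error(normalize_position(flat), class = "optokin_normalization_error")
})

test_that("magnitude dominates each axis pointwise", {
  withr::with_seed(4, {
    h <- rnorm(1000)
    v <- rnorm(1000)
  })
  m <- eye_magnitude(h, v)
  expect_true(all(m >= abs(h) - 1e-12))
  expect_true(all(m >= abs(v) - 1e-12))
})

test_that("noiseless saccade-free pipeline recovers the kernel within 2% of drive amplitude", {
  p <- quiet_params(led_durations = 1000, n_repeats_per_duration = 3)
  sim <- gen_opto_eye_trace(p)
  r <- animal_mean_response(sim, 1000)
  truth <- opto_kernel_position(r$mean$rel_time_s, p, 1.0)
  expect_lt(max(abs(r$mean$mag_deg - truth)), 0.02 * p$drive_amp)
})

test_that("cycle averages converge on the kernel at CLT rate", {
  p <- small_protocol(duration_ms = 500, n = 60, noise_sd = 0.1,
                      saccade_rate = 0, seed = 31)
  sim <- gen_opto_eye_trace(p)
  r <- animal_mean_response(sim, 500)
  truth <- opto_kernel_position(r$mean$rel_time_s, p, 0.5)
  sem <- 0.1 / sqrt(60)
  frac_in <- mean(abs(r$mean$mag_deg - truth) < 3 * sem)
  expect_gt(frac_in, 0.98)
})
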