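# Gamma-renewal spike generator, firing rate / CV2, epoch responses,
# classification and the current-step input-output curve.

test_that("CV2 is 0 for clockwork trains, ~1 for Poisson, and scale invariant", {
  regular <- seq(0, 10, by = 0.02)
  expect_equal(cv2(regular), 0)

  pois <- gen_spike_train(spike_gen_params(base_rate = 400, gamma_shape = 1,
                                           total_duration = 50, seed = 2))
  expect_gt(length(pois$spikes), 1.9e4)
  expect_equal(cv2(pois$spikes), 1, tolerance = 0.02)

  # rescaling time cannot change a dimensionless regularity index
  expect_equal(cv2(pois$spikes * 3.7), cv2(pois$spikes), tolerance = 1e-12)

  expect_warning(out <- cv2(c(0, 1)), "fewer than 3")
  expect_true(is.na(out))
})

test_that("firing rate is count over window", {
  expect_equal(firing_rate(seq(0, 1.99, by = 0.02), 0, 2), 50)
  expect_equal(firing_rate(numeric(0), 0, 2), 0)
  expect_error(firing_rate(1:3, 1, 1), "exceed")
})

test_that("a near-regular train hits its nominal rate", {
  st <- gen_spike_train(spike_gen_params(base_rate = 50, gamma_shape = 500,
                                         total_duration = 60, seed = 7))
  rate <- length(st$spikes) / 60
  expect_equal(rate, 50, tolerance = 2 / 50)
  expect_lt(cv2(st$spikes), 0.1)
})

test_that("epoch counts agree with the rescaled-gamma expectation", {
  onsets <- 1 + (0:59) * 2
  epochs <- tibble::tibble(onset_s = onsets, duration_ms = 200)
  st <- gen_spike_train(spike_gen_params(base_rate = 60, stim_factor = 3,
                                         gamma_shape = 4,
                                         epoch_schedule = epochs,
                                         total_duration = 122, seed = 5))
  counts <- vapply(onsets, function(on) {
    sum(st$spikes >= on & st$spikes < on + 0.2)
  }, numeric(1))
  expected <- 3 * 60 * 0.2
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)
})

test_that("normalized peri rate recovers the generator's stimulation factor", {
  onsets <- 1 + (0:59) * 2
  epochs <- tibble::tibble(onset_s = onsets, duration_ms = 200)
  for (fac in c(3, 0.25)) {
    st <- gen_spike_train(spike_gen_params(base_rate = 60, stim_factor = fac,
                                           gamma_shape = 4,
                                           epoch_schedule = epochs,
                                           total_duration = 122,
                                           seed = 100 + round(fac * 4)))
    resp <- epoch_response(st$spikes, onsets, peri_s = 0.2)
    tol <- if (fac > 1) 0.3 else 0.05
    expect_lt(abs(resp$summary$normalized_peri - fac), tol)
  }
})

test_that("a homogeneous train is unmodulated across arbitrary epochs", {
  st <- gen_spike_train(spike_gen_params(base_rate = 60, stim_factor = 1,
                                         gamma_shape = 4,
                                         total_duration = 122, seed = 9))
  onsets <- 1 + (0:59) * 2
  resp <- epoch_response(st$spikes, onsets, peri_s = 0.2)
  expect_equal(resp$summary$normalized_peri, 1, tolerance = 0.1)
  expect_equal(as.character(classify_response(resp)), "unmodulated")
})

test_that("PSTH bin means summed over the peri window equal peri rate x window", {
  onsets <- 1 + (0:29) * 2
  epochs <- tibble::tibble(onset_s = onsets, duration_ms = 100)
  st <- gen_spike_train(spike_gen_params(base_rate = 60, stim_factor = 3,
                                         gamma_shape = 2,
                                         epoch_schedule = epochs,
                                         total_duration = 62, seed = 4))
  resp <- epoch_response(st$spikes, onsets, peri_s = 0.1)
  peri_bins <- resp$psth$bin_start_s > -1e-9 & resp$psth$bin_start_s < 0.1 - 1e-9
  expect_equal(sum(resp$psth$mean_count[peri_bins]),
               resp$summary$peri_hz * 0.1, tolerance = 1e-9)
  # windows tile the 2-s epoch exactly
  w <- resp$windows
  expect_equal(w$pre_s + w$peri_s + w$post_s, 2)
})

test_that("classification follows the thresholds", {
  expect_identical(as.character(classify_response(3.0)), "excited")
  expect_identical(as.character(classify_response(0.25)), "suppressed")
  expect_identical(as.character(classify_response(1.0)), "unmodulated")
  expect_error(classify_response(1, up_thr = 0.4, down_thr = 0.5),
               class = "optokin_config_error")
})

test_that("synthetic excited and suppressed cells classify perfectly", {
  onsets <- 1 + (0:29) * 2
  epochs <- tibble::tibble(onset_s = onsets, duration_ms = 200)
  classes <- purrr::map_chr(1:20, function(i) {
    fac <- if (i %% 2 == 0) 3 else 0.25
    st <- gen_spike_train(spike_gen_params(base_rate = 60, stim_factor = fac,
                                           gamma_shape = 4,
                                           epoch_schedule = epochs,
                                           total_duration = 62,
                                           seed = 1000 + i))
    as.character(classify_response(
      epoch_response(st$spikes, onsets, peri_s = 0.2)))
  })
  expect_identical(classes, rep(c("suppressed", "excited"), 10))
})

test_that("pre-rate-zero epochs are flagged rather than silently divided", {
  spikes <- c(1.05, 1.1, 1.15)  # all inside the peri window
  expect_warning(resp <- epoch_response(spikes, onsets = 1, peri_s = 0.2),
                 "undefined")
  expect_true(resp$summary$pre_rate_zero)
  expect_true(is.na(resp$summary$normalized_peri))
})

test_that("the input-output curve counts spikes and latencies per current step", {
  # synthetic cell: rate g * (I - 100) above a 100-pA rheobase analog
  g <- 0.1
  currents <- seq(100, 900, by = 100)
  steps <- purrr::map_dfr(currents, function(I) {
    rate <- g * (I - 100)
    purrr::map_dfr(1:20, function(sw) {
      if (rate == 0) {
        return(tibble::tibble(current_pA = I, sweep = sw, spike_s = NA_real_))
      }
      st <- gen_spike_train(spike_gen_params(
        base_rate = rate, gamma_shape = 1, total_duration = 0.5,
        seed = I * 100 + sw
      ))
      if (length(st$spikes) == 0) {
        return(tibble::tibble(current_pA = I, sweep = sw, spike_s = NA_real_))
      }
      tibble::tibble(current_pA = I, sweep = sw, spike_s = st$spikes)
    })
  })
  sweeps <- tidyr::expand_grid(current_pA = currents, sweep = 1:20)
  io <- io_curve(steps, sweeps = sweeps)

  expect_identical(io$current_pA, currents)
  expect_equal(io$mean_count[io$current_pA == 100], 0)
  expect_true(is.na(io$mean_latency_ms[io$current_pA == 100]))
  # counts grow with current, close to the g * (I - 100) * 0.5 expectation
  expect_true(all(diff(io$mean_count) > 0))
  expected <- g * (currents[-1] - 100) * 0.5
  expect_equal(io$mean_count[-1], expected, tolerance = 0.2)
  # latency of the first spike shrinks with drive (monotone in expectation;
  # assert the trend, not every noisy adjacent pair)
  lat <- io$mean_latency_ms[-1]
  expect_lt(lat[length(lat)], lat[1])
  expect_lt(stats::cor(seq_along(lat), lat, method = "spearman"), -0.7)
  expect_true(all(lat <= 500))
})

test_that("generator parameter validation", {
  expect_error(spike_gen_params(base_rate = 0), class = "optokin_param_error")
  expect_error(spike_gen_params(gamma_shape = 0), class = "optokin_param_error")
  expect_error(spike_gen_params(stim_factor = -1), class = "optokin_param_error")
  expect_error(
    spike_gen_params(epoch_schedule = tibble::tibble(onset_s = 59.9,
                                                     duration_ms = 500),
                     total_duration = 60),
    class = "optokin_param_error"
  )
  # determinism
  a <- gen_spike_train(spike_gen_params(seed = 3, total_duration = 5))
  b <- gen_spike_train(spike_gen_params(seed = 3, total_duration = 5))
  expect_identical(a$spikes, b$spikes)
})
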