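test_that("parameter constructors enforce their invariants", {
  expect_error(plant_params(damping_ratio = 1.2), "damping")
  expect_error(plant_params(echo_gain = 1), "echo_gain")
  expect_error(plant_params(entrain_increment = -0.1), "entrain_increment")
  expect_error(spike_gen_params(baseline_rate_hz = 0), "positive")
  expect_error(spike_gen_params(refractory_ms = 2), "refractory")
  expect_error(spike_gen_params(cs_pause_ms = 5), "cs_pause")
  expect_equal(ss_plant_params()$n_echoes, 1)
  expect_equal(cf_plant_params()$n_echoes, 0)
})

test_that("the plant is linear, deterministic, and silent without drive", {
  tr <- suppressWarnings(build_train(4, n_pulses = 4))
  p1 <- ss_plant_params(noise_sd_deg = 0)
  p2 <- ss_plant_params(drive_gain = 2 * p1$drive_gain, noise_sd_deg = 0)
  x1 <- simulate_plant(tr, p1, seed = 1)
  x2 <- simulate_plant(tr, p2, seed = 1)
  expect_equal(x2$values_deg, 2 * x1$values_deg, tolerance = 1e-9)

  # bit-identical under the same seed, different under another
  pn <- ss_plant_params(noise_sd_deg = 0.3)
  expect_identical(simulate_plant(tr, pn, seed = 5)$values_deg,
                   simulate_plant(tr, pn, seed = 5)$values_deg)
  expect_false(identical(simulate_plant(tr, pn, seed = 5)$values_deg,
                         simulate_plant(tr, pn, seed = 6)$values_deg))

  # no stimuli in window, no noise: identically zero
  tr1 <- suppressWarnings(build_train(0.5, n_pulses = 1))
  x0 <- simulate_plant(tr1, cf_plant_params(drive_gain = 0, noise_sd_deg = 0),
                       duration_ms = 1000)
  expect_true(all(x0$values_deg == 0))

  expect_error(simulate_plant(tr, p1, duration_ms = 100), "within")
  expect_error(
    simulate_plant(tr, ss_plant_params(echo_delay_ms = 10), seed = 1),
    "pulse width")
})

test_that("the exact discrete update matches a reference integrator", {
  skip_if_not_installed("pracma")
  p <- plant_params(resonance_freq_hz = 8, damping_ratio = 0.25)
  st <- whiskres:::plant_discretize(p, fs_hz = 1000)
  zeta <- p$damping_ratio
  wn <- 2 * pi * p$resonance_freq_hz / sqrt(1 - zeta^2)
  A <- matrix(c(0, -wn^2, 1, -2 * zeta * wn), 2, 2)
  expect_equal(st$Ad, pracma::expm(A / 1000), tolerance = 1e-6)
})

test_that("free ringing peaks at the configured resonance frequency", {
  tr1 <- suppressWarnings(build_train(0.5, n_pulses = 1))
  for (f0 in c(6, 8, 14)) {
    p <- cf_plant_params(resonance_freq_hz = f0, noise_sd_deg = 0)
    x <- simulate_plant(tr1, p, duration_ms = 3000)
    pk <- mean_power_spectrum(cwt_scalogram(x))$peak_hz
    # a decaying transient has a broadened line; 0.5 Hz covers the skew
    expect_lte(abs(pk - f0), 0.5)
  }
})

test_that("single-pulse responses show the echo dichotomy", {
  tr1 <- suppressWarnings(build_train(0.5, n_pulses = 1))
  x_cf <- lowpass_angle(simulate_plant(tr1, cf_plant_params(noise_sd_deg = 0),
                                       duration_ms = 2000))
  ev <- detect_movements(x_cf)
  expect_equal(sum(ev$kind == "protraction"), 1)
  expect_equal(count_cycles(x_cf, c(0, 2000)), 1L)

  x_ss <- lowpass_angle(simulate_plant(tr1, ss_plant_params(noise_sd_deg = 0),
                                       duration_ms = 2000))
  expect_equal(count_cycles(x_ss, c(0, 2000)), 2L)
})

test_that("spontaneous whisking carries its design frequency and bounds", {
  w <- simulate_spontaneous_whisking(amp_deg = 8, mod_freq_hz = 8, seed = 7)
  wl <- lowpass_angle(w)
  per <- movement_periods(detect_movements(wl))
  sp <- mean_power_spectrum(cwt_scalogram(wl), periods_ms = per)
  expect_lte(abs(sp$peak_hz - 8), 0.5)

  # sub-threshold whisking produces no events
  w1 <- simulate_spontaneous_whisking(amp_deg = 1, seed = 8)
  expect_equal(nrow(detect_movements(lowpass_angle(w1))), 0)

  # no bouts, no movement periods
  w0 <- simulate_spontaneous_whisking(bout_rate = 0, seed = 9)
  expect_equal(nrow(attr(w0, "bouts")), 0)
  expect_equal(nrow(movement_periods(detect_movements(lowpass_angle(w0)))), 0)

  # too-short recording warns and flags
  expect_warning(
    ws <- simulate_spontaneous_whisking(bout_rate = 5, duration_ms = 500,
                                        seed = 1),
    "too short")
  expect_true(attr(ws, "too_short"))

  expect_identical(
    simulate_spontaneous_whisking(seed = 3)$values_deg,
    simulate_spontaneous_whisking(seed = 3)$values_deg)
})

test_that("simulated spike trains obey the QC constraints by construction", {
  for (s in c(1, 17, 99)) {
    st <- simulate_spike_train(spike_gen_params(), seed = s)
    expect_true(qc_single_unit(st)$pass)
    expect_gte(min(diff(st$ss_times_ms)), 3)
    for (cs in st$cs_times_ms) {
      expect_false(any(st$ss_times_ms > cs & st$ss_times_ms < cs + 8))
    }
  }
  expect_identical(simulate_spike_train(seed = 4)$ss_times_ms,
                   simulate_spike_train(seed = 4)$ss_times_ms)
})

test_that("rate modulation is recoverable, and absent when not injected", {
  st <- simulate_spike_train(spike_gen_params(mod_freq_hz = 7, mod_depth = 0.5),
                             seed = 6)
  r <- bandpass_rate(instantaneous_frequency(to_logical_vector(st)))
  sp <- mean_power_spectrum(cwt_scalogram(r))
  expect_lte(abs(sp$peak_hz - 7), 1)

  # unmodulated train: no dominant line, peak power comparable to the
  # spectrum's bulk (ratio far below a modulated train's)
  st0 <- simulate_spike_train(spike_gen_params(mod_depth = 0,
                                               duration_ms = 40000), seed = 6)
  r0 <- bandpass_rate(instantaneous_frequency(to_logical_vector(st0)))
  sp0 <- mean_power_spectrum(cwt_scalogram(r0))
  ratio0 <- max(sp0$power, na.rm = TRUE) / stats::median(sp0$power, na.rm = TRUE)
  ratio7 <- max(sp$power, na.rm = TRUE) / stats::median(sp$power, na.rm = TRUE)
  expect_lt(ratio0, ratio7 / 2)
})
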