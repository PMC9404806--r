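test_that("aligned responses store trials consistently with their mean", {
  tr <- suppressWarnings(build_train(4, n_pulses = 8))
  x <- lowpass_angle(simulate_plant(tr, ss_plant_params(noise_sd_deg = 0),
                                    seed = 2))
  ar <- align_traces(x, tr)
  expect_equal(nrow(ar$trial_matrix), 8)
  expect_equal(colMeans(ar$trial_matrix), ar$mean_trace, tolerance = 1e-12)

  # two whisk cycles per 250 ms window under SS-type drive
  m <- angle_trace(ar$mean_trace, x$fs_hz)
  expect_equal(count_cycles(m, c(0, 250)), 2L)

  # identical response to every pulse: zero dispersion
  per <- sin(2 * pi * 8 * (0:1999) / 1000)
  xp <- angle_trace(rep(per, 4))
  trp <- suppressWarnings(build_train(0.5, n_pulses = 4))
  arp <- align_traces(xp, trp)
  expect_lt(max(arp$dispersion), 1e-12)

  expect_error(align_traces(x, tr, window_ms = c(500, 250)), "stimulus 1")
})

test_that("epoch amplitudes follow the window rules", {
  flat <- angle_trace(rep(1, 21000))
  tr8 <- build_train(8)
  expect_equal(epoch_amplitude(flat, tr8, 1), 0)

  # full cycle per epoch at 8 Hz: 10 deg peak-to-peak everywhere
  t <- (0:20999) / 1000
  sine8 <- angle_trace(5 * sin(2 * pi * 8 * t))
  for (i in c(1, 70, 140)) {
    expect_equal(epoch_amplitude(sine8, tr8, i), 10, tolerance = 0.01)
  }
  expect_error(epoch_amplitude(sine8, tr8, 141), "out of range")

  # below 4 Hz the window is capped at 250 ms: a burst at +600 ms after a
  # 1 Hz stimulus is excluded
  tr1 <- suppressWarnings(build_train(1, n_pulses = 10))
  x <- numeric(11000)
  x[601:700] <- 10 * sin(2 * pi * 10 * (1:100) / 1000)  # spontaneous whisk
  x[1:100] <- 2 * sin(2 * pi * 10 * (1:100) / 1000)     # early response
  amp <- epoch_amplitude(angle_trace(x), tr1, 1)
  expect_lt(amp, 5)   # reflects only the 4 deg early response
  expect_gt(amp, 3)

  # invariance under offset, linearity under scaling
  off <- angle_trace(sine8$values_deg + 50)
  expect_equal(epoch_amplitude(off, tr8, 3), epoch_amplitude(sine8, tr8, 3),
               tolerance = 1e-12)
  sc <- angle_trace(3 * sine8$values_deg)
  expect_equal(epoch_amplitude(sc, tr8, 3), 3 * epoch_amplitude(sine8, tr8, 3),
               tolerance = 1e-12)
})

test_that("entrainment amplitudes use the first 15 stimuli (10 at 0.5 Hz)", {
  sess <- build_session(c(14, 0.5), rest_ms = 1000)
  x <- lowpass_angle(simulate_plant(sess, ss_plant_params(), seed = 3))
  e14 <- entrainment_amplitudes(x, sess$trains[[1]], "SS")
  expect_length(e14$amplitudes_deg, 15)
  e05 <- entrainment_amplitudes(x, sess$trains[[2]], "SS")
  expect_length(e05$amplitudes_deg, 10)
  expect_true(is.finite(e14$slope))

  short <- suppressWarnings(build_train(4, n_pulses = 5))
  expect_error(entrainment_amplitudes(x, short, "SS"), "at least 10")
})

test_that("gain growth is read out as an increasing amplitude trend", {
  tr4 <- build_train(4)
  slopes <- vapply(c(0, 0.01, 0.02), function(inc) {
    p <- ss_plant_params(entrain_increment = inc, noise_sd_deg = 0)
    x <- lowpass_angle(simulate_plant(tr4, p, seed = 5))
    er <- entrainment_amplitudes(x, tr4, "SS")
    if (inc > 0) {
      rho <- stats::cor(er$amplitudes_deg, seq_along(er$amplitudes_deg),
                        method = "spearman")
      expect_gt(rho, 0.8)
    } else {
      # without gain growth the per-stimulus trend is negligible relative
      # to the response amplitude (startup transient only)
      expect_lt(abs(er$slope), 0.01 * mean(er$amplitudes_deg))
    }
    er$slope
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("slopes match the closed-form least-squares oracle", {
  expect_equal(entrainment_slope(1:5), 1, tolerance = 1e-12)
  expect_equal(entrainment_slope(rep(2.5, 8)), 0, tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:5) {
    y <- rnorm(15)
    expect_equal(entrainment_slope(y), oracle_slope(y), tolerance = 1e-12)
  }
  expect_error(entrainment_slope(c(1, 2)), "at least 3")
})

test_that("slope comparison reproduces the paired t-test", {
  ss <- c(0.12, 0.08, 0.15, 0.11, 0.09, 0.13, 0.1)
  expect_equal(compare_slopes(ss, ss)$t, 0)
  expect_equal(compare_slopes(ss, ss)$p, 1)

  shift <- compare_slopes(ss + 0.05, ss)
  expect_true(shift$degenerate)
  expect_equal(shift$p, 0)
  expect_equal(shift$higher, "SS")

  set.seed(21)
  for (rep in 1:5) {
    a <- rnorm(7, 0.1, 0.05)
    b <- rnorm(7, 0.05, 0.05)
    got <- compare_slopes(a, b)
    want <- oracle_paired_t(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(compare_slopes(1:3, 1:4), "paired")
})

test_that("the tuning curve peaks at the plant resonance", {
  sess <- build_session()
  for (p in list(ss_plant_params(), cf_plant_params())) {
    x <- lowpass_angle(simulate_plant(sess, p, seed = 4))
    tun <- tuning_curve(x, sess)
    expect_equal(tun$peak_freq_hz, 8)
    expect_equal(nrow(tun$curve), 7)   # duplicated trains averaged
  }
  # moving the resonance moves the argmax (parameter-recovery control;
  # CF-type, because the SS echo loop itself is a fixed 125 ms structure)
  p14 <- cf_plant_params(resonance_freq_hz = 14, noise_sd_deg = 0)
  x14 <- lowpass_angle(simulate_plant(build_session(), p14, seed = 4))
  expect_equal(tuning_curve(x14, build_session())$peak_freq_hz, 14)
})

test_that("whisker oscillation does not outlive the train at the drive frequency", {
  tr14 <- build_train(14)
  dur <- tr14$onsets_ms[tr14$n_pulses] + 1500
  x <- lowpass_angle(simulate_plant(tr14, ss_plant_params(noise_sd_deg = 0),
                                    seed = 2, duration_ms = dur))
  ps <- post_stim_spectrum(x, tr14)
  expect_false(ps$same_peak)

  # positive control: a trace that keeps oscillating at the drive frequency
  tr8 <- suppressWarnings(build_train(8, n_pulses = 20))
  t <- (0:5999) / 1000
  osc <- lowpass_angle(angle_trace(5 * sin(2 * pi * 8 * t)))
  ps2 <- post_stim_spectrum(osc, tr8)
  expect_true(ps2$same_peak)

  # flat tail: near-zero post power and no drive-frequency peak
  x3 <- c(5 * sin(2 * pi * 8 * (0:2399) / 1000), rep(0, 3600))
  ps3 <- post_stim_spectrum(angle_trace(x3), tr8)
  expect_false(ps3$same_peak)
  expect_lt(max(ps3$spectrum_after$power, na.rm = TRUE),
            1e-3 * max(ps3$spectrum_before$power, na.rm = TRUE))

  expect_error(post_stim_spectrum(angle_trace(rep(0, 3000)), tr8), "1000 ms")
})
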