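#' Whisker plant parameters
#'
#' The synthetic whisker is a linear second-order underdamped oscillator
#' ("plant") converting motor commands into whisker angle. Each LED pulse
#' injects a rectangular 20 ms command; simple-spike-type drive additionally
#' injects delayed echo commands, emulating a premotor loop that reverberates
#' with a ~125 ms period, while climbing-fiber-type drive has no echo.
#'
#' `resonance_freq_hz` is the observed ringing (damped) frequency: the
#' undamped natural frequency is derived as
#' \eqn{\omega_n = 2\pi f_{res}/\sqrt{1-\zeta^2}}, so the free response
#' genuinely rings at `resonance_freq_hz`.
#'
#' @param resonance_freq_hz damped natural frequency in Hz (default 8).
#' @param damping_ratio dimensionless damping in (0, 1) (default 0.25).
#' @param drive_gain degrees of steady-state deflection per unit command
#'   (default 7; one 20 ms pulse then peaks near 5 degrees).
#' @param echo_delay_ms reverberation loop period in ms (default 125).
#' @param echo_gain relative amplitude of each successive echo, in [0, 1)
#'   (default 0.7).
#' @param n_echoes echoes per pulse: 1 for SS-type, 0 for CF-type drive.
#' @param entrain_increment fractional command-gain growth per successive
#'   stimulus within a train (>= 0, default 0).
#' @param noise_sd_deg SD of additive Gaussian measurement noise in degrees
#'   (default 0.3).
#' @param latency_ms delay from LED onset to command onset (default 0; the
#'   physiological latency is not pinned down, so it is a free parameter).
#' @return object of class `plant_params`.
#' @export
plant_params <- function(resonance_freq_hz = 8, damping_ratio = 0.25,
                         drive_gain = 7, echo_delay_ms = 125,
                         echo_gain = 0.7, n_echoes = 1,
                         entrain_increment = 0, noise_sd_deg = 0.3,
                         latency_ms = 0) {
  if (damping_ratio <= 0 || damping_ratio >= 1)
    stop("damping_ratio must lie strictly in (0, 1)")
  if (echo_gain < 0 || echo_gain >= 1) stop("echo_gain must lie in [0, 1)")
  if (entrain_increment < 0) stop("entrain_increment must be >= 0")
  structure(
    list(resonance_freq_hz = resonance_freq_hz,
         damping_ratio = damping_ratio, drive_gain = drive_gain,
         echo_delay_ms = echo_delay_ms, echo_gain = echo_gain,
         n_echoes = n_echoes, entrain_increment = entrain_increment,
         noise_sd_deg = noise_sd_deg, latency_ms = latency_ms),
    class = "plant_params"
  )
}

#' SS-type and CF-type plant presets
#'
#' Convenience constructors: SS-type drive carries one 125 ms echo per
#' pulse (reverberating loop engaged), CF-type drive none.
#'
#' @param ... overrides passed to [plant_params()].
#' @return a `plant_params` object.
#' @export
ss_plant_params <- function(...) plant_params(n_echoes = 1, ...)

#' @rdname ss_plant_params
#' @export
cf_plant_params <- function(...) plant_params(n_echoes = 0, ...)

# Exact one-step discretization (zero-order hold) of the underdamped
# second-order system x'' + 2*zeta*wn*x' + wn^2*x = wn^2*u at step h:
# closed-form matrix exponential, stable at arbitrary durations.
plant_discretize <- function(params, fs_hz = 1000) {
  h <- 1 / fs_hz
  zeta <- params$damping_ratio
  wd <- 2 * pi * params$resonance_freq_hz
  wn <- wd / sqrt(1 - zeta^2)
  a <- zeta * wn
  A <- matrix(c(0, -wn^2, 1, -2 * a), 2, 2)
  E <- exp(-a * h)
  cwd <- cos(wd * h); swd <- sin(wd * h)
  Ad <- E * matrix(c(cwd + a / wd * swd, -wn^2 / wd * swd,
                     swd / wd, cwd - a / wd * swd), 2, 2)
  Bd <- solve(A, (Ad - diag(2)) %*% c(0, wn^2))
  list(Ad = Ad, Bd = as.numeric(Bd))
}

# Build the command vector for one train, restarting the entrainment index.
# Returns the command and the per-stimulus command gains (ground truth).
train_command <- function(u, train, params, fs_hz) {
  n <- length(u)
  gains <- numeric(train$n_pulses)
  for (i in seq_len(train$n_pulses)) {
    g <- params$drive_gain * (1 + params$entrain_increment * (i - 1))
    gains[i] <- g
    for (k in 0:params$n_echoes) {
      t0 <- train$onsets_ms[i] + params$latency_ms + k * params$echo_delay_ms
      j0 <- floor(t0 * fs_hz / 1000) + 1
      j1 <- min(n, j0 + round(train$pulse_ms * fs_hz / 1000) - 1)
      if (j0 > n) next
      u[j0:j1] <- u[j0:j1] + g * params$echo_gain^k
    }
  }
  list(u = u, gains = gains)
}

#' Simulate stimulus-driven whisker movement
#'
#' Drives the resonant whisker plant with the command pattern of a pulse
#' train or a whole session: each LED pulse injects a rectangular 20 ms
#' command at its onset plus `n_echoes` echoes at multiples of
#' `echo_delay_ms`, scaled by `echo_gain^k`; the command amplitude of the
#' i-th stimulus of a train is `drive_gain * (1 + entrain_increment*(i-1))`.
#' The plant is integrated with the exact discrete update of the
#' underdamped linear system at `fs_hz`; Gaussian measurement noise is
#' added last.
#'
#' @param stim a `stim_train` or `stim_session`.
#' @param params a `plant_params`.
#' @param seed integer RNG seed for the measurement noise.
#' @param duration_ms trace length; default one IPI past the last onset.
#' @param fs_hz sampling rate (default 1000).
#' @return an `angle_trace`; attribute `"ground_truth"` holds the command
#'   vector and the per-train per-stimulus command gains.
#' @export
simulate_plant <- function(stim, params, seed = 1, duration_ms = NULL,
                           fs_hz = 1000) {
  stopifnot(inherits(params, "plant_params"))
  if (fs_hz <= 0) stop("sampling rate must be positive")
  trains <- if (inherits(stim, "stim_session")) stim$trains else list(stim)
  pulse_ms <- trains[[1]]$pulse_ms
  if (params$n_echoes > 0 && params$echo_delay_ms < pulse_ms)
    stop("echo_delay_ms must be at least the pulse width (", pulse_ms, " ms)")
  if (is.null(duration_ms)) {
    last <- trains[[length(trains)]]
    duration_ms <- last$onsets_ms[last$n_pulses] + last$ipi_ms
  }
  if (any(vapply(trains, function(tr) max(tr$onsets_ms), 0) >= duration_ms))
    stop("stimulus onsets must fall within the requested duration")
  n <- round(duration_ms * fs_hz / 1000)
  u <- numeric(n)
  gains <- vector("list", length(trains))
  for (k in seq_along(trains)) {
    tc <- train_command(u, trains[[k]], params, fs_hz)
    u <- tc$u
    gains[[k]] <- tc$gains
  }
  st <- plant_discretize(params, fs_hz)
  x <- plant_integrate(st$Ad, st$Bd, u)
  if (params$noise_sd_deg > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, 0, params$noise_sd_deg)
  }
  out <- angle_trace(x, fs_hz)
  attr(out, "ground_truth") <- list(command = u, gains = gains,
                                    params = params, seed = seed)
  out
}

# Fixed-step state propagation; kept separate so tests can exercise it
# against a reference matrix-exponential integrator.
plant_integrate <- function(Ad, Bd, u) {
  n <- length(u)
  x <- numeric(n)
  z1 <- 0; z2 <- 0
  a11 <- Ad[1, 1]; a12 <- Ad[1, 2]; a21 <- Ad[2, 1]; a22 <- Ad[2, 2]
  b1 <- Bd[1]; b2 <- Bd[2]
  for (k in seq_len(n)) {
    t1 <- a11 * z1 + a12 * z2 + b1 * u[k]
    z2 <- a21 * z1 + a22 * z2 + b2 * u[k]
    z1 <- t1
    x[k] <- z1
  }
  x
}

#' Simulate spontaneous whisking
#'
#' Alternates rest epochs (flat plus measurement noise) with whisking bouts:
#' amplitude-modulated sinusoids at `mod_freq_hz` under a tapered-cosine
#' (Tukey) envelope — flat over the central 80% of the bout with 10%
#' raised-cosine ramps at each end — reaching a peak-to-peak excursion of
#' `2 * amp_deg` over the bout core. Rest durations are exponential with
#' rate `bout_rate`; bout
#' durations are uniform on 1-2 s. With `bout_rate = 0` or a duration too
#' short for one bout the trace is rest only and the attribute
#' `"too_short"` is set.
#'
#' @param bout_rate bout initiations per second of rest (default 0.3).
#' @param mod_freq_hz whisking frequency in Hz (default 8).
#' @param amp_deg peak amplitude in degrees at bout centre (default 8).
#' @param duration_ms trace length in ms (default 40000).
#' @param seed integer RNG seed.
#' @param noise_sd_deg measurement noise SD (default 0.3).
#' @param fs_hz sampling rate (default 1000).
#' @return an `angle_trace`; attribute `"bouts"` is a data.frame of
#'   ground-truth bout intervals (`start_ms`, `end_ms`).
#' @export
simulate_spontaneous_whisking <- function(bout_rate = 0.3, mod_freq_hz = 8,
                                          amp_deg = 8, duration_ms = 40000,
                                          seed = 1, noise_sd_deg = 0.3,
                                          fs_hz = 1000) {
  if (amp_deg < 0) stop("amp_deg must be non-negative")
  set.seed(seed)
  n <- round(duration_ms * fs_hz / 1000)
  x <- numeric(n)
  starts <- numeric(0); ends <- numeric(0)
  t_ms <- 0
  if (bout_rate > 0) {
    repeat {
      t_ms <- t_ms + stats::rexp(1, rate = bout_rate) * 1000
      bout_ms <- stats::runif(1, 1000, 2000)
      if (t_ms + bout_ms > duration_ms) break
      j0 <- floor(t_ms * fs_hz / 1000) + 1
      j1 <- floor((t_ms + bout_ms) * fs_hz / 1000)
      tt <- (seq(j0, j1) - j0) / fs_hz
      frac <- tt / (bout_ms / 1000)
      taper <- 0.1
      env <- rep(1, length(frac))
      lo <- frac < taper
      hi <- frac > 1 - taper
      env[lo] <- 0.5 * (1 - cos(pi * frac[lo] / taper))
      env[hi] <- 0.5 * (1 - cos(pi * (1 - frac[hi]) / taper))
      x[j0:j1] <- amp_deg * env * sin(2 * pi * mod_freq_hz * tt)
      starts <- c(starts, t_ms); ends <- c(ends, t_ms + bout_ms)
      t_ms <- t_ms + bout_ms
    }
  }
  too_short <- bout_rate > 0 && length(starts) == 0
  if (too_short)
    warning("duration too short for a single whisking bout; rest only")
  if (noise_sd_deg > 0) x <- x + stats::rnorm(n, 0, noise_sd_deg)
  out <- angle_trace(x, fs_hz)
  attr(out, "bouts") <- data.frame(start_ms = starts, end_ms = ends)
  attr(out, "too_short") <- too_short
  out
}

#' Spike-generator parameters
#'
#' Parameters of the synthetic Purkinje-cell spike train: simple spikes are
#' an inhomogeneous point process whose rate oscillates in the theta band,
#' complex spikes a homogeneous Poisson process, each followed by a pause
#' in SS firing.
#'
#' @param baseline_rate_hz mean SS rate (default 60).
#' @param mod_freq_hz frequency of the rate oscillation (default 7).
#' @param mod_depth relative oscillation amplitude in [0, 1] (default 0.5).
#' @param cs_rate_hz CS Poisson rate (default 1).
#' @param cs_pause_ms SS suppression after each CS (default 8; >= 8 so
#'   generated trains pass quality control by construction).
#' @param refractory_ms minimum SS inter-spike interval (default 3; >= 3
#'   for the same reason).
#' @param duration_ms total length (default 60000; >= 40000 so the
#'   duration criterion passes).
#' @return object of class `spike_gen_params`.
#' @export
spike_gen_params <- function(baseline_rate_hz = 60, mod_freq_hz = 7,
                             mod_depth = 0.5, cs_rate_hz = 1,
                             cs_pause_ms = 8, refractory_ms = 3,
                             duration_ms = 60000) {
  if (baseline_rate_hz <= 0) stop("baseline_rate_hz must be positive")
  if (mod_depth < 0 || mod_depth > 1) stop("mod_depth must lie in [0, 1]")
  if (refractory_ms < 3) stop("refractory_ms must be >= 3 ms")
  if (cs_pause_ms < 8) stop("cs_pause_ms must be >= 8 ms")
  structure(
    list(baseline_rate_hz = baseline_rate_hz, mod_freq_hz = mod_freq_hz,
         mod_depth = mod_depth, cs_rate_hz = cs_rate_hz,
         cs_pause_ms = cs_pause_ms, refractory_ms = refractory_ms,
         duration_ms = duration_ms),
    class = "spike_gen_params"
  )
}

#' Simulate a Purkinje-cell spike train
#'
#' SS times are drawn from an inhomogeneous point process with rate
#' `r(t) = baseline * (1 + mod_depth * sin(2 pi mod_freq t))` (clipped at
#' 0), thinned to enforce the refractory period; CS times are homogeneous
#' Poisson; every SS falling within `cs_pause_ms` after a CS is deleted.
#' The result passes [qc_single_unit()] by construction.
#'
#' @param params a `spike_gen_params`.
#' @param seed integer RNG seed.
#' @return a `spike_train`; attribute `"true_rate_hz"` holds the modulated
#'   rate sampled at 1 kHz.
#' @export
simulate_spike_train <- function(params = spike_gen_params(), seed = 1) {
  stopifnot(inherits(params, "spike_gen_params"))
  set.seed(seed)
  dt <- 1e-3
  n <- round(params$duration_ms)
  tt <- (seq_len(n) - 1) * dt
  rate <- params$baseline_rate_hz *
    (1 + params$mod_depth * sin(2 * pi * params$mod_freq_hz * tt))
  rate <- pmax(rate, 0)
  # thinning against the rate envelope, then refractory enforcement
  cand <- which(stats::runif(n) < rate * dt)
  ss <- numeric(0)
  last <- -Inf
  for (i in cand) {
    t_ms <- (i - 1) + stats::runif(1)          # jitter within the 1 ms bin
    if (t_ms - last >= params$refractory_ms) {
      ss <- c(ss, t_ms)
      last <- t_ms
    }
  }
  n_cs <- stats::rpois(1, params$cs_rate_hz * params$duration_ms / 1000)
  cs <- sort(stats::runif(n_cs, 0, params$duration_ms))
  if (length(cs) > 0 && length(ss) > 0) {
    drop <- vapply(ss, function(t) {
      any(t > cs & t < cs + params$cs_pause_ms)
    }, logical(1))
    ss <- ss[!drop]
  }
  out <- spike_train(ss, cs, duration_ms = params$duration_ms)
  attr(out, "true_rate_hz") <- rate
  out
}
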