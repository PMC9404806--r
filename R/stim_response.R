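#' Align whisker traces to stimulus onsets
#'
#' Extracts the per-stimulus segment `[onset - pre, onset + post)` for every
#' pulse of a train and stacks them into a trial matrix together with the
#' per-sample mean and dispersion.
#'
#' @param trace an `angle_trace` covering the whole train.
#' @param train a `stim_train` with onsets in the trace's time base.
#' @param window_ms length-2 `c(pre, post)` in ms relative to onset
#'   (default `c(0, ipi)`).
#' @param dispersion "sd" (default) or "sem".
#' @return object of class `aligned_response`: `trial_matrix`
#'   (trials x samples), `mean_trace`, `dispersion`, `window_ms`, `fs_hz`,
#'   `freq_hz`.
#' @export
align_traces <- function(trace, train, window_ms = NULL,
                         dispersion = c("sd", "sem")) {
  stopifnot(inherits(trace, "angle_trace"), inherits(train, "stim_train"))
  dispersion <- match.arg(dispersion)
  if (is.null(window_ms)) window_ms <- c(0, train$ipi_ms)
  fs <- trace$fs_hz
  n <- length(trace$values_deg)
  pre <- round(window_ms[1] * fs / 1000)
  post <- round(window_ms[2] * fs / 1000)
  segs <- matrix(NA_real_, nrow = train$n_pulses, ncol = pre + post)
  for (i in seq_len(train$n_pulses)) {
    j0 <- floor(train$onsets_ms[i] * fs / 1000) + 1 - pre
    j1 <- j0 + pre + post - 1
    if (j0 < 1 || j1 > n)
      stop("alignment window for stimulus ", i, " exceeds the trace bounds")
    segs[i, ] <- trace$values_deg[j0:j1]
  }
  m <- colMeans(segs)
  sdv <- apply(segs, 2, stats::sd)
  if (dispersion == "sem") sdv <- sdv / sqrt(nrow(segs))
  structure(
    list(trial_matrix = segs, mean_trace = m, dispersion = sdv,
         window_ms = window_ms, fs_hz = fs, freq_hz = train$freq_hz),
    class = "aligned_response"
  )
}

# Window rule shared by the amplitude measures: full inter-stimulus
# interval at >= 4 Hz; a 250 ms cap strictly below 4 Hz, excluding
# spontaneous whisks between widely spaced stimuli. The last stimulus uses
# one nominal IPI after its onset.
epoch_window_ms <- function(train, i) {
  onset <- train$onsets_ms[i]
  nxt <- if (i < train$n_pulses) train$onsets_ms[i + 1] else onset + train$ipi_ms
  if (train$freq_hz < 4) nxt <- min(nxt, onset + 250)
  c(onset, nxt)
}

#' Whisker response amplitude within one inter-stimulus epoch
#'
#' Maximum minus minimum of the trace over the epoch of stimulus `i`:
#' `[onset_i, onset_{i+1})` for train frequencies of 4 Hz and above, capped
#' at 250 ms after the onset for frequencies strictly below 4 Hz (to
#' exclude spontaneous whisks between widely spaced stimuli). The last
#' stimulus uses one nominal IPI after its onset.
#'
#' @param trace an `angle_trace` (single-trial trace or a mean trace
#'   wrapped as an `angle_trace` whose time base starts at the train onset).
#' @param train a `stim_train`.
#' @param i 1-based stimulus index.
#' @return amplitude in degrees.
#' @export
epoch_amplitude <- function(trace, train, i) {
  if (i < 1 || i > train$n_pulses)
    stop("stimulus index ", i, " out of range 1..", train$n_pulses)
  w <- epoch_window_ms(train, i)
  fs <- trace$fs_hz
  j0 <- floor(w[1] * fs / 1000) + 1
  j1 <- min(length(trace$values_deg), ceiling(w[2] * fs / 1000))
  seg <- trace$values_deg[j0:j1]
  max(seg) - min(seg)
}

#' Amplitude tuning curve across stimulation frequencies
#'
#' For every train of a session, aligns the trace to stimulus onsets,
#' computes the stimulus-averaged mean whisker trace, and measures its
#' amplitude (max minus min over the epoch window rule). Frequencies
#' present twice are averaged. Returns the curve and the frequency of
#' maximal evoked amplitude.
#'
#' @param trace an `angle_trace` covering the session (low-passed).
#' @param session a `stim_session`.
#' @return object of class `tuning_curve`: data.frame `curve` with
#'   `freq_hz`, `amplitude_deg`; `peak_freq_hz`.
#' @export
tuning_curve <- function(trace, session) {
  stopifnot(inherits(session, "stim_session"))
  freqs <- vapply(session$trains, function(tr) tr$freq_hz, 0)
  amps <- vapply(session$trains, function(tr) {
    ar <- align_traces(trace, tr)
    w_ms <- if (tr$freq_hz < 4) min(tr$ipi_ms, 250) else tr$ipi_ms
    m <- ar$mean_trace[seq_len(round(w_ms * trace$fs_hz / 1000))]
    max(m) - min(m)
  }, 0)
  curve <- stats::aggregate(list(amplitude_deg = amps),
                            by = list(freq_hz = freqs), FUN = mean)
  curve <- curve[order(curve$freq_hz), ]
  rownames(curve) <- NULL
  structure(
    list(curve = curve,
         peak_freq_hz = curve$freq_hz[which.max(curve$amplitude_deg)]),
    class = "tuning_curve"
  )
}

#' Single-trial entrainment amplitudes
#'
#' Amplitudes (max minus min of the raw low-passed trace, not the mean
#' trace) between consecutive stimuli for the first 15 stimuli of a train
#' (10 at 0.5 Hz, matching the total pulse count at that frequency), using
#' the same 250 ms cap below 4 Hz as [epoch_amplitude()].
#'
#' @param trace an `angle_trace`.
#' @param train a `stim_train` with at least 10 pulses.
#' @param drive_type "SS" or "CF" label carried into the result.
#' @return object of class `entrainment_result` with `amplitudes_deg`,
#'   `slope` (deg/stimulus, OLS vs 1-based index), `freq_hz`, `drive_type`.
#' @export
entrainment_amplitudes <- function(trace, train, drive_type = c("SS", "CF")) {
  drive_type <- match.arg(drive_type)
  if (train$n_pulses < 10)
    stop("entrainment analysis needs at least 10 pulses, got ", train$n_pulses)
  n_use <- min(15, train$n_pulses)
  amps <- vapply(seq_len(n_use), function(i) epoch_amplitude(trace, train, i),
                 numeric(1))
  structure(
    list(amplitudes_deg = amps, slope = entrainment_slope(amps),
         freq_hz = train$freq_hz, drive_type = drive_type),
    class = "entrainment_result"
  )
}

#' Entrainment slope
#'
#' Ordinary least-squares slope of amplitude against 1-based stimulus
#' index, in degrees per stimulus: a positive slope means the evoked
#' response grows over successive stimuli.
#'
#' @param amplitudes numeric vector of per-stimulus amplitudes (>= 3).
#' @return slope in deg/stimulus.
#' @export
entrainment_slope <- function(amplitudes) {
  if (length(amplitudes) < 3)
    stop("need at least 3 amplitudes for a slope, got ", length(amplitudes))
  idx <- seq_along(amplitudes)
  unname(stats::coef(stats::lm(amplitudes ~ idx))[2])
}

#' Compare entrainment slopes between drive types
#'
#' Two-sided paired t-test of per-frequency slopes (paired by stimulation
#' frequency) between SS-type and CF-type drive. A zero-variance difference
#' is degenerate for the t statistic: with identical vectors `t = 0, p = 1`
#' is reported, with a constant nonzero shift the result carries
#' `degenerate = TRUE` and `p = 0`.
#'
#' @param ss,cf equal-length numeric vectors of slopes, paired by frequency.
#' @return list with `t`, `p`, `higher` ("SS", "CF" or "tie"), `df`,
#'   `degenerate`.
#' @export
compare_slopes <- function(ss, cf) {
  if (length(ss) != length(cf))
    stop("slope vectors must be paired: lengths ", length(ss), " vs ",
         length(cf))
  d <- ss - cf
  higher <- if (mean(d) > 0) "SS" else if (mean(d) < 0) "CF" else "tie"
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
    if (all(d == 0)) return(list(t = 0, p = 1, higher = "tie",
                                 df = length(d) - 1, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, higher = higher,
                df = length(d) - 1, degenerate = TRUE))
  }
  tt <- stats::t.test(ss, cf, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, higher = higher,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Whisker spectra before and after the end of a train
#'
#' Compares the Morlet-CWT mean power spectra of the whisker trace in the
#' 1 s before the last stimulus onset and the 1 s after the last pulse
#' ends, and reports whether the post-stimulation peak lies within one
#' grid step of the train frequency (i.e. whether the whisker keeps
#' oscillating at the drive frequency).
#'
#' @param trace an `angle_trace`.
#' @param train a `stim_train`.
#' @param window_ms comparison window length (default 1000).
#' @param ... passed to [cwt_scalogram()].
#' @return list with `spectrum_before`, `spectrum_after` (both
#'   `power_spectrum`), `same_peak` (logical), `post_peak_hz`.
#' @export
post_stim_spectrum <- function(trace, train, window_ms = 1000, ...) {
  fs <- trace$fs_hz
  last <- train$onsets_ms[train$n_pulses]
  n <- length(trace$values_deg)
  j_last <- floor(last * fs / 1000) + 1
  w <- round(window_ms * fs / 1000)
  j_post0 <- j_last + round(train$pulse_ms * fs / 1000)
  if (j_last - w < 1 || j_post0 + w - 1 > n)
    stop("need at least ", window_ms, " ms of samples on both sides of the ",
         "last stimulus")
  before <- trace$values_deg[(j_last - w):(j_last - 1)]
  after <- trace$values_deg[j_post0:(j_post0 + w - 1)]
  spec_b <- mean_power_spectrum(cwt_scalogram(before, fs, ...))
  spec_a <- mean_power_spectrum(cwt_scalogram(after, fs, ...))
  step <- mean(diff(spec_a$freqs_hz))
  post_peak <- spec_a$peak_hz
  same <- is.finite(post_peak) && max(spec_a$power, na.rm = TRUE) > 0 &&
    abs(post_peak - train$freq_hz) <= step + 1e-9
  list(spectrum_before = spec_b, spectrum_after = spec_a,
       same_peak = same, post_peak_hz = post_peak)
}

#' @export
print.aligned_response <- function(x, ...) {
  cat(sprintf(
    "<aligned_response> %g Hz train: %d trials x %d samples, window [%g, %g) ms\n",
    x$freq_hz, nrow(x$trial_matrix), ncol(x$trial_matrix),
    -x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' @export
plot.aligned_response <- function(x, ...) {
  t_ms <- seq(-x$window_ms[1], x$window_ms[2] - 1000 / x$fs_hz,
              by = 1000 / x$fs_hz)
  ylim <- range(x$mean_trace - x$dispersion, x$mean_trace + x$dispersion)
  graphics::plot(t_ms, x$mean_trace, type = "n", ylim = ylim,
                 xlab = "time from stimulus onset (ms)",
                 ylab = "whisker angle (deg)", ...)
  graphics::polygon(c(t_ms, rev(t_ms)),
                    c(x$mean_trace + x$dispersion,
                      rev(x$mean_trace - x$dispersion)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(t_ms, x$mean_trace)
  graphics::abline(v = 0, lty = 2, col = "blue")
  invisible(x)
}

#' @export
print.entrainment_result <- function(x, ...) {
  cat(sprintf(
    "<entrainment_result> %s drive at %g Hz: %d amplitudes, slope %.4f deg/stimulus\n",
    x$drive_type, x$freq_hz, length(x$amplitudes_deg), x$slope))
  invisible(x)
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("<tuning_curve> evoked amplitude by stimulation frequency:\n")
  print(x$curve)
  cat(sprintf("maximal response at %g Hz\n", x$peak_freq_hz))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$curve$freq_hz, x$curve$amplitude_deg, type = "b", log = "x",
                 xlab = "stimulation frequency (Hz)",
                 ylab = "evoked amplitude (deg)", ...)
  graphics::abline(v = x$peak_freq_hz, lty = 2, col = "grey")
  invisible(x)
}
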