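#' Construct a spike train
#'
#' Container for simple-spike (SS) and complex-spike (CS) event times from a
#' single-unit Purkinje cell recording.
#'
#' @param ss_times_ms SS event times in ms, ascending, within
#'   `[0, duration_ms)`.
#' @param cs_times_ms CS event times in ms (may be empty).
#' @param duration_ms recording length in ms.
#' @param fs_hz nominal sampling rate used when vectorizing (default 1000).
#' @param ss_amplitude,ss_width optional per-SS waveform amplitude and width
#'   series for the recording-stability check in [qc_single_unit()].
#' @return object of class `spike_train`.
#' @export
spike_train <- function(ss_times_ms, cs_times_ms = numeric(0), duration_ms,
                        fs_hz = 1000, ss_amplitude = NULL, ss_width = NULL) {
  ss_times_ms <- as.numeric(ss_times_ms)
  cs_times_ms <- as.numeric(cs_times_ms)
  if (length(duration_ms) != 1 || !is.finite(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be a single positive number")
  if (is.unsorted(ss_times_ms)) stop("ss_times_ms must be sorted ascending")
  bad <- c(ss_times_ms, cs_times_ms)
  bad <- bad[bad < 0 | bad >= duration_ms]
  if (length(bad) > 0)
    stop("spike time ", bad[1], " ms outside [0, ", duration_ms, ") ms")
  structure(
    list(ss_times_ms = ss_times_ms,
         cs_times_ms = sort(cs_times_ms),
         duration_ms = duration_ms,
         fs_hz = fs_hz,
         ss_amplitude = ss_amplitude,
         ss_width = ss_width),
    class = "spike_train"
  )
}

#' Convert a spike train to a logical (0/1) vector
#'
#' Bins SS times into half-open 1-sample bins `[k, k+1)` (in sample units at
#' `fs_hz`). The output is logical, not a count: two spikes in one bin yield
#' a single 1. With the 3 ms refractory period enforced by quality control
#' the two conventions coincide at 1 kHz.
#'
#' @param train a `spike_train`.
#' @return integer vector of 0/1 of length `round(duration_ms * fs_hz / 1000)`.
#' @export
to_logical_vector <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  n <- round(train$duration_ms * train$fs_hz / 1000)
  idx <- floor(train$ss_times_ms * train$fs_hz / 1000) + 1L
  out_of_range <- train$ss_times_ms[idx < 1L | idx > n]
  if (length(out_of_range) > 0)
    stop("spike time ", out_of_range[1], " ms falls outside the recording")
  v <- integer(n)
  v[idx] <- 1L
  v
}

#' Gaussian smoothing kernel
#'
#' Evaluates `exp(-x^2 / (2 n^2))` on a symmetric grid of `length` points
#' centred on 0 and normalizes to unit sum. For even `length` the grid is
#' half-sample offset (e.g. -49.5, ..., +49.5 for length 100) so the kernel
#' is exactly symmetric without an asymmetric centre sample.
#'
#' @param n kernel width parameter, in samples.
#' @param length kernel support in samples (default 100, i.e. 0.1 s at 1 kHz).
#' @return numeric vector of `length` weights summing to 1.
#' @export
gaussian_kernel <- function(n, length = 100) {
  if (n <= 0) stop("kernel width parameter n must be positive")
  if (length < 3) stop("kernel support must be at least 3 samples")
  x <- seq_len(length) - (length + 1) / 2
  k <- exp(-x^2 / (2 * n^2))
  k / sum(k)
}

#' Composite double-Gaussian kernel
#'
#' Elementwise mean of the unit-sum Gaussian kernels with width parameters
#' n = 8 and n = 20 on a 100-sample support. The narrow component preserves
#' fast rate transients while the wide component stabilizes the estimate;
#' the mean of two unit-sum kernels is itself unit-sum.
#'
#' @param length kernel support in samples (default 100).
#' @return numeric vector of weights summing to 1.
#' @export
composite_kernel <- function(length = 100) {
  (gaussian_kernel(8, length) + gaussian_kernel(20, length)) / 2
}

#' Instantaneous firing frequency by kernel convolution
#'
#' Convolves a logical spike vector with a unit-sum smoothing kernel and
#' scales by the sampling rate, so a periodic train at r Hz reads r Hz away
#' from the edges. Edges are zero-padded; the first and last `edge_ms`
#' (half the default kernel support) of the result are flagged as
#' edge-contaminated via the `edge_ms` field.
#'
#' @param vec 0/1 spike vector at `fs_hz`.
#' @param kernel unit-sum smoothing kernel (default [composite_kernel()]).
#' @param fs_hz sampling rate in Hz (default 1000).
#' @return object of class `rate_trace` with fields `values_hz`, `fs_hz`,
#'   `band` (NULL until filtered) and `edge_ms`.
#' @export
instantaneous_frequency <- function(vec, kernel = composite_kernel(),
                                    fs_hz = 1000) {
  if (length(kernel) > length(vec))
    stop("kernel (", length(kernel), ") longer than signal (", length(vec), ")")
  if (abs(sum(kernel) - 1) > 1e-8)
    stop("kernel must be normalized to unit sum")
  n <- length(vec)
  m <- length(kernel)
  full <- stats::convolve(as.numeric(vec), rev(kernel), type = "open")
  # centre of the full convolution: same-length output, zero-padded edges.
  # For even m the kernel grid is half-sample offset; take the leading
  # alignment so sample k of the output is centred on bin k.
  start <- floor((m + 1) / 2)
  vals <- full[start:(start + n - 1)] * fs_hz
  structure(
    list(values_hz = vals, fs_hz = fs_hz, band = NULL,
         edge_ms = ceiling(m / 2) * 1000 / fs_hz),
    class = "rate_trace"
  )
}

#' Band-pass filter an instantaneous-frequency trace
#'
#' Zero-phase (forward-backward) Butterworth band-pass, by default 3-25 Hz,
#' used to isolate whisking-band rate modulation and cancel 1/f trends.
#' The filter is 4th order (two second-order sections in `signal::butter`)
#' applied with `signal::filtfilt`, so event timing is preserved.
#'
#' @param rate a `rate_trace`.
#' @param low,high band edges in Hz (defaults 3 and 25).
#' @return a `rate_trace` with `band = c(low, high)`; mean approximately 0.
#' @export
bandpass_rate <- function(rate, low = 3, high = 25) {
  stopifnot(inherits(rate, "rate_trace"))
  nyq <- rate$fs_hz / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("invalid band [", low, ", ", high, "] Hz for fs ", rate$fs_hz, " Hz")
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  # demean first: DC is in the stopband anyway and removing it up front
  # suppresses the start-up transient of the recursive filter
  vals <- signal::filtfilt(bf, rate$values_hz - mean(rate$values_hz))
  structure(
    list(values_hz = vals, fs_hz = rate$fs_hz, band = c(low, high),
         edge_ms = rate$edge_ms),
    class = "rate_trace"
  )
}

#' Single-unit quality control
#'
#' Applies the acceptance criteria for a stable Purkinje-cell single unit:
#' \itemize{
#'   \item minimal SS inter-spike interval of 3 ms (`"ss_isi"`),
#'   \item every CS followed by an SS pause of at least 8 ms (`"cs_pause"`),
#'   \item no run of more than three consecutive spikes whose waveform
#'     amplitude or width deviates more than 3 SD from its mean
#'     (`"stability"`, only checked when the series are supplied),
#'   \item minimum recording duration of 40 s (`"duration"`).
#' }
#' All violated criteria are reported, not just the first; QC never raises
#' an error on recording content.
#'
#' @param train a `spike_train`.
#' @param min_isi_ms,min_cs_pause_ms,min_duration_ms criterion thresholds.
#' @return list with `pass` (logical) and `violated` (character vector of
#'   criterion names, empty when passing).
#' @export
qc_single_unit <- function(train, min_isi_ms = 3, min_cs_pause_ms = 8,
                           min_duration_ms = 40000) {
  stopifnot(inherits(train, "spike_train"))
  violated <- character(0)
  ss <- train$ss_times_ms
  if (length(ss) >= 2 && any(diff(ss) < min_isi_ms))
    violated <- c(violated, "ss_isi")
  if (length(train$cs_times_ms) > 0 && length(ss) > 0) {
    for (cs in train$cs_times_ms) {
      if (any(ss > cs & ss < cs + min_cs_pause_ms)) {
        violated <- c(violated, "cs_pause")
        break
      }
    }
  }
  unstable <- function(x) {
    if (is.null(x) || length(x) < 4) return(FALSE)
    dev <- abs(x - mean(x)) > 3 * stats::sd(x)
    r <- rle(dev)
    any(r$values & r$lengths > 3)
  }
  if (unstable(train$ss_amplitude) || unstable(train$ss_width))
    violated <- c(violated, "stability")
  if (train$duration_ms < min_duration_ms)
    violated <- c(violated, "duration")
  list(pass = length(violated) == 0, violated = violated)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d SS, %d CS over %.1f s (mean SS rate %.1f Hz)\n",
              length(x$ss_times_ms), length(x$cs_times_ms),
              x$duration_ms / 1000,
              length(x$ss_times_ms) / (x$duration_ms / 1000)))
  invisible(x)
}

#' @export
print.rate_trace <- function(x, ...) {
  band <- if (is.null(x$band)) "unfiltered"
          else sprintf("band-passed %g-%g Hz", x$band[1], x$band[2])
  cat(sprintf("<rate_trace> %d samples at %g Hz, %s, mean %.2f Hz\n",
              length(x$values_hz), x$fs_hz, band, mean(x$values_hz)))
  invisible(x)
}
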