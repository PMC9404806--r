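#' Morlet continuous wavelet transform scalogram
#'
#' Computes the magnitude-squared Morlet CWT of a uniformly sampled signal
#' on a regular frequency grid, preserving time as well as frequency
#' information. The transform is evaluated in the frequency domain: one FFT
#' of the signal, multiplied per scale by the analytic Morlet window
#' \eqn{\pi^{-1/4} e^{-(s\omega-\omega_0)^2/2}} (for \eqn{\omega>0}) with
#' the per-scale energy normalization \eqn{\sqrt{2\pi s/\delta t}}, then
#' inverse transformed. The centre-frequency parameter \eqn{\omega_0} is 6
#' cycles by default, the standard trade-off between time and frequency
#' resolution; the scale for frequency f is
#' \eqn{s = (\omega_0 + \sqrt{2+\omega_0^2})/(4\pi f)}.
#'
#' A cone-of-influence mask marks, per frequency, the samples within the
#' e-folding time \eqn{\sqrt{2}s} of either edge; those samples are excluded
#' from time averages so boundary effects do not inflate low-frequency
#' power.
#'
#' @param x numeric signal (or an `angle_trace` / `rate_trace`).
#' @param fs_hz sampling rate in Hz (taken from the object if one is given).
#' @param fmin,fmax frequency grid limits in Hz (defaults 1 and 30).
#' @param df grid spacing in Hz (default 0.1).
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return object of class `scalogram`: `freqs_hz` (ascending), `power`
#'   (frequency x time matrix), `fs_hz`, `coi` (logical matrix, TRUE where
#'   the sample is inside the valid region), `omega0`.
#' @export
cwt_scalogram <- function(x, fs_hz = 1000, fmin = 1, fmax = 30, df = 0.1,
                          omega0 = 6) {
  if (inherits(x, "angle_trace")) { fs_hz <- x$fs_hz; x <- x$values_deg }
  else if (inherits(x, "rate_trace")) { fs_hz <- x$fs_hz; x <- x$values_hz }
  n <- length(x)
  if (n < fs_hz / fmin)
    stop("signal (", n, " samples) shorter than one period of fmin = ",
         fmin, " Hz")
  freqs <- seq(fmin, fmax, by = df)
  dt <- 1 / fs_hz
  npad <- stats::nextn(n, 2)
  xhat <- stats::fft(c(x - mean(x), numeric(npad - n)))
  omega <- 2 * pi * c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * dt)
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  W <- matrix(0, nrow = length(freqs), ncol = n)
  coi <- matrix(FALSE, nrow = length(freqs), ncol = n)
  t_edge <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  for (j in seq_along(freqs)) {
    s <- fourier_factor / freqs[j]
    win <- numeric(npad)
    pos <- omega > 0
    win[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    wj <- stats::fft(xhat * win, inverse = TRUE)[seq_len(n)] / npad
    W[j, ] <- Mod(wj)^2
    coi[j, ] <- t_edge >= sqrt(2) * s
  }
  structure(
    list(freqs_hz = freqs, power = W, fs_hz = fs_hz, coi = coi,
         omega0 = omega0),
    class = "scalogram"
  )
}

#' Time-averaged power spectrum from a scalogram
#'
#' Averages scalogram power over time, optionally restricted to a union of
#' intervals (e.g. movement periods), always excluding cone-of-influence
#' samples. Frequencies whose valid-sample set is empty (possible for low
#' frequencies on short signals) get `NA` power and are ignored by
#' [peak_frequency()].
#'
#' @param scal a `scalogram`.
#' @param periods_ms optional data.frame with `start_ms`, `end_ms` columns
#'   (half-open intervals); NULL averages the whole signal.
#' @return object of class `power_spectrum`: `freqs_hz`, `power`,
#'   `peak_hz`, `normalized` (FALSE).
#' @export
mean_power_spectrum <- function(scal, periods_ms = NULL) {
  stopifnot(inherits(scal, "scalogram"))
  n <- ncol(scal$power)
  keep <- rep(TRUE, n)
  if (!is.null(periods_ms)) {
    if (nrow(periods_ms) == 0) stop("empty movement-period union")
    t_ms <- (seq_len(n) - 1) * 1000 / scal$fs_hz
    keep <- rep(FALSE, n)
    for (k in seq_len(nrow(periods_ms))) {
      keep <- keep | (t_ms >= periods_ms$start_ms[k] &
                      t_ms < periods_ms$end_ms[k])
    }
    if (!any(keep)) stop("empty movement-period union")
  }
  pw <- vapply(seq_along(scal$freqs_hz), function(j) {
    sel <- keep & scal$coi[j, ]
    if (!any(sel)) return(NA_real_)
    mean(scal$power[j, sel])
  }, numeric(1))
  new_power_spectrum(scal$freqs_hz, pw, normalized = FALSE)
}

new_power_spectrum <- function(freqs, power, normalized) {
  peak <- if (all(is.na(power))) NA_real_
          else freqs[which.max(replace(power, is.na(power), -Inf))]
  structure(
    list(freqs_hz = freqs, power = power, peak_hz = peak,
         normalized = normalized),
    class = "power_spectrum"
  )
}

#' Normalize a power spectrum to unit peak
#'
#' Divides power by its maximum so spectra from different animals or
#' conditions can be overlaid; the peak frequency is unchanged and the
#' operation is idempotent.
#'
#' @param spec a `power_spectrum`.
#' @param mode "max" (default) or "area" (divide by the integral).
#' @return normalized `power_spectrum`.
#' @export
normalize_spectrum <- function(spec, mode = c("max", "area")) {
  mode <- match.arg(mode)
  pw <- spec$power
  denom <- if (mode == "max") max(pw, na.rm = TRUE)
           else sum(pw, na.rm = TRUE) * mean(diff(spec$freqs_hz))
  if (!is.finite(denom) || denom <= 0)
    stop("cannot normalize an all-zero spectrum")
  new_power_spectrum(spec$freqs_hz, pw / denom, normalized = TRUE)
}

#' Frequency of maximum spectral power
#'
#' @param spec a `power_spectrum`.
#' @param band optional `c(low, high)` restriction in Hz (inclusive).
#' @return frequency in Hz of the maximum power in band; ties and flat
#'   spectra resolve to the lowest qualifying frequency.
#' @export
peak_frequency <- function(spec, band = NULL) {
  f <- spec$freqs_hz
  pw <- spec$power
  if (!is.null(band)) {
    sel <- f >= band[1] & f <= band[2]
    if (!any(sel)) stop("band [", band[1], ", ", band[2],
                        "] Hz contains no grid frequencies")
    f <- f[sel]; pw <- pw[sel]
  }
  if (all(is.na(pw))) return(NA_real_)
  pw[is.na(pw)] <- -Inf
  f[which.max(pw)]   # which.max takes the first (lowest-frequency) maximum
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d freqs (%g-%g Hz) x %d samples at %g Hz\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              ncol(x$power), x$fs_hz))
  invisible(x)
}

#' @export
plot.scalogram <- function(x, ...) {
  t_s <- (seq_len(ncol(x$power)) - 1) / x$fs_hz
  graphics::image(t_s, x$freqs_hz, t(x$power), xlab = "time (s)",
                  ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %g-%g Hz%s, peak at %.1f Hz\n",
              min(x$freqs_hz), max(x$freqs_hz),
              if (x$normalized) " (unit peak)" else "", x$peak_hz))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ...) {
  graphics::plot(x$freqs_hz, x$power, type = "l", xlab = "frequency (Hz)",
                 ylab = if (x$normalized) "normalized power" else "power", ...)
  graphics::abline(v = x$peak_hz, lty = 2, col = "grey")
  invisible(x)
}
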