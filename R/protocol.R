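#' Stimulation protocol table
#'
#' The optogenetic paradigm uses seven pulse-train frequencies with a fixed
#' 20 ms LED pulse. Inter-pulse intervals (IPI, onset-to-onset) and pulse
#' counts are stored as the printed lookup table rather than derived from
#' 20 s / IPI, because the printed counts deviate from exact division at the
#' higher frequencies and fidelity to the protocol wins.
#'
#' @return data.frame with columns `freq_hz`, `ipi_ms`, `n_pulses`.
#' @export
protocol_table <- function() {
  data.frame(
    freq_hz  = c(0.5, 1, 2, 4, 8, 14, 28),
    ipi_ms   = c(2000, 1000, 500, 250, 125, 77, 35),
    n_pulses = c(10, 20, 40, 80, 140, 280, 660)
  )
}

#' Construct a single stimulation pulse train
#'
#' Builds a train of rectangular LED pulses at one of the protocol
#' frequencies. Onsets start at 0 and are spaced by the printed IPI; the
#' pulse width is always 20 ms. A consistency warning (not an error) is
#' emitted if `n_pulses * ipi_ms` deviates from the nominal 20 s train
#' duration by more than 20%.
#'
#' @param freq_hz one of 0.5, 1, 2, 4, 8, 14, 28 Hz.
#' @param n_pulses optional override of the printed pulse count.
#' @param pulse_ms pulse duration in ms (default 20).
#' @return object of class `stim_train` with fields `freq_hz`, `onsets_ms`,
#'   `pulse_ms`, `ipi_ms`, `n_pulses`.
#' @export
#' @examples
#' tr <- build_train(2)
#' tr$n_pulses   # 40
#' tr$ipi_ms     # 500
build_train <- function(freq_hz, n_pulses = NULL, pulse_ms = 20) {
  tab <- protocol_table()
  row <- match(freq_hz, tab$freq_hz)
  if (is.na(row)) {
    stop("unsupported stimulation frequency ", freq_hz,
         " Hz; supported: ", paste(tab$freq_hz, collapse = ", "))
  }
  ipi <- tab$ipi_ms[row]
  if (is.null(n_pulses)) n_pulses <- tab$n_pulses[row]
  if (pulse_ms >= ipi) {
    stop("pulse_ms (", pulse_ms, ") must be shorter than the IPI (", ipi, " ms)")
  }
  if (abs(n_pulses * ipi - 20000) > 0.2 * 20000) {
    warning("train duration ", n_pulses * ipi,
            " ms deviates from the nominal 20 s by more than 20%")
  }
  structure(
    list(freq_hz = freq_hz,
         onsets_ms = (seq_len(n_pulses) - 1) * ipi,
         pulse_ms = pulse_ms,
         ipi_ms = ipi,
         n_pulses = n_pulses),
    class = "stim_train"
  )
}

#' Default session frequency order
#'
#' The listed sequence of train frequencies with the 0.5 and 14 Hz trains
#' repeated once at the end of the session. The within-session placement of
#' the repeats is configurable because the paradigm does not pin it down.
#'
#' @return numeric vector of frequencies (Hz), length 9.
#' @export
default_session_order <- function() c(0.5, 2, 14, 8, 28, 4, 1, 0.5, 14)

#' Assemble a stimulation session from trains
#'
#' Concatenates pulse trains with a resting gap between them. Train k+1
#' starts one IPI after the last onset of train k plus `rest_ms`.
#'
#' @param order frequencies of the successive trains
#'   (default [default_session_order()]).
#' @param rest_ms rest between trains in ms (default 10000).
#' @return object of class `stim_session`: list of `stim_train`s with
#'   absolute onsets, plus `train_start_ms` and `rest_ms`.
#' @export
build_session <- function(order = default_session_order(), rest_ms = 10000) {
  if (length(order) == 0) stop("empty session order")
  trains <- lapply(order, build_train)
  t0 <- 0
  starts <- numeric(length(trains))
  for (k in seq_along(trains)) {
    starts[k] <- t0
    trains[[k]]$onsets_ms <- trains[[k]]$onsets_ms + t0
    t0 <- trains[[k]]$onsets_ms[trains[[k]]$n_pulses] +
      trains[[k]]$ipi_ms + rest_ms
  }
  structure(
    list(trains = trains, train_start_ms = starts, rest_ms = rest_ms),
    class = "stim_session"
  )
}

#' Total duration of a session in ms
#'
#' Ends one IPI after the last onset of the final train (no trailing rest).
#' @param session a `stim_session`.
#' @return duration in ms.
#' @export
session_duration_ms <- function(session) {
  last <- session$trains[[length(session$trains)]]
  last$onsets_ms[last$n_pulses] + last$ipi_ms
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("<stim_train> %g Hz: %d pulses of %g ms, IPI %g ms, span %g ms\n",
              x$freq_hz, x$n_pulses, x$pulse_ms, x$ipi_ms,
              x$onsets_ms[x$n_pulses] - x$onsets_ms[1] + x$ipi_ms))
  invisible(x)
}

#' @export
print.stim_session <- function(x, ...) {
  cat(sprintf("<stim_session> %d trains, rest %g ms:\n",
              length(x$trains), x$rest_ms))
  for (tr in x$trains) {
    cat(sprintf("  %5.1f Hz  start %8.0f ms  %3d pulses\n",
                tr$freq_hz, tr$onsets_ms[1], tr$n_pulses))
  }
  invisible(x)
}
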