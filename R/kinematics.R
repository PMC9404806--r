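#' Construct a whisker angle trace
#'
#' Uniformly sampled mean whisker angle (degrees), one value per video frame.
#'
#' @param values_deg numeric vector of angles in degrees.
#' @param fs_hz sampling (frame) rate in Hz, default 1000.
#' @param filtered_hz low-pass cutoff already applied, or NULL for raw.
#' @return object of class `angle_trace`.
#' @export
angle_trace <- function(values_deg, fs_hz = 1000, filtered_hz = NULL) {
  values_deg <- as.numeric(values_deg)
  if (any(!is.finite(values_deg))) stop("angle trace contains non-finite values")
  structure(
    list(values_deg = values_deg, fs_hz = fs_hz, filtered_hz = filtered_hz),
    class = "angle_trace"
  )
}

#' Low-pass filter a whisker angle trace
#'
#' Zero-phase 4th-order Butterworth low-pass (default cutoff 30 Hz),
#' removing frame-to-frame tracking noise while leaving the whisking band
#' (< 25 Hz) essentially untouched.
#'
#' @param trace an `angle_trace`.
#' @param cutoff_hz cutoff frequency in Hz (default 30).
#' @return filtered `angle_trace` with `filtered_hz = cutoff_hz`.
#' @export
lowpass_angle <- function(trace, cutoff_hz = 30) {
  stopifnot(inherits(trace, "angle_trace"))
  if (cutoff_hz <= 0 || cutoff_hz >= trace$fs_hz / 2)
    stop("cutoff must lie in (0, fs/2) = (0, ", trace$fs_hz / 2, ") Hz")
  bf <- signal::butter(4, cutoff_hz / (trace$fs_hz / 2), type = "low")
  # filter around the mean: the low-pass has unit DC gain, and centring
  # suppresses the start-up transient of the recursive filter
  m <- mean(trace$values_deg)
  angle_trace(signal::filtfilt(bf, trace$values_deg - m) + m, trace$fs_hz,
              filtered_hz = cutoff_hz)
}

# Local extrema of a vector: indices of strict turning points, with plateaus
# resolved to their midpoint; the first and last samples are included so a
# monotone ramp yields exactly one extremum pair.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 2) return(seq_len(n))
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero slope through plateaus
  nz <- s != 0
  if (!any(nz)) return(c(1L, n))
  idx <- which(nz)
  turns <- integer(0)
  prev_i <- idx[1]
  for (i in idx[-1]) {
    if (s[i] != s[prev_i]) {
      # extremum spans the plateau (prev_i+1 .. i); take its midpoint
      turns <- c(turns, as.integer(floor((prev_i + 1 + i) / 2)))
    }
    prev_i <- i
  }
  unique(c(1L, turns, n))
}

# Prune an alternating extrema sequence so every remaining adjacent
# excursion is at least `thr`: repeatedly drop the interior pair bounding
# the smallest sub-threshold excursion (merging the neighbours, which stay
# alternating), then trim sub-threshold terminal swings.
prune_extrema <- function(ext, x, thr) {
  repeat {
    if (length(ext) < 2) return(integer(0))
    exc <- abs(diff(x[ext]))
    small <- which(exc < thr)
    if (length(small) == 0) return(ext)
    interior <- small[small > 1 & small < length(exc)]
    if (length(interior) > 0) {
      k <- interior[which.min(exc[interior])]
      ext <- ext[-c(k, k + 1)]
    } else if (exc[1] < thr && exc[length(exc)] >= thr) {
      ext <- ext[-1]
    } else if (exc[length(exc)] < thr && exc[1] >= thr) {
      ext <- ext[-length(ext)]
    } else {
      # both terminal swings sub-threshold (or only one swing left)
      k <- which.min(c(exc[1], exc[length(exc)]))
      ext <- if (k == 1) ext[-1] else ext[-length(ext)]
    }
  }
}

#' Detect whisker protraction and retraction events
#'
#' Identifies local extrema of a (low-pass filtered) angle trace and turns
#' every consecutive extremum pair whose angle change is at least
#' `threshold_deg` into one movement event: rising pairs (minimum to
#' maximum) are protractions, falling pairs retractions. Sub-threshold
#' wiggles are pruned before pairing, so reported events are
#' non-overlapping, time-ordered and alternate in kind wherever the trace
#' moves on the whisk time scale.
#'
#' Swings slower than `max_duration_ms` are discarded as drift: after
#' pruning, the excursion connecting the last whisk of one bout to the
#' first whisk of the next spans the whole rest period and would otherwise
#' be reported as a single seconds-long "movement". A whisker half-cycle at
#' the 3 Hz lower band edge lasts under 170 ms, so the 400 ms default keeps
#' every genuine protraction or retraction.
#'
#' @param trace an `angle_trace`, expected to be low-pass filtered.
#' @param threshold_deg minimum angle change for an event (default 4).
#' @param max_duration_ms maximum event duration (default 400); longer
#'   swings are treated as drift and dropped.
#' @return data.frame of class `movement_events` with columns `kind`
#'   ("protraction"/"retraction"), `start_idx`, `end_idx` (1-based sample
#'   indices, half-open span), `start_ms`, `end_ms`, `amplitude_deg`,
#'   `duration_ms`, `max_velocity_deg_ms`.
#' @export
detect_movements <- function(trace, threshold_deg = 4,
                             max_duration_ms = 400) {
  stopifnot(inherits(trace, "angle_trace"))
  x <- trace$values_deg
  ext <- prune_extrema(local_extrema(x), x, threshold_deg)
  if (length(ext) < 2) {
    ev <- data.frame(kind = character(0), start_idx = integer(0),
                     end_idx = integer(0), start_ms = numeric(0),
                     end_ms = numeric(0), amplitude_deg = numeric(0),
                     duration_ms = numeric(0),
                     max_velocity_deg_ms = numeric(0))
    class(ev) <- c("movement_events", "data.frame")
    return(ev)
  }
  s <- ext[-length(ext)]
  e <- ext[-1]
  kin <- t(vapply(seq_along(s), function(k) {
    seg <- x[s[k]:e[k]]
    v <- diff(seg) * trace$fs_hz / 1000     # deg per ms
    c(amp = abs(x[e[k]] - x[s[k]]),
      dur = (e[k] - s[k]) * 1000 / trace$fs_hz,
      vmax = max(abs(v)))
  }, numeric(3)))
  ev <- data.frame(
    kind = ifelse(x[e] > x[s], "protraction", "retraction"),
    start_idx = s, end_idx = e,
    start_ms = (s - 1) * 1000 / trace$fs_hz,
    end_ms = (e - 1) * 1000 / trace$fs_hz,
    amplitude_deg = kin[, "amp"],
    duration_ms = kin[, "dur"],
    max_velocity_deg_ms = kin[, "vmax"]
  )
  ev <- ev[ev$duration_ms <= max_duration_ms, ]
  rownames(ev) <- NULL
  class(ev) <- c("movement_events", "data.frame")
  ev
}

#' Define movement periods from detected events
#'
#' Takes the union of event spans and merges events separated by less than
#' `merge_gap_ms`, yielding disjoint, ordered, half-open intervals that
#' stand in for whisking bouts. The default gap of 250 ms is one
#' inter-pulse interval at 4 Hz.
#'
#' @param events a `movement_events` data.frame (time-ordered).
#' @param merge_gap_ms maximum gap bridged when merging (default 250).
#' @return data.frame with columns `start_ms`, `end_ms`.
#' @export
movement_periods <- function(events, merge_gap_ms = 250) {
  if (nrow(events) == 0)
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  s <- events$start_ms
  e <- events$end_ms
  out_s <- s[1]; out_e <- e[1]
  if (nrow(events) > 1) {
    for (k in 2:nrow(events)) {
      if (s[k] - out_e[length(out_e)] < merge_gap_ms) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], e[k])
      } else {
        out_s <- c(out_s, s[k]); out_e <- c(out_e, e[k])
      }
    }
  }
  data.frame(start_ms = out_s, end_ms = out_e)
}

#' Kinematics of a single movement event
#'
#' Amplitude is the absolute angle change between the event's endpoints,
#' duration the sample span over the frame rate, and maximum velocity the
#' largest absolute first difference scaled to deg/ms. No extra smoothing is
#' applied: the 30 Hz low-pass already suppresses frame noise.
#'
#' @param event one row of a `movement_events` data.frame.
#' @param trace the `angle_trace` the event was detected on.
#' @return list with `amplitude_deg`, `duration_ms`, `max_velocity_deg_ms`.
#' @export
event_kinematics <- function(event, trace) {
  s <- event$start_idx; e <- event$end_idx
  if (e <= s) stop("degenerate event: end_idx must exceed start_idx")
  if (s < 1 || e > length(trace$values_deg)) stop("event outside trace")
  seg <- trace$values_deg[s:e]
  list(
    amplitude_deg = abs(seg[length(seg)] - seg[1]),
    duration_ms = (e - s) * 1000 / trace$fs_hz,
    max_velocity_deg_ms = max(abs(diff(seg))) * trace$fs_hz / 1000
  )
}

#' Count whisk cycles in an interval
#'
#' A cycle is one complete protraction immediately followed by a
#' retraction; it is counted when the protraction starts inside the
#' half-open interval `[start_ms, end_ms)`.
#'
#' @param trace an `angle_trace` (low-pass filtered).
#' @param interval numeric length-2 vector `c(start_ms, end_ms)`.
#' @param threshold_deg event threshold passed to [detect_movements()].
#' @param events optional precomputed `movement_events` for `trace`.
#' @return integer cycle count.
#' @export
count_cycles <- function(trace, interval, threshold_deg = 4, events = NULL) {
  if (is.null(events)) events <- detect_movements(trace, threshold_deg)
  if (nrow(events) < 2) return(0L)
  n <- 0L
  for (k in seq_len(nrow(events) - 1)) {
    if (events$kind[k] == "protraction" &&
        events$kind[k + 1] == "retraction" &&
        events$start_ms[k] >= interval[1] && events$start_ms[k] < interval[2]) {
      n <- n + 1L
    }
  }
  n
}

#' @export
print.angle_trace <- function(x, ...) {
  filt <- if (is.null(x$filtered_hz)) "raw"
          else sprintf("low-passed %g Hz", x$filtered_hz)
  cat(sprintf("<angle_trace> %d samples at %g Hz (%s), range [%.2f, %.2f] deg\n",
              length(x$values_deg), x$fs_hz, filt,
              min(x$values_deg), max(x$values_deg)))
  invisible(x)
}

#' @export
plot.angle_trace <- function(x, ..., events = NULL) {
  t_ms <- (seq_along(x$values_deg) - 1) * 1000 / x$fs_hz
  graphics::plot(t_ms, x$values_deg, type = "l", xlab = "time (ms)",
                 ylab = "whisker angle (deg)", ...)
  if (!is.null(events) && nrow(events) > 0) {
    col <- ifelse(events$kind == "protraction", "blue", "red")
    graphics::points(events$start_ms, x$values_deg[events$start_idx],
                     col = col, pch = 16)
  }
  invisible(x)
}
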