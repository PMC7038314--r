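#' Detector parameters
#'
#' Tunables of the adaptive-threshold event detector. The threshold itself
#' is the running midpoint of the local extrema of the signal (see
#' [adaptive_threshold()]); `window` sets the duration over which "local" is
#' taken (it should span at least one gait cycle so both extrema are seen),
#' `refractory` suppresses repeated same-type detections closer than a
#' physiological step, and `min_amplitude` disarms detection while the
#' rolling max--min range is too small to be gait (e.g. quiet standing).
#'
#' @param window Rolling-extrema window, s (default 1.5).
#' @param refractory Minimum gap between same-type events, s (default 0.3).
#' @param min_amplitude Minimum rolling range (kPa) to arm detection
#'   (default 20).
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(window = 1.5, refractory = 0.3,
                            min_amplitude = 20) {
  if (!is.finite(window) || window <= 0) stop("window must be > 0",
                                              call. = FALSE)
  if (refractory < 0) stop("refractory must be >= 0", call. = FALSE)
  if (min_amplitude < 0) stop("min_amplitude must be >= 0", call. = FALSE)
  structure(list(window = window, refractory = refractory,
                 min_amplitude = min_amplitude), class = "detector_params")
}

# centered rolling extrema, window truncated at the edges
.roll_extrema <- function(x, fs, window) {
  width <- max(3L, 2L * floor(window * fs / 2) + 1L)
  width <- min(width, 2L * length(x) - 1L)
  list(max = zoo::rollapply(x, width, max, partial = TRUE, align = "center"),
       min = zoo::rollapply(x, width, min, partial = TRUE, align = "center"))
}

#' Adaptive threshold of a pressure signal
#'
#' The running midpoint between the local maximum and local minimum of the
#' signal: at each sample, `(rolling_max + rolling_min) / 2` over a centered
#' window of `params$window` seconds (truncated at the edges). By
#' construction the threshold is bounded by the rolling extrema everywhere.
#'
#' @param x Numeric pressure series, kPa; length >= 2.
#' @param fs Sampling frequency, Hz.
#' @param params A [detector_params()].
#' @return Numeric threshold series the same length as `x`, with attributes
#'   `roll_max` and `roll_min` (the rolling extrema).
#' @examples
#' adaptive_threshold(rep(100, 50), fs = 100)  # constant signal -> 100
#' @export
adaptive_threshold <- function(x, fs, params = detector_params()) {
  if (length(x) < 2L) stop("signal must have at least 2 samples",
                           call. = FALSE)
  ex <- .roll_extrema(x, fs, params$window)
  thr <- (ex$max + ex$min) / 2
  attr(thr, "roll_max") <- ex$max
  attr(thr, "roll_min") <- ex$min
  thr
}

# crossings: direction +1 for upward (signal rises to >= threshold),
# -1 for downward (signal falls to < threshold); refractory applied in order
.detect_crossings <- function(x, fs, params, direction, t0 = 0) {
  thr <- adaptive_threshold(x, fs, params)
  armed <- (attr(thr, "roll_max") - attr(thr, "roll_min")) >=
    params$min_amplitude
  above <- x >= thr
  idx <- if (direction > 0) {
    which(above & !c(TRUE, above[-length(above)]))
  } else {
    which(!above & c(FALSE, above[-length(above)]))
  }
  idx <- idx[armed[idx]]
  if (length(idx) > 1L && params$refractory > 0) {
    keep <- idx[1L]
    gap <- params$refractory * fs
    for (i in idx[-1L]) if (i - keep[length(keep)] >= gap) keep <- c(keep, i)
    idx <- keep
  }
  t0 + (idx - 1L) / fs
}

#' Detect initial contacts (heel strikes)
#'
#' An initial contact is reported at the first sample where the heel
#' pressure signal reaches or exceeds its adaptive threshold after having
#' been below it, subject to the refractory period and the arming range.
#' Event times are sample times (no sub-sample interpolation).
#'
#' @param heel Heel pressure series, kPa.
#' @param fs Sampling frequency, Hz.
#' @param params A [detector_params()].
#' @param t0 Time of the first sample, s.
#' @return Numeric vector of event times (possibly empty).
#' @export
detect_initial_contacts <- function(heel, fs, params = detector_params(),
                                    t0 = 0) {
  .detect_crossings(heel, fs, params, direction = +1L, t0 = t0)
}

#' Detect toe offs
#'
#' A toe off is reported at the first sample where the hallux pressure
#' signal drops below its adaptive threshold after having been at or above
#' it; otherwise identical to [detect_initial_contacts()].
#'
#' @param hallux Hallux pressure series, kPa.
#' @inheritParams detect_initial_contacts
#' @return Numeric vector of event times (possibly empty).
#' @export
detect_toe_offs <- function(hallux, fs, params = detector_params(), t0 = 0) {
  .detect_crossings(hallux, fs, params, direction = -1L, t0 = t0)
}

#' Pair events into stance intervals
#'
#' Each initial contact is paired with the first toe off strictly after it
#' and before the next initial contact; leading unpaired toe offs and
#' trailing unpaired initial contacts are dropped.
#'
#' @param ics,tos Sorted event-time vectors (s).
#' @param foot_side `"left"` or `"right"`.
#' @return A [stance_intervals()] object.
#' @examples
#' pair_stance_intervals(c(0.2, 1.2), c(0.8, 1.8), "left")
#' @export
pair_stance_intervals <- function(ics, tos, foot_side = "left") {
  ic_out <- numeric(0); to_out <- numeric(0)
  for (k in seq_along(ics)) {
    upper <- if (k < length(ics)) ics[k + 1L] else Inf
    cand <- tos[tos > ics[k] & tos < upper]
    if (length(cand)) {
      ic_out <- c(ic_out, ics[k])
      to_out <- c(to_out, cand[1L])
    }
  }
  stance_intervals(foot_side, ic_out, to_out)
}

#' Detect gait events for a whole recording
#'
#' Convenience wrapper: runs [detect_initial_contacts()] on the heel channel
#' and [detect_toe_offs()] on the hallux channel of a recording.
#'
#' @param rec A [pressure_recording()].
#' @param params A [detector_params()].
#' @return A [gait_events()] object.
#' @export
detect_gait_events <- function(rec, params = detector_params()) {
  stopifnot(inherits(rec, "pressure_recording"))
  gait_events(
    rec$foot_side,
    detect_initial_contacts(rec$pressures[, "heel"], rec$fs, params, rec$t0),
    detect_toe_offs(rec$pressures[, "hallux"], rec$fs, params, rec$t0)
  )
}
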