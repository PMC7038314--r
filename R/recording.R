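#' Construct a plantar-pressure recording
#'
#' A recording is a uniformly sampled T x 8 matrix of pressures in kPa, one
#' column per sensor site in canonical [SENSOR_SITES] order, for one foot.
#'
#' @param foot_side `"left"` or `"right"`.
#' @param pressures Numeric matrix, T rows x 8 columns; column names must be
#'   the canonical site labels (reordered to canonical order if needed).
#'   All values must be finite and non-negative (kPa).
#' @param fs Sampling frequency in Hz (default 100).
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(foot_side, pressures, fs = 100, t0 = 0) {
  foot_side <- match.arg(foot_side, c("left", "right"))
  pressures <- as.matrix(pressures)
  if (ncol(pressures) != 8L) {
    stop("pressures must have 8 columns (one per sensor site)", call. = FALSE)
  }
  if (is.null(colnames(pressures))) {
    colnames(pressures) <- SENSOR_SITES
  } else if (!setequal(colnames(pressures), SENSOR_SITES)) {
    stop("pressure columns must be the canonical sensor sites", call. = FALSE)
  } else {
    pressures <- pressures[, SENSOR_SITES, drop = FALSE]
  }
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (anyNA(pressures) || any(!is.finite(pressures))) {
    stop("pressures must be finite", call. = FALSE)
  }
  if (any(pressures < 0)) {
    stop("pressures must be non-negative", call. = FALSE)
  }
  structure(list(foot_side = foot_side, t0 = as.numeric(t0),
                 fs = as.numeric(fs), pressures = pressures),
            class = "pressure_recording")
}

#' Sample times of a recording
#'
#' @param rec A `pressure_recording`.
#' @return Numeric vector `t0 + (0:(T-1))/fs`, seconds.
#' @export
recording_times <- function(rec) {
  stopifnot(inherits(rec, "pressure_recording"))
  rec$t0 + (seq_len(nrow(rec$pressures)) - 1L) / rec$fs
}

#' Load a recording from CSV
#'
#' Expects the header `time_s,heel,midfoot_lateral,met1,met3,met5,hallux,
#' toe2,toe5`. The time column must be strictly increasing on a uniform grid;
#' the sampling frequency is inferred from the median time step and, when a
#' declared `fs` is given, validated against it within 1%.
#'
#' @param path CSV file path.
#' @param foot_side `"left"` or `"right"`.
#' @param fs Optional declared sampling frequency (Hz) to validate against.
#' @return A `pressure_recording`.
#' @export
load_recording <- function(path, foot_side, fs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", SENSOR_SITES)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("recording CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tm <- df$time_s
  if (length(tm) < 2L) {
    fs_inf <- if (is.null(fs)) 100 else fs
  } else {
    dt <- diff(tm)
    if (any(dt <= 0)) stop("time column must be strictly increasing",
                           call. = FALSE)
    step <- stats::median(dt)
    if (max(abs(dt - step)) > 0.01 * step) {
      stop("time column is not on a uniform grid", call. = FALSE)
    }
    fs_inf <- 1 / step
  }
  if (!is.null(fs) && abs(fs_inf - fs) > 0.01 * fs) {
    stop(sprintf("inferred sampling rate %.3f Hz disagrees with declared %.3f Hz",
                 fs_inf, fs), call. = FALSE)
  }
  mat <- as.matrix(df[, SENSOR_SITES, drop = FALSE])
  if (any(mat < 0)) stop("pressures must be non-negative", call. = FALSE)
  pressure_recording(foot_side, mat, fs = fs_inf, t0 = tm[1L])
}

#' Write a recording to CSV
#'
#' Round-trip stable through [load_recording()] (values written at full
#' precision, well beyond 6 significant digits).
#'
#' @param rec A `pressure_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pressure_recording"))
  df <- data.frame(time_s = recording_times(rec), rec$pressures,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct gait events
#'
#' Detected initial-contact (heel strike) and toe-off times for one foot.
#' Each list must be strictly increasing.
#'
#' @param foot_side `"left"` or `"right"`.
#' @param initial_contacts,toe_offs Numeric vectors of event times, seconds.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(foot_side, initial_contacts, toe_offs) {
  foot_side <- match.arg(foot_side, c("left", "right"))
  ic <- as.numeric(initial_contacts); to <- as.numeric(toe_offs)
  if (is.unsorted(ic, strictly = TRUE) || is.unsorted(to, strictly = TRUE)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  structure(list(foot_side = foot_side, initial_contacts = ic,
                 toe_offs = to), class = "gait_events")
}

#' Construct stance intervals
#'
#' @param foot_side `"left"` or `"right"`.
#' @param ic_time,to_time Paired initial-contact and toe-off times (s);
#'   intervals must be sorted, disjoint, with `ic_time < to_time`.
#' @return An object of class `stance_intervals` with an `intervals` data
#'   frame (`ic_time`, `to_time`).
#' @export
stance_intervals <- function(foot_side, ic_time, to_time) {
  foot_side <- match.arg(foot_side, c("left", "right"))
  ic <- as.numeric(ic_time); to <- as.numeric(to_time)
  if (length(ic) != length(to)) stop("ic/to lengths differ", call. = FALSE)
  if (length(ic)) {
    if (any(to <= ic)) stop("each stance needs ic_time < to_time",
                            call. = FALSE)
    if (is.unsorted(ic, strictly = TRUE) ||
        any(utils::head(to, -1) > utils::tail(ic, -1))) {
      stop("stance intervals must be sorted and disjoint", call. = FALSE)
    }
  }
  structure(list(foot_side = foot_side,
                 intervals = data.frame(ic_time = ic, to_time = to)),
            class = "stance_intervals")
}

#' Read / write gait events as JSON
#'
#' Schema in `inst/schemas/events.schema.json`; ordering is preserved.
#'
#' @param ev A `gait_events` object.
#' @param path File path.
#' @export
write_events <- function(ev, path) {
  stopifnot(inherits(ev, "gait_events"))
  jsonlite::write_json(
    list(format = "gaitseg-events", version = "1.0",
         foot_side = ev$foot_side,
         initial_contacts_s = ev$initial_contacts,
         toe_offs_s = ev$toe_offs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gait_events(obj$foot_side,
              as.numeric(obj$initial_contacts_s),
              as.numeric(obj$toe_offs_s))
}

#' Read / write a gait summary as JSON
#'
#' The summary JSON carries the six report indices (each as `mean`/`sd`):
#' CoP mean velocity (cm/s), mean double-support time (s), mean cadence
#' (steps/min), and stance/swing/double-support percentages of the gait
#' cycle. Schema in `inst/schemas/summary.schema.json`.
#'
#' @param summary A `gait_summary` (see [summarize_gait()]).
#' @param path File path.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "gait_summary"))
  jsonlite::write_json(
    c(list(format = "gaitseg-summary", version = "1.0"),
      unclass(summary)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format <- NULL; obj$version <- NULL
  structure(obj, class = "gait_summary")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("<pressure_recording> %s foot: %d samples @ %g Hz (%.2f s)\n",
              x$foot_side, nrow(x$pressures), x$fs,
              nrow(x$pressures) / x$fs))
  invisible(x)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s foot: %d initial contacts, %d toe offs\n",
              x$foot_side, length(x$initial_contacts), length(x$toe_offs)))
  invisible(x)
}

#' @export
print.stance_intervals <- function(x, ...) {
  cat(sprintf("<stance_intervals> %s foot: %d stances\n",
              x$foot_side, nrow(x$intervals)))
  if (nrow(x$intervals)) print(utils::head(x$intervals, 5), row.names = FALSE)
  invisible(x)
}
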