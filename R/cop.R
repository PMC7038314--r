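#' Compute the center-of-pressure trajectory
#'
#' Per sample, the CoP is the pressure-weighted mean of the sensor
#' positions:
#' \deqn{CoP_x = \frac{\sum_i X_i P_i}{\sum_i P_i}, \qquad
#'       CoP_y = \frac{\sum_i Y_i P_i}{\sum_i P_i},}
#' where \eqn{X_i, Y_i} are the medial--lateral and anteroposterior sensor
#' coordinates and \eqn{P_i} the pressures. Samples whose total pressure
#' falls below `contact_floor` (the foot is in the air, or barely loaded)
#' have no meaningful CoP and are masked invalid rather than zero-filled.
#' Wherever valid, the CoP lies inside the layout's bounding box.
#'
#' @param rec A [pressure_recording()]; columns must match the layout.
#' @param layout A [sensor_layout()] for the same foot side.
#' @param contact_floor Total-pressure threshold in kPa below which the CoP
#'   is undefined (default 10).
#' @return An object of class `cop_trajectory`: a data frame with columns
#'   `time_s`, `cop_x`, `cop_y` (mm, `NA` where invalid), `valid`, `vel_x`,
#'   `vel_y` (mm/s, filled by [compute_cop_velocity()]), with the sampling
#'   rate and foot side as attributes.
#' @export
compute_cop <- function(rec, layout, contact_floor = 10) {
  stopifnot(inherits(rec, "pressure_recording"),
            inherits(layout, "sensor_layout"))
  if (!identical(rec$foot_side, layout$foot_side)) {
    stop("recording and layout are for different feet", call. = FALSE)
  }
  sens <- layout$sensors
  if (!identical(colnames(rec$pressures), sens$site)) {
    ord <- match(colnames(rec$pressures), sens$site)
    if (anyNA(ord)) stop("layout does not cover the recording's sensor sites",
                         call. = FALSE)
    sens <- sens[ord, ]
  }
  P <- rec$pressures
  total <- rowSums(P)
  valid <- total >= contact_floor
  cop_x <- cop_y <- rep(NA_real_, nrow(P))
  cop_x[valid] <- (P[valid, , drop = FALSE] %*% sens$x_ml) / total[valid]
  cop_y[valid] <- (P[valid, , drop = FALSE] %*% sens$y_ap) / total[valid]
  out <- data.frame(time_s = recording_times(rec),
                    cop_x = cop_x, cop_y = cop_y, valid = valid,
                    vel_x = NA_real_, vel_y = NA_real_)
  structure(out, class = c("cop_trajectory", "data.frame"),
            fs = rec$fs, foot_side = rec$foot_side,
            contact_floor = contact_floor)
}

#' Fill instantaneous CoP velocity
#'
#' First difference of consecutive CoP samples scaled by the sampling rate:
#' \deqn{Vel_{x}(T) = \frac{CoP_x(T) - CoP_x(T-1)}{1/f_s},}
#' and likewise for the anteroposterior axis (at 100 Hz the divisor is
#' 0.01 s). Velocity is undefined at the first valid sample of each contact
#' episode and wherever either of the two samples is invalid.
#'
#' @param cop A `cop_trajectory` from [compute_cop()].
#' @param fs Sampling rate, Hz; defaults to the trajectory's own.
#' @return The trajectory with `vel_x`/`vel_y` (mm/s) filled.
#' @export
compute_cop_velocity <- function(cop, fs = attr(cop, "fs")) {
  stopifnot(inherits(cop, "cop_trajectory"))
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  n <- nrow(cop)
  ok <- cop$valid & c(FALSE, cop$valid[-n])
  cop$vel_x <- cop$vel_y <- rep(NA_real_, n)
  cop$vel_x[ok] <- (cop$cop_x[ok] - cop$cop_x[which(ok) - 1L]) * fs
  cop$vel_y[ok] <- (cop$cop_y[ok] - cop$cop_y[which(ok) - 1L]) * fs
  cop
}

#' Mean CoP speed
#'
#' Mean over all defined velocity samples of the Euclidean speed
#' \eqn{\sqrt{Vel_x^2 + Vel_y^2}}, converted from mm/s to cm/s. This is the
#' scalar aggregation used for the "CoP mean velocity" report index;
#' axis-wise means are returned as attributes for users who prefer them.
#'
#' @param cop A `cop_trajectory` with velocities filled.
#' @return Mean speed in cm/s (with attributes `mean_abs_vel_x`,
#'   `mean_abs_vel_y`, cm/s); errors if no velocity sample is defined.
#' @export
mean_cop_speed <- function(cop) {
  stopifnot(inherits(cop, "cop_trajectory"))
  ok <- !is.na(cop$vel_x) & !is.na(cop$vel_y)
  if (!any(ok)) stop("no defined velocity samples", call. = FALSE)
  speed <- sqrt(cop$vel_x[ok]^2 + cop$vel_y[ok]^2) / 10
  structure(mean(speed),
            mean_abs_vel_x = mean(abs(cop$vel_x[ok])) / 10,
            mean_abs_vel_y = mean(abs(cop$vel_y[ok])) / 10)
}

# mean CoP speed (cm/s) per stance interval, over defined velocity samples
# restricted to the stance window; NA-free result, one value per stance
# that contains at least one defined sample
.stance_cop_speeds <- function(cop, stance) {
  ok <- !is.na(cop$vel_x) & !is.na(cop$vel_y)
  out <- numeric(0)
  for (i in seq_len(nrow(stance$intervals))) {
    sel <- ok & cop$time_s >= stance$intervals$ic_time[i] &
      cop$time_s < stance$intervals$to_time[i]
    if (any(sel)) {
      out <- c(out, mean(sqrt(cop$vel_x[sel]^2 + cop$vel_y[sel]^2) / 10))
    }
  }
  out
}

# fallback when no stance intervals are supplied: maximal runs of valid
# samples stand in for contact episodes
.episode_cop_speeds <- function(cop) {
  ok <- !is.na(cop$vel_x) & !is.na(cop$vel_y)
  if (!any(ok)) return(numeric(0))
  runs <- rle(cop$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- numeric(0)
  for (r in which(runs$values)) {
    sel <- starts[r]:ends[r]
    sel <- sel[ok[sel]]
    if (length(sel)) {
      out <- c(out, mean(sqrt(cop$vel_x[sel]^2 + cop$vel_y[sel]^2) / 10))
    }
  }
  out
}

#' Export a CoP trajectory as CSV
#'
#' Columns `time_s,cop_x_mm,cop_y_mm,valid,vel_x_mm_s,vel_y_mm_s`, suitable
#' for plotting CoP traces.
#'
#' @param cop A `cop_trajectory`.
#' @param path Output path.
#' @export
write_cop <- function(cop, path) {
  stopifnot(inherits(cop, "cop_trajectory"))
  df <- data.frame(time_s = cop$time_s, cop_x_mm = cop$cop_x,
                   cop_y_mm = cop$cop_y, valid = cop$valid,
                   vel_x_mm_s = cop$vel_x, vel_y_mm_s = cop$vel_y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
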