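# maximal overlap episodes of two sorted disjoint interval trains
# (data frames with ic_time/to_time); two-pointer sweep
.intersect_trains <- function(a, b) {
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$ic_time[i], b$ic_time[j])
    e <- min(a$to_time[i], b$to_time[j])
    if (e > s) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a$to_time[i] < b$to_time[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(start = out_s, end = out_e, duration = out_e - out_s)
}

# total duration of episodes clipped to [lo, hi)
.clip_total <- function(episodes, lo, hi) {
  if (!nrow(episodes)) return(0)
  sum(pmax(0, pmin(episodes$end, hi) - pmax(episodes$start, lo)))
}

#' Double-support episodes
#'
#' The maximal time intervals during which a left and a right stance phase
#' overlap, i.e. both feet are on the ground; in normal gait there are two
#' such episodes per gait cycle.
#'
#' @param stance_left,stance_right [stance_intervals()] for the two feet.
#' @return Data frame with columns `start`, `end`, `duration` (s), in
#'   chronological order; zero rows if the stances never overlap.
#' @examples
#' l <- stance_intervals("left", 0, 0.6)
#' r <- stance_intervals("right", 0.5, 1.1)
#' double_support_times(l, r)$duration  # 0.1
#' @export
double_support_times <- function(stance_left, stance_right) {
  stopifnot(inherits(stance_left, "stance_intervals"),
            inherits(stance_right, "stance_intervals"))
  .intersect_trains(stance_left$intervals, stance_right$intervals)
}

#' Build gait cycles from stance intervals
#'
#' A gait cycle runs from one initial contact to the next initial contact
#' of the same foot. The stance duration is the foot's paired stance
#' clipped to the cycle; the swing duration is the remainder, so stance +
#' swing equals the cycle duration exactly. The double-support duration of
#' a cycle is the total overlap of the two feet's stances falling inside
#' the cycle.
#'
#' @param stance_left,stance_right [stance_intervals()] for the two feet.
#' @return Data frame with one row per cycle: `foot_side`, `start`, `end`,
#'   `duration`, `stance_duration`, `swing_duration`,
#'   `double_support_duration` (all s). Empty (with a warning) if neither
#'   foot has two initial contacts.
#' @export
build_cycles <- function(stance_left, stance_right) {
  stopifnot(inherits(stance_left, "stance_intervals"),
            inherits(stance_right, "stance_intervals"))
  ds <- double_support_times(stance_left, stance_right)
  one_foot <- function(st) {
    iv <- st$intervals
    if (nrow(iv) < 2L) return(NULL)
    k <- seq_len(nrow(iv) - 1L)
    start <- iv$ic_time[k]; end <- iv$ic_time[k + 1L]
    stance <- pmin(iv$to_time[k], end) - start
    data.frame(foot_side = st$foot_side, start = start, end = end,
               duration = end - start, stance_duration = stance,
               swing_duration = (end - start) - stance,
               double_support_duration =
                 vapply(k, function(i) .clip_total(ds, start[i], end[i]),
                        numeric(1)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_foot(stance_left), one_foot(stance_right))
  if (is.null(out) || !nrow(out)) {
    warning("fewer than 2 initial contacts on both feet; no gait cycles")
    out <- data.frame(foot_side = character(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0),
                      stance_duration = numeric(0),
                      swing_duration = numeric(0),
                      double_support_duration = numeric(0))
  }
  out
}

#' Cadence
#'
#' `total_steps / test_time * 60`, in steps per minute. A step is one
#' initial contact of either foot, so both feet contribute; stride cadence
#' (cycles per minute, one foot) is half of this in symmetric gait.
#'
#' @param total_steps Number of initial contacts in the analysis window.
#' @param test_time Duration of the analysis window, s; must be positive.
#' @return Cadence in steps/min.
#' @examples
#' cadence(20, 30)  # 40 steps/min
#' @export
cadence <- function(total_steps, test_time) {
  if (!is.finite(test_time) || test_time <= 0) {
    stop("test_time must be positive", call. = FALSE)
  }
  total_steps / test_time * 60
}

#' Per-cycle phase percentages
#'
#' For each gait cycle: stance and swing time as percentages of the cycle
#' duration (the two sum to 100 exactly, by construction) and the
#' double-support time inside the cycle as a percentage of the cycle.
#'
#' @param cycles Cycle table from [build_cycles()].
#' @return The cycle table with columns `pct_stance`, `pct_swing`,
#'   `pct_double_support` appended; errors on an empty cycle table.
#' @export
phase_percentages <- function(cycles) {
  if (!nrow(cycles)) stop("no gait cycles", call. = FALSE)
  cycles$pct_stance <- cycles$stance_duration / cycles$duration * 100
  cycles$pct_swing <- 100 - cycles$pct_stance
  cycles$pct_double_support <-
    cycles$double_support_duration / cycles$duration * 100
  cycles
}

# internal constructor shared by the pipeline summary and truth_summary
new_gait_summary <- function(cop_speeds, ds_durations, cadence_overall,
                             cadence_per_cycle, pct_stance, pct_swing,
                             pct_ds, n_cycles) {
  ms <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(mean = NA_real_, sd = NA_real_))
    list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
  }
  cadence_entry <- ms(cadence_per_cycle)
  if (!is.na(cadence_overall)) cadence_entry$mean <- cadence_overall
  structure(list(
    cop_mean_velocity_cm_s = ms(cop_speeds),
    mean_double_support_time_s = ms(ds_durations),
    mean_cadence_steps_min = cadence_entry,
    pct_stance = ms(pct_stance),
    pct_swing = ms(pct_swing),
    pct_double_support = ms(pct_ds),
    n_cycles = n_cycles
  ), class = "gait_summary")
}

#' Summarize a gait analysis
#'
#' Aggregates the six report indices as mean and standard deviation:
#' CoP mean velocity (cm/s, over contact episodes of both feet), mean
#' double-support time (s, over episodes), mean cadence (steps/min; the
#' mean is the overall steps-over-time value, the SD that of the per-cycle
#' instantaneous cadence), and stance / swing / double-support percentages
#' of the gait cycle (over cycles).
#'
#' @param cycles Cycle table from [build_cycles()] (or
#'   [phase_percentages()]).
#' @param cop_left,cop_right `cop_trajectory` objects with velocities
#'   filled.
#' @param ds_times Double-support episode table from
#'   [double_support_times()].
#' @param cadence_value Overall cadence (steps/min) from [cadence()].
#' @param stance_left,stance_right Optional [stance_intervals()]; when
#'   given, CoP speeds are aggregated over stance samples only (one mean
#'   per stance), otherwise over maximal valid-contact episodes.
#' @return An object of class `gait_summary`.
#' @export
summarize_gait <- function(cycles, cop_left, cop_right, ds_times,
                           cadence_value, stance_left = NULL,
                           stance_right = NULL) {
  if (!nrow(cycles)) stop("no gait cycles to summarize", call. = FALSE)
  if (!("pct_stance" %in% names(cycles))) {
    cycles <- phase_percentages(cycles)
  }
  speeds <- if (!is.null(stance_left) && !is.null(stance_right)) {
    c(.stance_cop_speeds(cop_left, stance_left),
      .stance_cop_speeds(cop_right, stance_right))
  } else {
    c(.episode_cop_speeds(cop_left), .episode_cop_speeds(cop_right))
  }
  steps_per_cycle <- 2  # one IC per foot per cycle in alternating gait
  new_gait_summary(
    cop_speeds = speeds,
    ds_durations = ds_times$duration,
    cadence_overall = cadence_value,
    cadence_per_cycle = steps_per_cycle / cycles$duration * 60,
    pct_stance = cycles$pct_stance,
    pct_swing = cycles$pct_swing,
    pct_ds = cycles$pct_double_support,
    n_cycles = nrow(cycles)
  )
}

#' @export
print.gait_summary <- function(x, ...) {
  fmt <- function(e) if (is.na(e$mean)) "      --" else
    sprintf("%8.4f ± %.4f", e$mean, e$sd)
  cat("<gait_summary>", x$n_cycles, "gait cycles\n")
  cat("  CoP mean velocity (cm/s):   ", fmt(x$cop_mean_velocity_cm_s), "\n")
  cat("  Mean double-support time (s):", fmt(x$mean_double_support_time_s), "\n")
  cat("  Mean cadence (steps/min):   ", fmt(x$mean_cadence_steps_min), "\n")
  cat("  % stance / gait cycle:      ", fmt(x$pct_stance), "\n")
  cat("  % swing / gait cycle:       ", fmt(x$pct_swing), "\n")
  cat("  % double support / cycle:   ", fmt(x$pct_double_support), "\n")
  invisible(x)
}
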