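#' Analyze a pair of plantar-pressure recordings
#'
#' Runs the full gait-segmentation chain on synchronized left/right
#' recordings: adaptive-threshold event detection on the heel and hallux
#' channels, stance pairing, CoP trajectory and velocity, subphase
#' segmentation from the anteroposterior CoP position, gait-cycle
#' construction, double-support intersection, cadence, and the summary
#' indices.
#'
#' The cadence analysis window runs from the first detected initial contact
#' (either foot) to the last detected event, excluding quiet standing
#' before and after the walk; set `full_window = TRUE` to use the whole
#' recording instead.
#'
#' @param rec_left,rec_right [pressure_recording()]s for the two feet.
#' @param layout_left,layout_right Matching [sensor_layout()]s.
#' @param params [detector_params()].
#' @param zones [zone_boundaries()]; defaults to
#'   [default_zones()] of the left layout's foot length.
#' @param contact_floor Total-pressure floor for CoP validity, kPa.
#' @param full_window Use the full recording span as the cadence window.
#' @return A list of class `gait_analysis` with components `events_left`,
#'   `events_right`, `stance_left`, `stance_right`, `cop_left`,
#'   `cop_right`, `annotation_left`, `annotation_right`, `cycles` (with
#'   phase percentages), `double_support`, `cadence_steps_min`,
#'   `stride_cadence_cycles_min`, `test_time_s`, `summary`.
#' @examples
#' g <- generate_gait(gait_profile(n_cycles = 5, noise_sigma = 0))
#' a <- analyze_gait(g$left, g$right)
#' a$summary
#' @export
analyze_gait <- function(rec_left, rec_right,
                         layout_left = default_layout("left"),
                         layout_right = default_layout("right"),
                         params = detector_params(),
                         zones = default_zones(layout_left$foot_length),
                         contact_floor = 10,
                         full_window = FALSE) {
  ev_l <- detect_gait_events(rec_left, params)
  ev_r <- detect_gait_events(rec_right, params)
  st_l <- pair_stance_intervals(ev_l$initial_contacts, ev_l$toe_offs, "left")
  st_r <- pair_stance_intervals(ev_r$initial_contacts, ev_r$toe_offs, "right")

  cop_l <- compute_cop_velocity(compute_cop(rec_left, layout_left,
                                            contact_floor))
  cop_r <- compute_cop_velocity(compute_cop(rec_right, layout_right,
                                            contact_floor))
  ann_l <- segment_stance(cop_l, st_l, zones)
  ann_r <- segment_stance(cop_r, st_r, zones)

  cycles <- build_cycles(st_l, st_r)
  if (nrow(cycles)) cycles <- phase_percentages(cycles)
  ds <- double_support_times(st_l, st_r)

  all_ics <- sort(c(ev_l$initial_contacts, ev_r$initial_contacts))
  all_ev <- c(ev_l$initial_contacts, ev_l$toe_offs,
              ev_r$initial_contacts, ev_r$toe_offs)
  test_time <- if (full_window || length(all_ev) < 2L) {
    max(recording_times(rec_left)) - min(recording_times(rec_left))
  } else {
    max(all_ev) - min(all_ics)
  }
  cad <- if (length(all_ics) && test_time > 0) {
    cadence(length(all_ics), test_time)
  } else NA_real_

  summary <- if (nrow(cycles)) {
    summarize_gait(cycles, cop_l, cop_r, ds, cad,
                   stance_left = st_l, stance_right = st_r)
  } else NULL

  structure(list(events_left = ev_l, events_right = ev_r,
                 stance_left = st_l, stance_right = st_r,
                 cop_left = cop_l, cop_right = cop_r,
                 annotation_left = ann_l, annotation_right = ann_r,
                 cycles = cycles, double_support = ds,
                 cadence_steps_min = cad,
                 stride_cadence_cycles_min = if (is.na(cad)) NA_real_ else
                   cad / 2,
                 test_time_s = test_time,
                 summary = summary),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> %d left / %d right stances, %d cycles\n",
              nrow(x$stance_left$intervals), nrow(x$stance_right$intervals),
              nrow(x$cycles)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write synthetic gait to a directory
#'
#' Writes `left.csv`, `right.csv` (recordings), `truth.json` (true events
#' and per-cycle durations) and `profile.json` under `out_dir`.
#'
#' @param profile A [gait_profile()].
#' @param out_dir Output directory (created if missing).
#' @return The generated list from [generate_gait()], invisibly.
#' @export
simulate_to_dir <- function(profile, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- generate_gait(profile)
  write_recording(g$left, file.path(out_dir, "left.csv"))
  write_recording(g$right, file.path(out_dir, "right.csv"))
  write_profile(profile, file.path(out_dir, "profile.json"))
  tr <- g$truth
  jsonlite::write_json(
    list(format = "gaitseg-truth", version = "1.0",
         left = list(initial_contacts_s = tr$left$initial_contacts,
                     toe_offs_s = tr$left$toe_offs),
         right = list(initial_contacts_s = tr$right$initial_contacts,
                      toe_offs_s = tr$right$toe_offs),
         cycles = tr$cycles),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(g)
}

# --- config handling -------------------------------------------------------

#' Default analysis configuration
#'
#' The layered configuration consumed by [run_pipeline()] and the command
#' line: detector parameters, CoP contact floor, zone cuts and foot length.
#' Schema in `inst/schemas/config.schema.json`.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    detector = list(window = 1.5, refractory = 0.3, min_amplitude = 20),
    contact_floor = 10,
    foot_length = 260,
    zone_fractions = c(0.25, 0.45, 0.70),
    full_window = FALSE
  )
}

#' Validate an analysis configuration
#'
#' Structural validation against the shipped schema: unknown keys, missing
#' types and out-of-range values are reported with the offending field
#' path.
#'
#' @param config Nested list (e.g. parsed from JSON).
#' @return The merged (defaults < config) configuration, invisibly valid.
#' @export
validate_config <- function(config) {
  base <- default_config()
  bad_key <- setdiff(names(config), names(base))
  if (length(bad_key)) {
    stop("unknown config field(s): ", paste(bad_key, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$detector)) {
    bad <- setdiff(names(config$detector), names(base$detector))
    if (length(bad)) {
      stop("unknown config field(s): ",
           paste0("detector.", bad, collapse = ", "), call. = FALSE)
    }
    base$detector[names(config$detector)] <- config$detector
  }
  for (k in setdiff(names(config), "detector")) base[[k]] <- config[[k]]
  chk_num <- function(x, path, lo = 0) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo) {
      stop("config field '", path, "' must be a number >= ", lo,
           call. = FALSE)
    }
  }
  chk_num(base$detector$window, "detector.window", lo = 1e-9)
  chk_num(base$detector$refractory, "detector.refractory")
  chk_num(base$detector$min_amplitude, "detector.min_amplitude")
  chk_num(base$contact_floor, "contact_floor")
  chk_num(base$foot_length, "foot_length", lo = 1e-9)
  zf <- base$zone_fractions
  if (!is.numeric(zf) || length(zf) != 3L ||
      is.unsorted(zf, strictly = TRUE) || zf[1] <= 0 || zf[3] >= 1) {
    stop("config field 'zone_fractions' must be 3 increasing fractions in (0,1)",
         call. = FALSE)
  }
  if (!is.logical(base$full_window) || length(base$full_window) != 1L) {
    stop("config field 'full_window' must be TRUE or FALSE", call. = FALSE)
  }
  base
}

#' Run the analysis pipeline from files
#'
#' Loads two recording CSVs and an optional layout/config, runs
#' [analyze_gait()], and writes events, annotations, the per-cycle table,
#' the gait summary and a run manifest (package version, parameters, input
#' MD5 hashes) under `out_dir`. Deterministic given identical inputs and
#' configuration.
#'
#' @param left,right Paths to the left/right recording CSVs.
#' @param out_dir Output directory.
#' @param layout Optional path to a layout JSON (both feet); defaults to
#'   the built-in EU 41 layout.
#' @param config Optional path to a config JSON, or a config list.
#' @return The `gait_analysis`, invisibly.
#' @export
run_pipeline <- function(left, right, out_dir, layout = NULL,
                         config = list()) {
  for (f in c(left, right)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- validate_config(config)
  if (is.null(layout)) {
    lay_l <- default_layout("left", cfg$foot_length)
    lay_r <- default_layout("right", cfg$foot_length)
  } else {
    lays <- read_layout(layout)
    lay_l <- lays$left; lay_r <- lays$right
  }
  rec_l <- load_recording(left, "left")
  rec_r <- load_recording(right, "right")
  res <- analyze_gait(
    rec_l, rec_r, lay_l, lay_r,
    params = detector_params(cfg$detector$window, cfg$detector$refractory,
                             cfg$detector$min_amplitude),
    zones = zone_boundaries(cfg$zone_fractions * lay_l$foot_length,
                            lay_l$foot_length),
    contact_floor = cfg$contact_floor,
    full_window = cfg$full_window)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events(res$events_left, file.path(out_dir, "events_left.json"))
  write_events(res$events_right, file.path(out_dir, "events_right.json"))
  write_annotation(res$annotation_left,
                   file.path(out_dir, "annotation_left.json"))
  write_annotation(res$annotation_right,
                   file.path(out_dir, "annotation_right.json"))
  utils::write.csv(res$cycles, file.path(out_dir, "cycles.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(res$summary)) {
    write_summary(res$summary, file.path(out_dir, "summary.json"))
  }
  manifest <- list(
    format = "gaitseg-manifest", version = "1.0",
    package_version = as.character(utils::packageVersion("gaitseg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg,
    inputs = list(
      left = list(path = left, md5 = unname(tools::md5sum(left))),
      right = list(path = right, md5 = unname(tools::md5sum(right)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
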