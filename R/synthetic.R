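#' Default per-sensor activation waveform table
#'
#' One row per sensor site: the activation window (`start`, `end`, as
#' fractions of the stance phase), the half-cosine attack and release ramp
#' durations (same units), and the plateau pressure in kPa. The heel has a
#' near-instant attack so that its half-range threshold crossing coincides
#' with the true initial contact; every sensor that stays loaded to the end
#' of stance (metatarsal heads, hallux, toes) shares the same sharp release
#' ending exactly at toe off, which keeps the late-stance center of pressure
#' stationary and pins the hallux threshold crossing to the true toe off.
#' Peak pressures lie inside the 0--1200 kPa range over which insole sensors
#' of this class are characterized.
#'
#' @return Data frame with columns `site`, `start`, `end`, `attack`,
#'   `release`, `peak`.
#' @export
default_sensor_waveforms <- function() {
  data.frame(
    site    = c("heel", "midfoot_lateral", "met5", "met3", "met1",
                "hallux", "toe2", "toe5"),
    start   = c(0.00, 0.08, 0.20, 0.25, 0.30, 0.40, 0.50, 0.50),
    end     = c(0.55, 0.62, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    attack  = c(0.008, 0.20, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25),
    release = c(0.30, 0.20, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    peak    = c(900, 400, 550, 650, 700, 600, 350, 250),
    stringsAsFactors = FALSE
  )
}

#' Construct a synthetic gait profile
#'
#' Parameters of the synthetic two-foot walking model: strictly periodic
#' gait cycles, a stance phase occupying `stance_fraction` of each cycle
#' (healthy-adult default 0.60), heel-to-toe pressure progression encoded by
#' per-sensor activation windows, and the feet in anti-phase
#' (`phase_offset = 0.5` cycles).
#'
#' @param cycle_duration Gait cycle duration, s (default 1.05).
#' @param stance_fraction Fraction of the cycle spent in stance (default 0.60).
#' @param subphase_fractions Named fractions of stance for the four stance
#'   subphases `ICP`, `FFCP`, `FFP`, `FFPOP`; positive, summing to 1
#'   (defaults 0.15/0.20/0.35/0.30).
#' @param waveforms Per-sensor activation table, see
#'   [default_sensor_waveforms()].
#' @param phase_offset Right-foot lag as a fraction of the cycle (default 0.5).
#' @param noise_sigma Additive Gaussian sensor noise, kPa, truncated at 0
#'   (default 5).
#' @param n_cycles Number of gait cycles per foot (default 30).
#' @param fs Sampling frequency, Hz (default 100).
#' @param lead_in,tail Quiet time before the first initial contact and after
#'   the last toe off, s.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(cycle_duration = 1.05, stance_fraction = 0.60,
                         subphase_fractions = c(ICP = 0.15, FFCP = 0.20,
                                                FFP = 0.35, FFPOP = 0.30),
                         waveforms = default_sensor_waveforms(),
                         phase_offset = 0.5, noise_sigma = 5,
                         n_cycles = 30, fs = 100,
                         lead_in = 0.6, tail = 0.4, seed = 1L) {
  if (!is.finite(cycle_duration) || cycle_duration <= 0) {
    stop("cycle_duration must be positive", call. = FALSE)
  }
  if (!(stance_fraction > 0 && stance_fraction < 1)) {
    stop("stance_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  sf <- subphase_fractions
  if (length(sf) != 4L || any(sf <= 0) || abs(sum(sf) - 1) > 1e-9) {
    stop("subphase_fractions must be 4 positive values summing to 1",
         call. = FALSE)
  }
  names(sf) <- c("ICP", "FFCP", "FFP", "FFPOP")
  .validate_waveforms(waveforms)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!(phase_offset >= 0 && phase_offset < 1)) {
    stop("phase_offset must lie in [0, 1)", call. = FALSE)
  }
  structure(list(cycle_duration = cycle_duration,
                 stance_fraction = stance_fraction,
                 subphase_fractions = sf,
                 waveforms = waveforms,
                 phase_offset = phase_offset,
                 noise_sigma = noise_sigma,
                 n_cycles = as.integer(n_cycles), fs = fs,
                 lead_in = lead_in, tail = tail,
                 seed = as.integer(seed)),
            class = "gait_profile")
}

.validate_waveforms <- function(w) {
  need <- c("site", "start", "end", "attack", "release", "peak")
  if (!is.data.frame(w) || !all(need %in% names(w)) ||
      !setequal(w$site, SENSOR_SITES)) {
    stop("waveforms must be a data frame covering the 8 sensor sites",
         call. = FALSE)
  }
  bad <- w$start < 0 | w$end > 1 | w$start >= w$end
  if (any(bad)) {
    stop("activation window for ", paste(w$site[bad], collapse = ", "),
         " must satisfy 0 <= start < end <= 1 (fractions of stance)",
         call. = FALSE)
  }
  if (any(w$attack <= 0 | w$release <= 0 |
          w$attack + w$release > w$end - w$start)) {
    stop("attack/release ramps must be positive and fit inside the window",
         call. = FALSE)
  }
  if (any(w$peak < 0 | w$peak > 1200)) {
    stop("peak pressures must lie in [0, 1200] kPa", call. = FALSE)
  }
  invisible(w)
}

# Generalized raised-cosine (Tukey-style) pulse evaluated at stance
# fractions f: half-cosine attack over [w0, w0+attack], plateau, half-cosine
# release over [w1-release, w1]; exactly 0 outside (w0, w1).
.tukey_pulse <- function(f, w0, w1, attack, release) {
  v <- numeric(length(f))
  inside <- f > w0 & f < w1
  fi <- f[inside]
  vi <- rep(1, length(fi))
  a <- fi < w0 + attack
  vi[a] <- 0.5 * (1 - cos(pi * (fi[a] - w0) / attack))
  r <- fi > w1 - release
  vi[r] <- pmin(vi[r], 0.5 * (1 + cos(pi * (fi[r] - (w1 - release)) / release)))
  v[inside] <- vi
  v
}

#' Generate synthetic two-foot gait recordings with ground truth
#'
#' Simulates cyclic walking: each foot's stance runs from a true initial
#' contact to a true toe off; within stance every sensor traces a smooth
#' unimodal raised-cosine pulse inside its activation window and is exactly
#' zero during swing. Additive Gaussian noise (truncated at 0 kPa) is applied
#' after the noiseless waveform is built, so ground-truth event times are
#' unaffected by noise.
#'
#' @param profile A [gait_profile()].
#' @param layout_left,layout_right Sensor layouts; defaults mirror EU 41.
#' @return A list with components `left` and `right`
#'   ([pressure_recording()]s) and `truth` (a `ground_truth` object holding
#'   per-foot true IC/TO times, per-sample true phase labels, and per-cycle
#'   true stance/swing/double-support durations).
#' @examples
#' g <- generate_gait(gait_profile(n_cycles = 3, noise_sigma = 0))
#' g$truth$left$initial_contacts
#' @export
generate_gait <- function(profile,
                          layout_left = default_layout("left"),
                          layout_right = default_layout("right")) {
  stopifnot(inherits(profile, "gait_profile"))
  p <- profile
  cyc <- p$cycle_duration
  st <- p$stance_fraction * cyc
  ic_left <- p$lead_in + (seq_len(p$n_cycles) - 1L) * cyc
  ic_right <- ic_left + p$phase_offset * cyc
  last_event <- max(ic_left, ic_right) + st
  n_samp <- ceiling((last_event + p$tail) * p$fs) + 1L
  times <- (seq_len(n_samp) - 1L) / p$fs

  set.seed(p$seed)
  build_foot <- function(ics, side) {
    mat <- matrix(0, n_samp, 8L, dimnames = list(NULL, SENSOR_SITES))
    w <- p$waveforms
    for (k in seq_along(ics)) {
      f <- (times - ics[k]) / st      # stance fraction; <0 before IC
      live <- which(f > 0 & f < 1)
      if (!length(live)) next
      for (j in seq_len(nrow(w))) {
        mat[live, w$site[j]] <- mat[live, w$site[j]] +
          w$peak[j] * .tukey_pulse(f[live], w$start[j], w$end[j],
                                   w$attack[j], w$release[j])
      }
    }
    if (p$noise_sigma > 0) {
      mat <- pmax(mat + matrix(stats::rnorm(length(mat), 0, p$noise_sigma),
                               nrow(mat)), 0)
    }
    pressure_recording(side, mat, fs = p$fs, t0 = 0)
  }
  rec_left <- build_foot(ic_left, "left")
  rec_right <- build_foot(ic_right, "right")

  truth <- .build_ground_truth(p, times, ic_left, ic_right)
  list(left = rec_left, right = rec_right, truth = truth)
}

.phase_levels <- c("SWING", "ICP", "FFCP", "FFP", "FFPOP")

.build_ground_truth <- function(p, times, ic_left, ic_right) {
  cyc <- p$cycle_duration
  st <- p$stance_fraction * cyc
  label_foot <- function(ics) {
    lab <- factor(rep("SWING", length(times)), levels = .phase_levels)
    bounds <- c(0, cumsum(p$subphase_fractions)) * st
    for (ic in ics) {
      in_st <- times >= ic & times < ic + st
      z <- findInterval(times[in_st] - ic, bounds,
                        rightmost.closed = FALSE)
      z <- pmin(pmax(z, 1L), 4L)
      lab[in_st] <- .phase_levels[z + 1L]
    }
    lab
  }
  st_left <- stance_intervals("left", ic_left, ic_left + st)
  st_right <- stance_intervals("right", ic_right, ic_right + st)
  ds_all <- .intersect_trains(st_left$intervals, st_right$intervals)
  cycles <- do.call(rbind, lapply(list(list(ic_left, "left"),
                                       list(ic_right, "right")),
    function(x) {
      ics <- x[[1]]
      data.frame(foot_side = x[[2]], start = ics, end = ics + cyc,
                 duration = cyc, stance_duration = st,
                 swing_duration = cyc - st,
                 double_support_duration =
                   vapply(ics, function(s)
                     .clip_total(ds_all, s, s + cyc), numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  structure(list(
    profile = p, times = times,
    left = list(initial_contacts = ic_left, toe_offs = ic_left + st,
                labels = label_foot(ic_left)),
    right = list(initial_contacts = ic_right, toe_offs = ic_right + st,
                 labels = label_foot(ic_right)),
    stance_left = st_left, stance_right = st_right,
    double_support = ds_all, cycles = cycles
  ), class = "ground_truth")
}

#' Reference gait summary computed from ground truth
#'
#' Computes the report indices directly from the generator's true intervals,
#' bypassing event detection entirely; used as the oracle in recovery tests.
#' CoP mean velocity is reported as `NA`: it depends on the pressure field,
#' not on event times alone.
#'
#' @param gt A `ground_truth` object from [generate_gait()].
#' @return A `gait_summary`.
#' @export
truth_summary <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  cyc <- gt$cycles
  if (!nrow(cyc)) stop("empty ground truth", call. = FALSE)
  # alternating gait places exactly 2 initial contacts in every cycle, so
  # the true cadence is steps over walking time: 2 n / (n T) * 60 = 120 / T
  cad_per_cycle <- 2 / cyc$duration * 60
  p <- gt$profile
  cadence_true <- (2 * p$n_cycles) / (p$n_cycles * p$cycle_duration) * 60
  pct_stance <- cyc$stance_duration / cyc$duration * 100
  new_gait_summary(
    cop_speeds = NA_real_,
    ds_durations = gt$double_support$duration,
    cadence_overall = cadence_true,
    cadence_per_cycle = cad_per_cycle,
    pct_stance = pct_stance,
    pct_swing = 100 - pct_stance,
    pct_ds = cyc$double_support_duration / cyc$duration * 100,
    n_cycles = nrow(cyc)
  )
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(paste0("<gait_profile> %d cycles of %.3f s (stance %.0f%%), ",
                     "fs %g Hz, noise %g kPa, seed %d\n"),
              x$n_cycles, x$cycle_duration, 100 * x$stance_fraction,
              x$fs, x$noise_sigma, x$seed))
  invisible(x)
}

#' Read / write gait profiles as JSON
#'
#' @param profile A `gait_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gait_profile"))
  obj <- unclass(profile)
  obj$subphase_fractions <- as.list(obj$subphase_fractions)
  jsonlite::write_json(c(list(format = "gaitseg-profile", version = "1.0"),
                         obj),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gait_profile(cycle_duration = obj$cycle_duration,
               stance_fraction = obj$stance_fraction,
               subphase_fractions = unlist(obj$subphase_fractions),
               waveforms = as.data.frame(obj$waveforms,
                                         stringsAsFactors = FALSE),
               phase_offset = obj$phase_offset,
               noise_sigma = obj$noise_sigma,
               n_cycles = obj$n_cycles, fs = obj$fs,
               lead_in = obj$lead_in, tail = obj$tail, seed = obj$seed)
}
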