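test_that("noiseless pressures are zero outside each sensor's activation window", {
  p <- gait_profile(n_cycles = 3, noise_sigma = 0, seed = 4)
  g <- generate_gait(p)
  st <- p$stance_fraction * p$cycle_duration
  for (foot in c("left", "right")) {
    rec <- g[[foot]]
    truth <- g$truth[[foot]]
    t <- recording_times(rec)
    # stance fraction at each sample relative to the nearest preceding IC
    frac <- rep(-1, length(t))
    for (ic in truth$initial_contacts) {
      in_st <- t >= ic & t < ic + st
      frac[in_st] <- (t[in_st] - ic) / st
    }
    for (j in seq_len(nrow(p$waveforms))) {
      w <- p$waveforms[j, ]
      outside <- frac < w$start | frac > w$end
      expect_true(all(rec$pressures[outside, w$site] == 0),
                  label = paste(foot, w$site, "zero outside window"))
      expect_true(any(rec$pressures[!outside, w$site] > 0.5 * w$peak),
                  label = paste(foot, w$site, "pulse reaches near peak"))
    }
    # swing is exactly silent
    expect_true(all(rec$pressures[frac < 0, ] == 0))
  }
})

test_that("the generator is deterministic under a fixed seed", {
  p <- gait_profile(n_cycles = 3, noise_sigma = 5, seed = 99)
  g1 <- generate_gait(p)
  g2 <- generate_gait(p)
  expect_identical(g1$left$pressures, g2$left$pressures)
  expect_identical(g1$right$pressures, g2$right$pressures)
  g3 <- generate_gait(gait_profile(n_cycles = 3, noise_sigma = 5, seed = 100))
  expect_false(identical(g1$left$pressures, g3$left$pressures))
})

test_that("n_cycles controls the exact number of true events per foot", {
  g <- generate_gait(gait_profile(n_cycles = 10, noise_sigma = 0, seed = 1))
  for (foot in c("left", "right")) {
    expect_length(g$truth[[foot]]$initial_contacts, 10)
    expect_length(g$truth[[foot]]$toe_offs, 10)
    expect_true(all(g$truth[[foot]]$toe_offs >
                      g$truth[[foot]]$initial_contacts))
  }
})

test_that("adding noise leaves the stored ground truth untouched", {
  p0 <- gait_profile(n_cycles = 5, noise_sigma = 0, seed = 3)
  p5 <- gait_profile(n_cycles = 5, noise_sigma = 5, seed = 3)
  t0 <- generate_gait(p0)$truth
  t5 <- generate_gait(p5)$truth
  expect_identical(t0$left$initial_contacts, t5$left$initial_contacts)
  expect_identical(t0$right$toe_offs, t5$right$toe_offs)
  expect_identical(t0$cycles, t5$cycles)
})

test_that("truth_summary recovers the profile's phase split exactly", {
  g <- generate_gait(gait_profile(n_cycles = 6, noise_sigma = 0, seed = 1))
  ts <- truth_summary(g$truth)
  expect_equal(ts$pct_stance$mean, 60)
  expect_equal(ts$pct_stance$sd, 0)
  expect_equal(ts$pct_swing$mean, 40)
})

test_that("truth double support and cadence match brute-force interval oracles", {
  # cycle 1.0 s, stance 0.6, anti-phase feet: per-cycle double support 0.2 s,
  # cadence 120 steps/min
  p <- gait_profile(cycle_duration = 1.0, stance_fraction = 0.6,
                    phase_offset = 0.5, n_cycles = 6, noise_sigma = 0,
                    seed = 1)
  g <- generate_gait(p)
  tr <- g$truth
  ts <- truth_summary(tr)

  orc <- oracle_overlaps(tr$stance_left$intervals, tr$stance_right$intervals)
  expect_equal(tr$double_support$start, orc$start)
  expect_equal(tr$double_support$duration, orc$duration)

  per_cycle_ds <- vapply(seq_len(nrow(tr$cycles)), function(i) {
    sum(pmax(0, pmin(orc$end, tr$cycles$end[i]) -
               pmax(orc$start, tr$cycles$start[i])))
  }, numeric(1))
  expect_equal(tr$cycles$double_support_duration, per_cycle_ds)
  # every interior cycle carries the full 2 x 0.1 s of double support; only
  # the first left and last right cycle lack a contralateral neighbour
  expect_equal(max(per_cycle_ds), 0.2, tolerance = 1e-9)
  expect_gte(sum(abs(per_cycle_ds - 0.2) < 1e-9), nrow(tr$cycles) - 2)

  # Eq. 5 applied to the true events: 2 ICs per 1 s cycle
  expect_equal(ts$mean_cadence_steps_min$mean, 120, tolerance = 1e-9)
})

test_that("noiseless CoP advances monotonically through all four zones", {
  g <- generate_gait(gait_profile(n_cycles = 5, noise_sigma = 0, seed = 8))
  zones <- default_zones()
  for (foot in c("left", "right")) {
    layout <- default_layout(foot)
    cop <- compute_cop(g[[foot]], layout)
    truth <- g$truth[[foot]]
    seen <- integer(0)
    for (i in seq_along(truth$initial_contacts)) {
      idx <- which(cop$time_s >= truth$initial_contacts[i] &
                     cop$time_s < truth$toe_offs[i] & cop$valid)
      y <- cop$cop_y[idx]
      expect_true(all(diff(y) >= -1e-9),
                  label = paste(foot, "stance", i, "cop_y non-decreasing"))
      seen <- union(seen, unique(findInterval(y, zones$cuts)))
    }
    expect_setequal(seen, 0:3)  # all four anteroposterior zones visited
  }
})

test_that("profile validation rejects inconsistent configurations", {
  expect_error(gait_profile(stance_fraction = 1.2), "stance_fraction")
  expect_error(gait_profile(subphase_fractions = c(0.5, 0.5, 0.1, 0.1)),
               "summing to 1")
  w <- default_sensor_waveforms()
  w$end[w$site == "heel"] <- 1.4
  expect_error(gait_profile(waveforms = w), "activation window")
  w2 <- default_sensor_waveforms()
  w2$peak[1] <- 1500
  expect_error(gait_profile(waveforms = w2), "1200")
  expect_error(gait_profile(n_cycles = 0), "n_cycles")
})

test_that("profiles round-trip through JSON", {
  p <- gait_profile(cycle_duration = 0.9, n_cycles = 4, noise_sigma = 2,
                    seed = 42)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_profile(p, tmp)
  expect_equal(read_profile(tmp), p)
})
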