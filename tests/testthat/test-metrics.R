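test_that("gait cycles split into stance and swing that sum to the cycle", {
  st_l <- stance_intervals("left", c(0, 1), c(0.6, 1.6))
  st_r <- stance_intervals("right", numeric(0), numeric(0))
  cyc <- build_cycles(st_l, st_r)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$stance_duration, 0.6)
  expect_equal(cyc$swing_duration, 0.4)
  expect_equal(cyc$stance_duration + cyc$swing_duration, cyc$duration)

  # a single IC cannot form a cycle
  expect_warning(
    empty <- build_cycles(stance_intervals("left", 0, 0.6), st_r),
    "fewer than 2")
  expect_equal(nrow(empty), 0)
})

test_that("cycles built from true stance trains match the ground truth", {
  g <- generate_gait(gait_profile(n_cycles = 10, noise_sigma = 0, seed = 2))
  tr <- g$truth
  cyc <- build_cycles(tr$stance_left, tr$stance_right)
  expect_equal(nrow(cyc), 18)  # 9 full IC-to-IC cycles per foot
  for (foot in c("left", "right")) {
    got <- cyc[cyc$foot_side == foot, ]
    want <- tr$cycles[tr$cycles$foot_side == foot, ][seq_len(nrow(got)), ]
    expect_equal(got$start, want$start)
    expect_equal(got$duration, want$duration)
    expect_equal(got$stance_duration, want$stance_duration)
    expect_equal(got$swing_duration, want$swing_duration)
    expect_equal(got$double_support_duration, want$double_support_duration)
  }
})

test_that("double support is the intersection of the two stance trains", {
  l <- stance_intervals("left", 0, 0.6)
  r <- stance_intervals("right", 0.5, 1.1)
  ds <- double_support_times(l, r)
  expect_equal(ds$duration, 0.1, tolerance = 1e-12)
  expect_equal(ds$start, 0.5)

  # disjoint stances never overlap
  ds0 <- double_support_times(stance_intervals("left", 0, 0.4),
                              stance_intervals("right", 0.5, 0.9))
  expect_equal(nrow(ds0), 0)
})

test_that("double support equals the O(n^2) sweep and is symmetric in feet", {
  set.seed(41)
  for (rep in 1:20) {
    a <- random_stance_train(sample(3:10, 1))
    b <- random_stance_train(sample(3:10, 1), start = runif(1, 0, 1))
    sl <- stance_intervals("left", a$ic_time, a$to_time)
    sr <- stance_intervals("right", b$ic_time, b$to_time)
    got <- double_support_times(sl, sr)
    want <- oracle_overlaps(a, b)
    expect_equal(got, want)
    flipped <- double_support_times(
      stance_intervals("left", b$ic_time, b$to_time),
      stance_intervals("right", a$ic_time, a$to_time))
    expect_equal(sum(got$duration), sum(flipped$duration))
  }
})

test_that("cadence follows steps over time normalized to a minute", {
  expect_equal(cadence(20, 30), 40)
  expect_equal(cadence(0, 30), 0)
  expect_equal(cadence(13, 11.7), 13 / 11.7 * 60)
  expect_error(cadence(10, 0), "positive")
  expect_error(cadence(10, -5), "positive")
})

test_that("phase percentages sum to 100 per cycle by construction", {
  st_l <- stance_intervals("left", c(0, 1), c(0.6, 1.6))
  st_r <- stance_intervals("right", c(0.5, 1.5), c(1.1, 2.1))
  cyc <- phase_percentages(build_cycles(st_l, st_r))
  expect_equal(cyc$pct_stance[1], 60)
  expect_equal(cyc$pct_swing[1], 40)
  expect_true(all(cyc$pct_stance + cyc$pct_swing == 100))

  # degenerate: stance fills the whole cycle
  full <- phase_percentages(build_cycles(
    stance_intervals("left", c(0, 1), c(1, 2.2)),
    stance_intervals("right", numeric(0), numeric(0))))
  expect_equal(full$pct_stance, 100)
  expect_equal(full$pct_swing, 0)

  empty <- suppressWarnings(build_cycles(
    stance_intervals("left", numeric(0), numeric(0)),
    stance_intervals("right", numeric(0), numeric(0))))
  expect_error(phase_percentages(empty), "no gait cycles")
})

test_that("truth-bypassed percentages equal the truth summary exactly", {
  g <- generate_gait(gait_profile(n_cycles = 8, noise_sigma = 0, seed = 5))
  tr <- g$truth
  cyc <- phase_percentages(build_cycles(tr$stance_left, tr$stance_right))
  ts <- truth_summary(tr)
  expect_equal(mean(cyc$pct_stance), ts$pct_stance$mean)
  expect_equal(mean(cyc$pct_swing), ts$pct_swing$mean)
  # per-cycle double-support percentages match the truth table row by row
  # (build_cycles drops the last IC-to-IC cycle of each foot)
  for (foot in c("left", "right")) {
    got <- cyc[cyc$foot_side == foot, ]
    want <- tr$cycles[tr$cycles$foot_side == foot, ][seq_len(nrow(got)), ]
    expect_equal(got$pct_double_support,
                 want$double_support_duration / want$duration * 100,
                 tolerance = 1e-9)
  }
})

test_that("a single-cycle summary has zero dispersion", {
  st_l <- stance_intervals("left", c(0, 1.05), c(0.63, 1.68))
  st_r <- stance_intervals("right", 0.525, 1.155)
  cyc <- build_cycles(st_l, st_r)
  ds <- double_support_times(st_l, st_r)
  cop <- compute_cop_velocity(make_cop(rep(0, 200), seq(30, 229)))
  s <- summarize_gait(cyc, cop, cop, ds, cadence_value = 114)
  expect_s3_class(s, "gait_summary")
  expect_equal(s$pct_stance$sd, 0)
  expect_equal(s$pct_swing$sd, 0)
  expect_equal(s$mean_cadence_steps_min$mean, 114)
  expect_true(all(vapply(
    s[c("cop_mean_velocity_cm_s", "mean_double_support_time_s",
        "pct_stance", "pct_swing", "pct_double_support")],
    function(e) e$sd >= 0, logical(1))))
})
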