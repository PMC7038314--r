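one_frame_rec <- function(p, side = "left", n = 1) {
  mat <- matrix(rep(p, each = n), n, 8, dimnames = list(NULL, SENSOR_SITES))
  pressure_recording(side, mat)
}

test_that("single-sensor support puts the CoP on that sensor", {
  layout <- default_layout("left")
  for (j in 1:8) {
    p <- rep(0, 8); p[j] <- 300
    cop <- compute_cop(one_frame_rec(p), layout)
    expect_equal(cop$cop_x, layout$sensors$x_ml[j])
    expect_equal(cop$cop_y, layout$sensors$y_ap[j])
  }
})

test_that("equal load on two sensors lands midway between them", {
  # heel at y = 30 mm, hallux at y = 230 mm
  f <- default_layout("left")
  y <- f$sensors$y_ap; y[f$sensors$site == "heel"] <- 30
  y[f$sensors$site == "hallux"] <- 230
  y[f$sensors$site %in% c("toe2", "toe5")] <- 230
  layout <- sensor_layout("left", f$sensors$x_ml, y, sites = f$sensors$site)
  p <- c(heel = 100, midfoot_lateral = 0, met1 = 0, met3 = 0, met5 = 0,
         hallux = 100, toe2 = 0, toe5 = 0)
  cop <- compute_cop(one_frame_rec(p), layout)
  expect_equal(cop$cop_y, 130)
})

test_that("CoP equals the brute-force weighted-mean oracle", {
  layout <- default_layout("right")
  # the 1..8 kPa frame of the worked example
  cop <- compute_cop(one_frame_rec(1:8, "right"), layout)
  orc <- oracle_cop(matrix(1:8, 1), layout$sensors$x_ml, layout$sensors$y_ap)
  expect_equal(cop$cop_x, orc[1, 1], tolerance = 1e-12)
  expect_equal(cop$cop_y, orc[1, 2], tolerance = 1e-12)

  set.seed(5)
  P <- matrix(runif(200 * 8, 0, 900), 200, 8,
              dimnames = list(NULL, SENSOR_SITES))
  rec <- pressure_recording("right", P)
  cop <- compute_cop(rec, layout)
  orc <- oracle_cop(P, layout$sensors$x_ml, layout$sensors$y_ap)
  expect_equal(cop$cop_x, orc[, 1], tolerance = 1e-12)
  expect_equal(cop$cop_y, orc[, 2], tolerance = 1e-12)
})

test_that("CoP is invariant to uniform pressure scaling and stays in the bounding box", {
  set.seed(6)
  layout <- default_layout("left")
  P <- matrix(runif(50 * 8, 1, 500), 50, 8,
              dimnames = list(NULL, SENSOR_SITES))
  c1 <- compute_cop(pressure_recording("left", P), layout)
  c2 <- compute_cop(pressure_recording("left", P * 7.3), layout)
  expect_equal(c1$cop_x, c2$cop_x, tolerance = 1e-12)
  expect_equal(c1$cop_y, c2$cop_y, tolerance = 1e-12)
  expect_true(all(c1$cop_x >= min(layout$sensors$x_ml) - 1e-9 &
                    c1$cop_x <= max(layout$sensors$x_ml) + 1e-9))
  expect_true(all(c1$cop_y >= min(layout$sensors$y_ap) - 1e-9 &
                    c1$cop_y <= max(layout$sensors$y_ap) + 1e-9))
})

test_that("CoP is invariant to a consistent permutation of the sensor order", {
  set.seed(7)
  layout <- default_layout("left")
  P <- matrix(runif(20 * 8, 0, 500), 20, 8,
              dimnames = list(NULL, SENSOR_SITES))
  perm <- sample(8)
  Pp <- P[, perm]
  colnames(Pp) <- SENSOR_SITES[perm]
  c1 <- compute_cop(pressure_recording("left", P), layout)
  c2 <- compute_cop(pressure_recording("left", Pp), layout)
  expect_equal(c1$cop_x, c2$cop_x)
  expect_equal(c1$cop_y, c2$cop_y)
})

test_that("samples below the contact floor are masked, not zero-filled", {
  layout <- default_layout("left")
  P <- matrix(0, 4, 8, dimnames = list(NULL, SENSOR_SITES))
  P[2, "heel"] <- 100
  P[3, "heel"] <- 5   # below the 10 kPa floor
  cop <- compute_cop(pressure_recording("left", P), layout)
  expect_equal(cop$valid, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(cop$cop_y[!cop$valid])))
})

test_that("CoP velocity is the first difference scaled by fs", {
  # constant trajectory: zero velocity wherever defined
  cop <- compute_cop_velocity(make_cop(rep(3, 30), rep(40, 30)))
  expect_true(all(cop$vel_x[-1] == 0) && all(cop$vel_y[-1] == 0))
  expect_true(is.na(cop$vel_x[1]))

  # 1 mm/sample anteroposterior ramp at 100 Hz -> 100 mm/s
  cop <- compute_cop_velocity(make_cop(rep(0, 50), seq(10, 59)))
  expect_true(all(cop$vel_y[-1] == 100))

  # random trajectory vs finite-difference loop
  set.seed(8)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  cop <- compute_cop_velocity(make_cop(x, y, fs = 250), fs = 250)
  want <- vapply(2:100, function(i) (y[i] - y[i - 1]) * 250, numeric(1))
  expect_equal(cop$vel_y[-1], want, tolerance = 1e-12)

  # velocity undefined at the first valid sample of each contact episode
  valid <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  cop <- compute_cop_velocity(make_cop(1:5, 1:5, valid))
  expect_true(is.na(cop$vel_y[4]) && !is.na(cop$vel_y[5]))
  expect_true(is.na(cop$vel_y[3]))
})

test_that("mean CoP speed aggregates Euclidean speeds in cm/s", {
  expect_equal(as.numeric(mean_cop_speed(
    compute_cop_velocity(make_cop(rep(0, 40), rep(7, 40))))), 0)

  v <- mean_cop_speed(compute_cop_velocity(make_cop(rep(0, 60), seq(0, 59))))
  expect_equal(as.numeric(v), 10)

  set.seed(9)
  x <- cumsum(rnorm(80)); y <- cumsum(rnorm(80))
  v <- mean_cop_speed(compute_cop_velocity(make_cop(x, y)))
  orc <- mean(sqrt(diff(x)^2 + diff(y)^2) * 100 / 10)
  expect_equal(as.numeric(v), orc, tolerance = 1e-12)

  expect_error(mean_cop_speed(make_cop(1:5, 1:5, rep(FALSE, 5))),
               "no defined velocity")
})

test_that("recording/layout mismatches raise config errors", {
  rec <- one_frame_rec(rep(10, 8), "left")
  expect_error(compute_cop(rec, default_layout("right")), "different feet")
})
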