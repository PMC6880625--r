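test_that("time normalization yields 101 interpolated steps with exact endpoints", {
  set.seed(7)
  tr <- random_trajectory(37)
  rs <- resample_trajectory(tr)
  expect_length(rs$t_ms, 101L)
  expect_identical(c(rs$x[1], rs$y[1]), c(tr$x[1], tr$y[1]))
  expect_identical(c(rs$x[101], rs$y[101]), c(tr$x[37], tr$y[37]))

  # resampling a straight constant-speed path stays on the line
  line <- line_trajectory(c(0, 0), c(0.3, 0.6), dur_ms = 800)
  rl <- resample_trajectory(line, 50)
  expect_lt(max(abs(rl$y - 2 * rl$x)), 1e-12)

  expect_error(resample_trajectory(trajectory(0, 0, 0)), "2 samples")
})

test_that("total distance sums consecutive Euclidean segments", {
  still <- trajectory(seq(0, 160, 16), rep(0.1, 11), rep(0.2, 11))
  expect_equal(total_distance(still), 0)
  two_legs <- trajectory(c(0, 100, 200), c(0, 0, 0.4), c(0, 0.3, 0.3))
  expect_equal(total_distance(two_legs), 0.7)
  expect_equal(total_distance(trajectory(0, 1, 1)), 0)

  set.seed(11)
  for (i in 1:300) {
    tr <- random_trajectory(sample(2:50, 1))
    expect_equal(total_distance(tr), oracle_total_distance(tr),
                 tolerance = 1e-12)
  }
})

test_that("maximum velocity and acceleration follow segmentwise definitions", {
  # constant 0.5 units/s sampled every 16 ms
  line <- line_trajectory(c(0, 0), c(0, 0.5), dur_ms = 1000)
  expect_equal(max_velocity(line), 0.5, tolerance = 1e-9)
  expect_equal(max_acceleration(line), 0, tolerance = 1e-6)

  still <- trajectory(seq(0, 160, 16), rep(0, 11), rep(0, 11))
  expect_equal(max_velocity(still), 0)

  # speed step 0 -> 0.5 units/s across one 16 ms interval: 31.25 units/s^2
  step <- trajectory(c(0, 16, 32), c(0, 0, 0.008), c(0, 0, 0))
  expect_equal(max_acceleration(step), 31.25)

  set.seed(12)
  for (i in 1:300) {
    tr <- random_trajectory(sample(3:50, 1))
    expect_equal(max_velocity(tr), oracle_max_velocity(tr), tolerance = 1e-12)
    expect_equal(max_acceleration(tr), oracle_max_acceleration(tr),
                 tolerance = 1e-12)
  }
})

test_that("stopping distance is the post-signal path, split at the signal", {
  # all movement before the signal
  early <- line_trajectory(c(0, -0.8), c(0.6, 0.7), dur_ms = 400)
  expect_equal(stopping_distance(early, 500), 0)
  # no movement before the signal: full path length
  late <- trajectory(c(0, 600, 700, 800), c(0, 0, 0.3, 0.3), c(0, 0, 0, 0.6))
  expect_equal(stopping_distance(late, 500), 0.9)
  # signal after the last sample
  expect_equal(stopping_distance(early, 5000), 0)

  set.seed(13)
  for (i in 1:500) {
    tr <- random_trajectory(sample(2:40, 1))
    ts <- runif(1, -10, max(tr$t_ms) + 10)
    expect_equal(stopping_distance(tr, ts), oracle_stopping_distance(tr, ts),
                 tolerance = 1e-12)
  }
})

test_that("stopping distance is non-increasing in the signal time", {
  set.seed(14)
  for (i in 1:50) {
    tr <- random_trajectory(30)
    ts <- sort(runif(6, 0, max(tr$t_ms)))
    deltas <- vapply(ts, function(s) stopping_distance(tr, s), numeric(1))
    expect_true(all(diff(deltas) <= 1e-12))
  }
})

test_that("per-SSD averaging of stopping distance is unweighted over levels", {
  one <- data.frame(ssd_ms = c(100, 100, 100), delta = c(0.1, 0.2, 0.6))
  expect_equal(average_stopping_distance(one), 0.3)
  two <- data.frame(ssd_ms = c(100, 100, 600), delta = c(0.2, 0.4, 0.0))
  expect_equal(average_stopping_distance(two), 0.15)
  # balanced design: per-level averaging equals the pooled grand mean
  bal <- data.frame(ssd_ms = rep(c(100, 300, 600), each = 4),
                    delta = runif(12))
  expect_equal(average_stopping_distance(bal), mean(bal$delta))
  # unbalanced: differs from the pooled mean when level means differ
  unb <- data.frame(ssd_ms = c(100, 100, 100, 600), delta = c(1, 1, 1, 0))
  expect_equal(average_stopping_distance(unb), 0.5)
  expect_false(isTRUE(all.equal(average_stopping_distance(unb),
                                mean(unb$delta))))
  expect_error(average_stopping_distance(data.frame(ssd_ms = numeric(0),
                                                    delta = numeric(0))))
})

test_that("movement initiation and movement time behave on constructed trials", {
  # still until 350 ms, then a straight reach
  tt <- seq(0, 1000, 16)
  y <- ifelse(tt < 350, -0.8, -0.8 + (tt - 350) / 650 * 1.5)
  tr <- trajectory(tt, rep(0, length(tt)), y)
  init <- movement_initiation_time(tr, move_threshold = 0.01)
  # threshold crossing lands within two 16 ms samples of the true onset
  expect_true(abs(init - 350) <= 32 + 1e-9)

  still <- trajectory(tt, rep(0, length(tt)), rep(-0.8, length(tt)))
  expect_true(is.na(movement_initiation_time(still)))

  expect_equal(movement_time(400, 1300), 900)
  expect_equal(movement_time(400, 3100), 2700)
  expect_error(movement_time(400, 300), "negative")

  # zero threshold: first displaced sample, verified by scan
  set.seed(15)
  tr2 <- random_trajectory(20)
  init0 <- movement_initiation_time(tr2, move_threshold = 0)
  cum <- cumsum(sqrt(diff(tr2$x)^2 + diff(tr2$y)^2))
  expect_equal(init0, tr2$t_ms[which(cum > 0)[1] + 1])
})

test_that("distance and velocity are invariant under time reversal", {
  set.seed(16)
  for (i in 1:30) {
    tr <- random_trajectory(25)
    rev_tr <- trajectory(max(tr$t_ms) - rev(tr$t_ms), rev(tr$x), rev(tr$y))
    expect_equal(total_distance(tr), total_distance(rev_tr), tolerance = 1e-12)
    expect_equal(max_velocity(tr), max_velocity(rev_tr), tolerance = 1e-12)
  }
})

test_that("resampling never lengthens the path and preserves it for linear motion", {
  set.seed(17)
  for (i in 1:30) {
    tr <- random_trajectory(40)
    expect_lte(total_distance(resample_trajectory(tr)),
               total_distance(tr) + 1e-9)
  }
  # equally spaced, collinear per segment: length preserved exactly
  line <- line_trajectory(c(0, 0), c(0.8, 0.4), dur_ms = 1600)
  expect_equal(total_distance(resample_trajectory(line)),
               total_distance(line), tolerance = 1e-12)
})
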