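test_that("finishing time is the ceiling-rank order statistic of go RTs", {
  # the worked example: p_respond = 0.55 picks the 55th percentile
  rts <- seq(10, 1000, by = 10)
  expect_equal(finishing_time(rts, 0.55), 550)
  expect_equal(finishing_time(500, 0.55), 500)
  expect_true(is.na(finishing_time(rts, 0)))
  expect_true(is.na(finishing_time(rts, 1)))
  expect_error(finishing_time(numeric(0), 0.5), "go RTs")

  set.seed(71)
  for (i in 1:100) {
    v <- runif(sample(5:100, 1), 100, 2000)
    p <- runif(1, 0.01, 0.99)
    expect_equal(finishing_time(v, p), oracle_finishing_time(v, p))
  }
  # monotone non-decreasing in p_respond
  v <- runif(60, 300, 900)
  fts <- vapply(seq(0.05, 0.95, 0.05), function(p) finishing_time(v, p),
                numeric(1))
  expect_true(all(diff(fts) >= 0))
})

test_that("preset-SSD SSRT averages defined per-level estimates", {
  # one level: median go RT 600 at SSD 300 and p = 0.5 gives 300
  go <- seq(401, 799, 2)  # 200 RTs, 100th/101st around 600
  st <- data.frame(ssd_ms = rep(300, 10), responded = rep(c(TRUE, FALSE), 5))
  est <- ssrt_preset(go, st)
  expect_equal(as.numeric(est), finishing_time(go, 0.5) - 300)

  # two levels averaging: construct p = 0.5 at both SSDs
  st2 <- data.frame(ssd_ms = rep(c(200, 400), each = 4),
                    responded = rep(c(TRUE, TRUE, FALSE, FALSE), 2))
  ft <- finishing_time(go, 0.5)
  expect_equal(as.numeric(ssrt_preset(go, st2)), mean(c(ft - 200, ft - 400)))

  # boundary levels are dropped and counted
  st3 <- data.frame(ssd_ms = c(100, 100, 600, 600),
                    responded = c(FALSE, FALSE, TRUE, FALSE))
  est3 <- ssrt_preset(go, st3)
  expect_equal(attr(est3, "dropped_levels"), 1L)
  expect_equal(as.numeric(est3), finishing_time(go, 0.5) - 600)
  all_bound <- data.frame(ssd_ms = c(100, 600), responded = c(FALSE, TRUE))
  expect_true(is.na(as.numeric(ssrt_preset(go, all_bound))))
})

test_that("staircase SSRT subtracts the mean SSD from the overall finishing time", {
  go <- seq(101, 999, 2)
  st <- data.frame(ssd_ms = c(500, 550, 600, 550),
                   responded = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ssrt_staircase(go, st), finishing_time(go, 0.5) - 550)
  # all SSDs equal: coincides with the preset estimator
  st_eq <- data.frame(ssd_ms = rep(400, 6),
                      responded = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ssrt_staircase(go, st_eq), as.numeric(ssrt_preset(go, st_eq)))
  expect_true(is.na(ssrt_staircase(go, data.frame(ssd_ms = 1:3 * 100,
                                                  responded = rep(FALSE, 3)))))
})

test_that("session summaries match hand computation on a built fixture", {
  d <- session_design("exp1", "keypress")
  trials <- data.frame(
    index = 1:6,
    trial_type = c("go", "go", "go", "go", "stop", "stop"),
    coherence = c(0.1, 0.1, 0.8, 0.8, 0.1, 0.8),
    direction = c("L", "R", "L", "R", "L", "R"),
    ssd_ms = c(NA, NA, NA, NA, 300, 300),
    responded = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    response_direction = c("L", "L", "L", NA, "L", NA),
    rt_ms = c(700, 800, 600, NA, 500, NA),
    inhibition_failure = c(NA, NA, NA, NA, TRUE, FALSE),
    points = c(100L, -50L, 100L, -50L, -50L, 100L),
    trajectory_id = NA_character_,
    stringsAsFactors = FALSE)
  ses <- structure(list(trials = trials, trajectories = list(), design = d,
                        participant_id = 1L), class = "sst_session")
  f <- summarize_performance(ses)
  expect_equal(f$rt_go, 700)
  expect_equal(f$sd_rt_go, 100)
  expect_equal(f$acc_go, 2 / 4)
  expect_equal(f$direction_discrimination_acc, 2 / 3)
  expect_equal(f$p_respond_stop, 0.5)
  expect_equal(f$acc_stop, 0.5)
  expect_equal(f$rt_stop, 500)
  # SSRT: p = 0.5 at SSD 300 over go RTs {600,700,800} -> 700 - 300
  expect_equal(f$ssrt, 400)
  # per-coherence blocks
  expect_equal(f$rt_go_c10, 750)
  expect_equal(f$rt_go_c80, 600)
  expect_equal(f$acc_go_c80, 1 / 2)

  # degenerate: no stop responses
  trials0 <- trials
  trials0$responded[5] <- FALSE
  trials0$inhibition_failure[5] <- FALSE
  trials0$rt_ms[5] <- NA
  ses0 <- structure(list(trials = trials0, trajectories = list(), design = d,
                         participant_id = 1L), class = "sst_session")
  f0 <- summarize_performance(ses0)
  expect_equal(f0$acc_stop, 1)
  expect_true(is.na(f0$ssrt))

  # constant-RT session has zero SD
  trialsC <- trials
  trialsC$rt_ms <- c(700, 700, 700, NA, 500, NA)
  sesC <- structure(list(trials = trialsC, trajectories = list(), design = d,
                         participant_id = 1L), class = "sst_session")
  expect_equal(summarize_performance(sesC)$sd_rt_go, 0)
})

test_that("integration-method SSRT recovers the generative value within 25 ms", {
  # abbreviated recovery run; the acceptance suite runs the full grid
  pop <- population_config()
  g <- sst_geometry()
  d <- session_design("exp1", "keypress")
  errs <- sapply(1:30, function(i) {
    tr <- fixed_traits(ssrt = 250)
    s <- simulate_session(tr, d, g, pop, seed = 700 + i)
    summarize_performance(s, split_by_coherence = FALSE)$ssrt - 250
  })
  expect_lt(abs(median(errs)), 25)
})
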