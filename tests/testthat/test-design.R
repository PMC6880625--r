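test_that("schedules reproduce the task structure and balance cells evenly", {
  d <- session_design("exp1", "keypress")
  sch <- make_trial_schedule(d, seed = 11)
  expect_equal(nrow(sch), 576L)
  expect_equal(sum(sch$trial_type == "stop"), 144L)
  expect_equal(sum(sch$trial_type == "go"), 432L)

  # 12 trials, 3 coherences, 2 directions, no stop: every cell exactly twice
  d12 <- session_design("exp1", "keypress", n_trials = 12, n_stop = 0,
                        coherence_levels = c(0.1, 0.5, 0.8))
  sch12 <- make_trial_schedule(d12, seed = 3)
  counts <- table(sch12$coherence, sch12$direction)
  expect_true(all(counts == 2L))

  # degenerate: zero stop trials
  d4 <- session_design("exp1", "keypress", n_trials = 4, n_stop = 0)
  expect_true(all(make_trial_schedule(d4, seed = 1)$trial_type == "go"))

  expect_error(session_design("exp1", n_trials = 10, n_stop = 10), "n_stop")
})

test_that("schedules are permutations of one multiset across seeds", {
  d <- tiny_design(n_trials = 30, n_stop = 6)
  a <- make_trial_schedule(d, seed = 1)
  b <- make_trial_schedule(d, seed = 2)
  key <- function(s) sort(paste(s$trial_type, s$coherence, s$direction))
  expect_identical(key(a), key(b))
  expect_identical(make_trial_schedule(d, seed = 1), a)  # determinism
})

test_that("preset SSDs are drawn uniformly from the configured support", {
  d <- session_design("exp1", "keypress")
  sch <- assign_preset_ssd(make_trial_schedule(d, seed = 2),
                           d$preset_ssds, seed = 7)
  ssds <- sch$ssd_ms[sch$trial_type == "stop"]
  expect_true(all(ssds %in% seq(100, 600, 100)))
  expect_true(all(is.na(sch$ssd_ms[sch$trial_type == "go"])))

  one <- assign_preset_ssd(make_trial_schedule(d, seed = 2), 300, seed = 1)
  expect_true(all(one$ssd_ms[one$trial_type == "stop"] == 300))
  expect_error(assign_preset_ssd(sch, numeric(0)), "empty")

  # frequencies within 3 binomial SDs of uniform over a large draw
  big <- session_design("exp1", "keypress", n_trials = 10001, n_stop = 10000)
  bs <- assign_preset_ssd(make_trial_schedule(big, seed = 5),
                          d$preset_ssds, seed = 9)
  freq <- table(bs$ssd_ms[bs$trial_type == "stop"]) / 10000
  tol <- 3 * sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) < tol))
})

test_that("staircase moves 50 ms toward harder stopping on success and clamps", {
  expect_equal(staircase_update(600, TRUE, 50), 650)
  expect_equal(staircase_update(600, FALSE, 50), 550)
  expect_equal(staircase_update(0, FALSE, 50, c(0, 1500)), 0)
  expect_equal(staircase_update(1500, TRUE, 50, c(0, 1500)), 1500)
  expect_error(staircase_update(600, TRUE, 0), "positive")
})

test_that("stop-trial response detection follows the mode-specific criterion", {
  g <- sst_geometry()
  d2 <- session_design("exp2", "mouse")
  rec <- list(trial_type = "stop", responded = FALSE)

  still <- trajectory(seq(0, 500, 16), rep(0, 32), rep(-0.8, 32))
  expect_false(detect_stop_response(rec, still, d2, g))

  # vertical span is 1.5; 26% progress crosses the 25% cutoff line
  cross <- trajectory(c(0, 100, 200), c(0, 0, 0), c(-0.8, -0.8 + 0.2, -0.8 + 0.26 * 1.5))
  expect_true(detect_stop_response(rec, cross, d2, g))

  # keypress: criterion is response emission
  dk <- session_design("exp2", "keypress")
  expect_true(detect_stop_response(list(trial_type = "stop", responded = TRUE),
                                   NULL, dk, g))
  # exp1 mouse: criterion is the click, not the cutoff
  d1 <- session_design("exp1", "mouse")
  expect_false(detect_stop_response(rec, cross, d1, g))
  expect_error(detect_stop_response(rec, NULL, d2, g), "trajectory")
})

test_that("cutoff detection equals a full-scan oracle and is monotone", {
  g <- sst_geometry()
  d2 <- session_design("exp2", "mouse")
  rec <- list(trial_type = "stop", responded = FALSE)
  cutoff_y <- g$start[2] + d2$cutoff_fraction * (g$button_left[2] - g$start[2])
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    tr <- trajectory(seq_len(n) * 16, cumsum(rnorm(n, 0, 0.02)),
                     -0.8 + cumsum(abs(rnorm(n, 0.01, 0.03))))
    got <- detect_stop_response(rec, tr, d2, g)
    want <- FALSE
    for (j in seq_len(n)) if (tr$y[j] > cutoff_y) want <- TRUE
    expect_identical(got, want)
    # monotone: adding samples can flip false -> true but never true -> false
    if (n > 3) {
      tr_cut <- trajectory(tr$t_ms[1:3], tr$x[1:3], tr$y[1:3])
      prefix <- detect_stop_response(rec, tr_cut, d2, g)
      if (prefix) expect_true(got)
    }
  }
})

test_that("feedback scoring awards +100 for correct outcomes and -50 otherwise", {
  go_ok <- list(trial_type = "go", responded = TRUE, response_direction = "L",
                direction = "L")
  go_wrong <- list(trial_type = "go", responded = TRUE, response_direction = "R",
                   direction = "L")
  go_miss <- list(trial_type = "go", responded = FALSE,
                  response_direction = NA, direction = "L")
  stop_ok <- list(trial_type = "stop", inhibition_failure = FALSE)
  stop_fail <- list(trial_type = "stop", inhibition_failure = TRUE)
  expect_equal(score_trial(go_ok), 100L)
  expect_equal(score_trial(go_wrong), -50L)
  expect_equal(score_trial(go_miss), -50L)
  expect_equal(score_trial(stop_ok), 100L)
  expect_equal(score_trial(stop_fail), -50L)
  # cumulative check over a session of correct go trials
  expect_equal(sum(replicate(10, score_trial(go_ok))), 1000L)
})

test_that("the 5% exclusion rule is inclusive on both measures", {
  expect_true(apply_exclusion(list(acc_stop = 0.5,
                                   direction_discrimination_acc = 0.9)))
  expect_false(apply_exclusion(list(acc_stop = 0.04,
                                    direction_discrimination_acc = 0.9)))
  expect_false(apply_exclusion(list(acc_stop = 0.99,
                                    direction_discrimination_acc = 0.04)))
  expect_true(apply_exclusion(list(acc_stop = 0.05,
                                   direction_discrimination_acc = 0.05)))
  expect_error(apply_exclusion(list(acc_stop = NA,
                                    direction_discrimination_acc = 0.5)))
})
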