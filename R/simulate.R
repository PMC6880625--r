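# Horse-race simulator: keypress responses and continuous cursor
# trajectories for go and stop trials.
#
# Going and stopping race independently. In keypress mode the go process
# finishing time G is lognormal and a stop-trial response is emitted iff G
# precedes the stop finishing time S = SSD + SSRT. In mouse mode the overt go
# process is a reach: movement initiation, a symmetric bell-shaped
# (sine-squared) speed profile toward the chosen button, and -- if the stop
# process finishes first -- constant-deceleration braking from the moment S,
# which halts the cursor after v(S)^2 / (2 * brake_decel) screen units.

# Arc-length position (screen units) along the bell profile at time tau (s)
# into the movement: s(tau) = peak * (tau/2 - T/(4 pi) sin(2 pi tau / T)).
bell_position <- function(tau, peak, T_move) {
  tau <- clamp(tau, 0, T_move)
  peak * (tau / 2 - T_move / (4 * pi) * sin(2 * pi * tau / T_move))
}

bell_speed <- function(tau, peak, T_move) {
  ifelse(tau < 0 | tau > T_move, 0, peak * sin(pi * tau / T_move)^2)
}

# First time (s) at which the bell profile reaches arc length s_target.
bell_time_at <- function(s_target, peak, T_move) {
  total <- peak * T_move / 2
  if (s_target <= 0) return(0)
  if (s_target >= total) return(T_move)
  stats::uniroot(function(tau) bell_position(tau, peak, T_move) - s_target,
                 lower = 0, upper = T_move, tol = 1e-9)$root
}

# Piecewise arc length at times tau (s) for a reach that brakes at tau_b with
# entry speed v_b and deceleration a; Inf tau_b means no braking.
reach_position <- function(tau, peak, T_move, tau_b = Inf, a = NULL, s_end = Inf) {
  s <- bell_position(tau, peak, T_move)
  if (is.finite(tau_b)) {
    v_b <- bell_speed(tau_b, peak, T_move)
    s_b <- bell_position(tau_b, peak, T_move)
    halt <- tau_b + v_b / a
    u <- clamp(tau - tau_b, 0, v_b / a)
    s <- ifelse(tau <= tau_b, s, s_b + v_b * u - a * u^2 / 2)
  }
  pmin(s, s_end)
}

#' Simulate a single trial
#'
#' Runs the independent horse-race model for one trial plan and one
#' participant, returning the trial record and (in mouse mode) the recorded
#' cursor trajectory. Randomness is drawn from the current RNG state unless a
#' `seed` is given.
#'
#' @param traits One row of an `sst_traits` data frame.
#' @param plan One row of a trial schedule (with `ssd_ms` set on stop trials).
#' @param design An [session_design()].
#' @param geometry An [sst_geometry()] (mouse mode).
#' @param population The [population_config()] the traits were drawn from.
#' @param seed Optional integer seed.
#' @return A list with `record` (one-row data frame) and `trajectory`
#'   (`sst_trajectory` or `NULL` in keypress mode).
#' @export
simulate_trial <- function(traits, plan, design, geometry = sst_geometry(),
                           population = population_config(), seed = NULL) {
  out <- with_seed(seed, sim_trial_impl(traits, plan, design, geometry, population))
  out$record <- record_list_to_df(list(out$record))
  out
}

sim_trial_impl <- function(traits, plan, design, geometry, population) {
  is_stop <- identical(as.character(plan$trial_type), "stop")
  if (is_stop && (is.null(plan$ssd_ms) || is.na(plan$ssd_ms))) {
    stop("stop trial has no SSD assigned", call. = FALSE)
  }
  window <- design$response_window_ms
  p_correct <- stats::plogis(population$direction_slope * plan$coherence)
  correct_dir <- stats::runif(1) < p_correct
  chosen <- if (correct_dir) as.character(plan$direction) else
    setdiff(c("L", "R"), as.character(plan$direction))
  lapse <- stats::runif(1) < traits$lapse_rate

  if (design$response_mode == "keypress") {
    responded <- FALSE; rt <- NA_real_
    if (!lapse) {
      mu <- log(go_median_ms(population, traits, plan$coherence))
      G <- stats::rlnorm(1, mu, traits$go_sigma_log)
      if (is_stop) {
        S <- plan$ssd_ms + traits$ssrt_true_ms
        responded <- G < S && G <= window
      } else {
        responded <- G <= window
      }
      if (responded) rt <- G
    }
    record <- finalize_record(plan, responded,
                              if (responded) chosen else NA_character_,
                              rt, trajectory = NULL, design, geometry)
    return(list(record = record, trajectory = NULL))
  }

  # --- mouse mode ---
  start <- geometry$start
  target <- if (chosen == "L") geometry$button_left else geometry$button_right
  D <- sqrt(sum((target - start)^2))
  s_click <- D - geometry$button_radius
  dt <- 16
  times <- seq(0, window, by = dt)

  if (lapse) {
    traj <- trajectory(times, rep(start[1], length(times)),
                       rep(start[2], length(times)), dt)
    record <- finalize_record(plan, FALSE, NA_character_, NA_real_, traj,
                              design, geometry)
    return(list(record = record, trajectory = traj))
  }

  t0 <- max(100, stats::rnorm(1, traits$init_mu_ms, population$init_sd_ms))
  peak <- traits$peak_speed * exp(stats::rnorm(1, 0, population$peak_trial_sd_log))
  T_move <- 2 * D / peak
  tau_click <- bell_time_at(s_click, peak, T_move)

  tau_b <- Inf
  responded <- FALSE
  rt <- NA_real_
  s_end <- s_click
  if (is_stop) {
    S_ms <- plan$ssd_ms + traits$ssrt_true_ms
    tau_S <- (S_ms - t0) / 1000
    if (tau_S <= 0) {
      # stop process finishes before movement initiation: no motion at all
      traj <- trajectory(times, rep(start[1], length(times)),
                         rep(start[2], length(times)), dt)
      record <- finalize_record(plan, FALSE, NA_character_, NA_real_, traj,
                                design, geometry)
      return(list(record = record, trajectory = traj))
    }
    if (tau_S < tau_click) {
      tau_b <- tau_S
      v_b <- bell_speed(tau_b, peak, T_move)
      s_b <- bell_position(tau_b, peak, T_move)
      a <- traits$brake_decel
      s_halt <- s_b + v_b^2 / (2 * a)
      if (s_halt >= s_click) {
        # cursor coasts into the button while braking: inhibition failure
        u <- (v_b - sqrt(max(v_b^2 - 2 * a * (s_click - s_b), 0))) / a
        responded <- TRUE
        rt <- t0 + 1000 * (tau_b + u)
      }
    } else {
      responded <- TRUE
      rt <- t0 + 1000 * tau_click
    }
  } else {
    responded <- TRUE
    rt <- t0 + 1000 * tau_click
  }
  if (responded && rt > window) {
    responded <- FALSE
    rt <- NA_real_
  }

  end_ms <- if (responded) min(window, dt * ceiling(rt / dt)) else window
  times <- seq(0, end_ms, by = dt)
  tau <- (times - t0) / 1000
  s <- reach_position(tau, peak, T_move,
                      tau_b = tau_b, a = traits$brake_decel, s_end = s_end)
  xs <- start[1] + (s / D) * (target[1] - start[1])
  ys <- start[2] + (s / D) * (target[2] - start[2])
  moved <- c(FALSE, diff(s) > 0)
  n_mov <- sum(moved)
  if (n_mov > 0 && population$jitter_sd > 0) {
    xs[moved] <- xs[moved] + stats::rnorm(n_mov, 0, population$jitter_sd)
    ys[moved] <- ys[moved] + stats::rnorm(n_mov, 0, population$jitter_sd)
  }
  traj <- trajectory(times, xs, ys, dt)
  record <- finalize_record(plan, responded,
                            if (responded) chosen else NA_character_,
                            rt, traj, design, geometry)
  list(record = record, trajectory = traj)
}

# Assemble the one-row trial record (as a plain list), applying the response
# criterion and the feedback scoring.
finalize_record <- function(plan, responded, response_direction, rt, trajectory,
                            design, geometry) {
  rec <- list(
    index = plan$index,
    trial_type = as.character(plan$trial_type),
    coherence = plan$coherence,
    direction = as.character(plan$direction),
    ssd_ms = if (is.null(plan$ssd_ms)) NA_real_ else plan$ssd_ms,
    responded = responded,
    response_direction = response_direction,
    rt_ms = rt,
    inhibition_failure = NA
  )
  if (rec$trial_type == "stop") {
    rec$inhibition_failure <- detect_stop_response(rec, trajectory, design, geometry)
  }
  rec$points <- score_trial(rec)
  rec
}

record_list_to_df <- function(records) {
  data.frame(
    index = vapply(records, function(r) as.integer(r$index), integer(1)),
    trial_type = vapply(records, function(r) as.character(r$trial_type), character(1)),
    coherence = vapply(records, function(r) as.numeric(r$coherence), numeric(1)),
    direction = vapply(records, function(r) as.character(r$direction), character(1)),
    ssd_ms = vapply(records, function(r) as.numeric(r$ssd_ms), numeric(1)),
    responded = vapply(records, function(r) as.logical(r$responded), logical(1)),
    response_direction = vapply(records, function(r)
      as.character(r$response_direction), character(1)),
    rt_ms = vapply(records, function(r) as.numeric(r$rt_ms), numeric(1)),
    inhibition_failure = vapply(records, function(r)
      as.logical(r$inhibition_failure), logical(1)),
    points = vapply(records, function(r) as.integer(r$points), integer(1)),
    stringsAsFactors = FALSE
  )
}

# Vectorized keypress session: the race has no trajectory, so every trial's
# lognormal go draw, lapse and direction choice can be drawn in bulk. The
# staircase still walks the stop trials in presentation order.
sim_keypress_session <- function(traits, schedule, design, population) {
  n <- nrow(schedule)
  window <- design$response_window_ms
  mu <- log(vapply(schedule$coherence, function(coh)
    go_median_ms(population, traits, coh), numeric(1)))
  G <- stats::rlnorm(n, mu, traits$go_sigma_log)
  lapse <- stats::runif(n) < traits$lapse_rate
  correct_dir <- stats::runif(n) <
    stats::plogis(population$direction_slope * schedule$coherence)
  chosen <- ifelse(correct_dir, schedule$direction,
                   ifelse(schedule$direction == "L", "R", "L"))
  is_stop <- schedule$trial_type == "stop"
  ssd <- schedule$ssd_ms
  if (design$ssd_policy == "staircase" && any(is_stop)) {
    bounds <- staircase_bounds(design)
    cur <- design$staircase_initial
    for (i in which(is_stop)) {
      ssd[i] <- cur
      failed <- !lapse[i] && G[i] < cur + traits$ssrt_true_ms && G[i] <= window
      cur <- staircase_update(cur, !failed, design$staircase_step, bounds)
    }
  }
  S <- ssd + traits$ssrt_true_ms
  responded <- !lapse & G <= window & (!is_stop | G < S)
  rt <- ifelse(responded, G, NA_real_)
  response_direction <- ifelse(responded, chosen, NA_character_)
  inhibition_failure <- ifelse(is_stop, responded, NA)
  correct_go <- !is_stop & responded & chosen == schedule$direction
  points <- ifelse(is_stop, ifelse(inhibition_failure, -50L, 100L),
                   ifelse(correct_go, 100L, -50L))
  data.frame(index = schedule$index,
             trial_type = schedule$trial_type,
             coherence = schedule$coherence,
             direction = schedule$direction,
             ssd_ms = ssd,
             responded = responded,
             response_direction = response_direction,
             rt_ms = rt,
             inhibition_failure = inhibition_failure,
             points = as.integer(points),
             stringsAsFactors = FALSE)
}

#' Simulate a full session for one participant
#'
#' Builds a balanced seeded schedule, assigns SSDs (uniform preset draw, or a
#' running 50 ms staircase updated from each stop trial's outcome), and
#' simulates every trial in order.
#'
#' @param traits One row of an `sst_traits` data frame.
#' @param design An [session_design()].
#' @param geometry An [sst_geometry()].
#' @param population The [population_config()].
#' @param seed Integer seed; fixed seed gives a bit-identical session.
#' @return An object of class `sst_session`: list with `trials` (data frame,
#'   one row per trial) and `trajectories` (list keyed by trial index;
#'   empty in keypress mode), plus the design.
#' @export
simulate_session <- function(traits, design, geometry = sst_geometry(),
                             population = population_config(), seed = NULL) {
  validate_design(design)
  with_seed(seed, {
    schedule <- make_trial_schedule(design)
    if (design$ssd_policy == "preset" && design$n_stop > 0) {
      schedule <- assign_preset_ssd(schedule, design$preset_ssds)
    }
    if (design$response_mode == "keypress") {
      trials <- sim_keypress_session(traits, schedule, design, population)
      trials$trajectory_id <- NA_character_
      return(structure(list(trials = trials, trajectories = list(),
                            design = design,
                            participant_id = traits$participant_id),
                       class = "sst_session"))
    }
    bounds <- staircase_bounds(design)
    ssd <- design$staircase_initial
    records <- vector("list", nrow(schedule))
    trajectories <- vector("list", nrow(schedule))
    plans <- split(schedule, seq_len(nrow(schedule)))
    for (i in seq_len(nrow(schedule))) {
      plan <- plans[[i]]
      if (plan$trial_type == "stop" && design$ssd_policy == "staircase") {
        plan$ssd_ms <- ssd
      }
      out <- sim_trial_impl(traits, plan, design, geometry, population)
      rec <- out$record
      if (plan$trial_type == "stop" && design$ssd_policy == "staircase") {
        ssd <- staircase_update(ssd, !rec$inhibition_failure,
                                design$staircase_step, bounds)
      }
      records[[i]] <- rec
      trajectories[[i]] <- out$trajectory
    }
    trials <- record_list_to_df(records)
    names(trajectories) <- as.character(trials$index)
    trials$trajectory_id <- as.character(trials$index)
    structure(list(trials = trials, trajectories = trajectories,
                   design = design,
                   participant_id = traits$participant_id),
              class = "sst_session")
  })
}

#' @export
print.sst_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("Stop-signal session ('%s', %s): %d trials, %d stop\n",
              x$design$profile, x$design$response_mode,
              nrow(tr), sum(tr$trial_type == "stop")))
  st <- tr[tr$trial_type == "stop", ]
  if (nrow(st) > 0) {
    cat(sprintf("  P(respond | stop) = %.3f; total points = %d\n",
                mean(st$inhibition_failure), sum(tr$points)))
  }
  invisible(x)
}

#' Simulate a multi-participant study
#'
#' Draws a participant sample, simulates one session each, summarizes each
#' session into the participant feature vector, and generates questionnaire
#' scores from the same latent traits. Per-participant session seeds are
#' derived deterministically from `seed`.
#'
#' @param n Number of participants.
#' @param design An [session_design()].
#' @param geometry An [sst_geometry()].
#' @param population A [population_config()].
#' @param seed Master integer seed.
#' @param keep_sessions Keep the full sessions (with trajectories) in the
#'   result? Default drops them and keeps only the feature table.
#' @return An object of class `sst_study`: list with `traits`, `scores`,
#'   `features` (one row per participant) and optionally `sessions`.
#' @export
simulate_study <- function(n, design, geometry = sst_geometry(),
                           population = population_config(), seed = 1,
                           keep_sessions = FALSE) {
  traits <- sample_participants(n, population, seed = stage_seed(seed, 1))
  scores <- questionnaire_scores(traits, population, seed = stage_seed(seed, 2))
  feats <- vector("list", n)
  sessions <- if (keep_sessions) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ses <- simulate_session(traits[i, ], design, geometry, population,
                            seed = stage_seed(seed, 100 + i))
    feats[[i]] <- summarize_performance(ses)
    if (keep_sessions) sessions[[i]] <- ses
  }
  features <- do.call(rbind, feats)
  features <- cbind(participant_id = traits$participant_id, features)
  rownames(features) <- NULL
  structure(list(traits = traits, scores = scores, features = features,
                 sessions = sessions, design = design,
                 population = population, seed = seed),
            class = "sst_study")
}

#' @export
print.sst_study <- function(x, ...) {
  cat(sprintf("Simulated stop-signal study: %d participants ('%s', %s, scenario '%s')\n",
              nrow(x$traits), x$design$profile, x$design$response_mode,
              x$population$scenario))
  cat(sprintf("  feature table: %d columns; subscales: %s\n",
              ncol(x$features),
              paste(setdiff(names(x$scores), "participant_id"), collapse = ", ")))
  invisible(x)
}
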