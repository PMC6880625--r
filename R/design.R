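# Session design: trial schedules, stop-signal delay policies, response and
# exclusion criteria, and point scoring for the stop-signal task.

#' Define a stop-signal session design
#'
#' Builds the task structure of one session: trial and stop-trial counts, dot
#' coherence levels, the stop-signal delay (SSD) policy, timing constants and
#' the response criterion. The two named profiles reproduce the task
#' parameterizations used throughout the package:
#'
#' * `"exp1"`: 576 trials (432 go, 144 stop), coherences 10/50/80%, SSDs drawn
#'   uniformly from the preset values 100--600 ms. On mouse stop trials a
#'   response (inhibition failure) is a button click.
#' * `"exp2"`: same trial structure, but SSD follows a 50 ms up/down staircase
#'   starting at 600 ms, and on mouse stop trials a response is the cursor
#'   crossing 25% of the vertical start-to-button distance.
#'
#' @param profile `"exp1"` (preset SSDs) or `"exp2"` (staircase SSDs).
#' @param response_mode `"keypress"` or `"mouse"`.
#' @param n_trials,n_stop Total trial count and number of stop trials.
#' @param coherence_levels Fractions in (0, 1]: proportion of coherently
#'   moving dots.
#' @param preset_ssds Preset SSD values in ms (preset policy only).
#' @param staircase_step,staircase_initial Staircase step and starting SSD, ms.
#' @param fixation_ms,stimulus_ms,response_window_ms,stop_tone_ms Timing
#'   constants in ms.
#' @param cutoff_fraction Fraction of the vertical start-to-button distance
#'   whose crossing counts as a response on mouse stop trials (staircase
#'   profile).
#' @return An object of class `sst_design` (a named list).
#' @examples
#' d <- session_design("exp1", "mouse")
#' d$n_trials
#' @export
session_design <- function(profile = c("exp1", "exp2"),
                           response_mode = c("keypress", "mouse"),
                           n_trials = 576L,
                           n_stop = 144L,
                           coherence_levels = c(0.1, 0.5, 0.8),
                           preset_ssds = seq(100, 600, by = 100),
                           staircase_step = 50,
                           staircase_initial = 600,
                           fixation_ms = 500,
                           stimulus_ms = 1100,
                           response_window_ms = 3100,
                           stop_tone_ms = 100,
                           cutoff_fraction = 0.25) {
  profile <- match.arg(profile)
  response_mode <- match.arg(response_mode)
  design <- structure(list(
    profile = profile,
    response_mode = response_mode,
    n_trials = as.integer(n_trials),
    n_stop = as.integer(n_stop),
    coherence_levels = as.numeric(coherence_levels),
    ssd_policy = if (profile == "exp1") "preset" else "staircase",
    preset_ssds = as.numeric(preset_ssds),
    staircase_step = as.numeric(staircase_step),
    staircase_initial = as.numeric(staircase_initial),
    fixation_ms = as.numeric(fixation_ms),
    stimulus_ms = as.numeric(stimulus_ms),
    response_window_ms = as.numeric(response_window_ms),
    stop_tone_ms = as.numeric(stop_tone_ms),
    cutoff_fraction = as.numeric(cutoff_fraction)
  ), class = "sst_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  stopifnot(inherits(design, "sst_design"))
  if (!is_count(design$n_trials) || !is_count(design$n_stop)) {
    stop("n_trials and n_stop must be non-negative integers", call. = FALSE)
  }
  if (design$n_stop >= design$n_trials) {
    stop("invalid design: n_stop must be smaller than n_trials", call. = FALSE)
  }
  if (any(design$coherence_levels <= 0 | design$coherence_levels > 1)) {
    stop("coherence levels must lie in (0, 1]", call. = FALSE)
  }
  if (design$ssd_policy == "preset") {
    if (length(design$preset_ssds) == 0L) stop("preset_ssds is empty", call. = FALSE)
    if (any(design$preset_ssds >= design$response_window_ms)) {
      stop("preset SSDs must be shorter than the response window", call. = FALSE)
    }
  }
  if (design$staircase_step <= 0) stop("staircase step must be positive", call. = FALSE)
  if (design$cutoff_fraction <= 0 || design$cutoff_fraction >= 1) {
    stop("cutoff_fraction must lie in (0, 1)", call. = FALSE)
  }
  invisible(design)
}

# SSD bounds implied by the design: the stop tone must end inside the window.
staircase_bounds <- function(design) {
  c(0, design$response_window_ms - design$stop_tone_ms)
}

#' @export
print.sst_design <- function(x, ...) {
  cat(sprintf(
    "Stop-signal session design ('%s', %s response)\n", x$profile, x$response_mode))
  cat(sprintf("  trials: %d (%d stop, %.0f%%)\n", x$n_trials, x$n_stop,
              100 * x$n_stop / x$n_trials))
  cat(sprintf("  coherence levels: %s\n",
              paste0(100 * x$coherence_levels, "%", collapse = ", ")))
  if (x$ssd_policy == "preset") {
    cat(sprintf("  SSD policy: preset {%s} ms\n",
                paste(x$preset_ssds, collapse = ", ")))
  } else {
    cat(sprintf("  SSD policy: staircase, start %g ms, step %g ms\n",
                x$staircase_initial, x$staircase_step))
  }
  cat(sprintf("  window %g ms, stimulus %g ms, stop tone %g ms\n",
              x$response_window_ms, x$stimulus_ms, x$stop_tone_ms))
  invisible(x)
}

#' Build a balanced, seeded trial schedule
#'
#' Assigns trial types, coherence levels and motion directions. Coherence and
#' direction are balanced as evenly as divisibility allows within each trial
#' type (go and stop separately); any remainder cells are chosen by a seeded
#' draw. The resulting order is shuffled deterministically by `seed`.
#'
#' @param design An [session_design()] object.
#' @param seed Integer seed; a fixed seed gives an identical schedule.
#' @return A data frame with one row per trial: `index`, `trial_type`
#'   (`"go"`/`"stop"`), `coherence`, `direction` (`"L"`/`"R"`), `ssd_ms`
#'   (`NA`; set later for stop trials).
#' @export
make_trial_schedule <- function(design, seed = NULL) {
  validate_design(design)
  cells <- expand.grid(coherence = design$coherence_levels,
                       direction = c("L", "R"),
                       stringsAsFactors = FALSE)
  fill_type <- function(n, type) {
    k <- nrow(cells)
    reps <- rep(seq_len(k), n %/% k)
    extra_n <- n %% k
    if (extra_n > 0L) reps <- c(reps, sample.int(k, extra_n))
    data.frame(trial_type = rep(type, n),
               coherence = cells$coherence[reps],
               direction = cells$direction[reps],
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    plans <- rbind(fill_type(design$n_trials - design$n_stop, "go"),
                   fill_type(design$n_stop, "stop"))
    plans <- plans[sample.int(nrow(plans)), , drop = FALSE]
    plans$index <- seq_len(nrow(plans))
    plans$ssd_ms <- NA_real_
    rownames(plans) <- NULL
    plans[, c("index", "trial_type", "coherence", "direction", "ssd_ms")]
  })
}

#' Assign preset stop-signal delays
#'
#' Draws each stop trial's SSD independently and uniformly from the preset
#' values; go trials are untouched.
#'
#' @param schedule Trial schedule from [make_trial_schedule()].
#' @param preset_ssds Candidate SSD values in ms.
#' @param seed Integer seed for the uniform draw.
#' @return The schedule with `ssd_ms` filled on stop trials.
#' @export
assign_preset_ssd <- function(schedule, preset_ssds, seed = NULL) {
  if (length(preset_ssds) == 0L) stop("preset_ssds is empty", call. = FALSE)
  is_stop <- schedule$trial_type == "stop"
  if (!any(is_stop)) stop("schedule contains no stop trials", call. = FALSE)
  with_seed(seed, {
    schedule$ssd_ms[is_stop] <-
      preset_ssds[sample.int(length(preset_ssds), sum(is_stop), replace = TRUE)]
    schedule
  })
}

#' One step of the adaptive SSD staircase
#'
#' After a successful inhibition the SSD increases by `step` (stopping is made
#' harder); after a failed inhibition it decreases by `step`. The result is
#' clamped to `bounds`. This up/down rule tracks the SSD at which inhibition
#' succeeds half the time.
#'
#' @param current_ssd Current SSD in ms.
#' @param inhibition_success Logical: was the response withheld?
#' @param step Staircase step in ms (must be positive).
#' @param bounds Length-2 numeric `c(lower, upper)` in ms.
#' @return The updated SSD in ms.
#' @examples
#' staircase_update(600, TRUE, 50)   # 650
#' staircase_update(600, FALSE, 50)  # 550
#' @export
staircase_update <- function(current_ssd, inhibition_success, step,
                             bounds = c(0, 3000)) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("staircase step must be a positive duration", call. = FALSE)
  }
  stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2])
  out <- current_ssd + if (isTRUE(inhibition_success)) step else -step
  clamp(out, bounds[1], bounds[2])
}

#' Decide whether a stop trial counts as a response
#'
#' Applies the response (inhibition-failure) criterion to one stop trial:
#'
#' * keypress mode: a response is any keypress (`responded`);
#' * mouse mode, preset-SSD profile: a response is a click on a response
#'   button;
#' * mouse mode, staircase profile: a response is the cursor's vertical
#'   progress from the start exceeding `cutoff_fraction` of the vertical
#'   start-to-button distance at any sample.
#'
#' @param record A one-row trial record (list or data-frame row) with at least
#'   `trial_type` and `responded`.
#' @param trajectory An [trajectory()] object; required in mouse mode.
#' @param design An [session_design()] object.
#' @param geometry An [sst_geometry()] object.
#' @return Logical flag: `TRUE` if the trial counts as a response
#'   (inhibition failure).
#' @export
detect_stop_response <- function(record, trajectory = NULL, design, geometry) {
  if (!identical(as.character(record$trial_type), "stop")) {
    stop("detect_stop_response applies to stop trials only", call. = FALSE)
  }
  if (design$response_mode == "keypress") {
    return(isTRUE(as.logical(record$responded)))
  }
  if (is.null(trajectory)) {
    stop("mouse mode requires a trajectory", call. = FALSE)
  }
  if (design$ssd_policy == "preset") {
    return(isTRUE(as.logical(record$responded)))
  }
  traj <- as_trajectory(trajectory)
  v_span <- geometry$button_left[2] - geometry$start[2]
  progress <- traj$y - geometry$start[2]
  any(progress > design$cutoff_fraction * v_span)
}

#' Score one trial
#'
#' Feedback points: +100 for a correct go response or a successful inhibition;
#' -50 for any incorrect response. A go trial with no response earns -50 (no
#' direction was indicated).
#'
#' @param record One-row trial record with `trial_type`, `responded`,
#'   `response_direction`, `direction` (planned) and, for stop trials,
#'   `inhibition_failure`.
#' @return Integer points.
#' @export
score_trial <- function(record) {
  if (identical(as.character(record$trial_type), "stop")) {
    if (isTRUE(as.logical(record$inhibition_failure))) -50L else 100L
  } else {
    correct <- isTRUE(as.logical(record$responded)) &&
      identical(as.character(record$response_direction),
                as.character(record$direction))
    if (correct) 100L else -50L
  }
}

#' Participant inclusion rule
#'
#' A participant is retained only with at least 5% successful response
#' inhibition on stop trials and a correct direction indication on at least 5%
#' of go trials (both inclusive).
#'
#' @param summary Participant summary with fields/columns
#'   `acc_stop` (inhibition success rate) and `direction_discrimination_acc`.
#' @return Logical: `TRUE` to retain.
#' @export
apply_exclusion <- function(summary) {
  inh <- summary[["acc_stop"]]
  dda <- summary[["direction_discrimination_acc"]]
  if (is.null(inh) || is.null(dda) || is.na(inh) || is.na(dda)) {
    stop("summary must provide acc_stop and direction_discrimination_acc",
         call. = FALSE)
  }
  inh >= 0.05 && dda >= 0.05
}
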