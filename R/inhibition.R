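# Reactive-inhibition measures: integration-method SSRT under preset and
# staircase SSD regimes, and the participant-level performance summary.

#' Finishing time of the stop process (integration method)
#'
#' Rank-orders the go RTs and selects the n-th order statistic, with n
#' corresponding to the proportion of responding on stop trials: the k-th
#' smallest go RT with k = ceiling(p_respond * length(go_rts)). For example,
#' with p_respond = 0.55 the finishing time is the 55th percentile of the go
#' RTs.
#'
#' @param go_rts Go-trial response times in ms (responded trials only).
#' @param p_respond Proportion of stop trials with a response, in (0, 1).
#' @return The finishing time in ms, or `NA` when `p_respond` is exactly 0 or
#'   1 (the estimate is undefined at the boundary).
#' @export
finishing_time <- function(go_rts, p_respond) {
  go_rts <- go_rts[!is.na(go_rts)]
  if (length(go_rts) == 0L) stop("no go RTs supplied", call. = FALSE)
  if (!is_fraction(p_respond)) stop("p_respond must lie in [0, 1]", call. = FALSE)
  if (p_respond <= 0 || p_respond >= 1) return(NA_real_)
  # tiny slack so p * n that is an integer up to floating-point error (e.g.
  # 0.55 * 100) is not pushed to the next rank by ceiling()
  k <- ceiling(p_respond * length(go_rts) - 1e-9)
  sort(go_rts)[max(k, 1L)]
}

#' Integration-method SSRT with preset stop-signal delays
#'
#' For each SSD level, the stop process's finishing time is estimated at that
#' level's observed response proportion and the SSD is subtracted; the
#' participant's SSRT is the unweighted mean over levels. Levels whose
#' response proportion is exactly 0 or 1 have no defined estimate and are
#' dropped (their count is attached as attribute `dropped_levels`).
#'
#' @param go_rts Go RTs in ms.
#' @param stop_trials Data frame with columns `ssd_ms` and `responded`
#'   (logical/0-1: did the stop trial end in a response).
#' @return SSRT in ms (`NA` if no level has a defined estimate), with
#'   attribute `dropped_levels`.
#' @export
ssrt_preset <- function(go_rts, stop_trials) {
  stop_trials <- as.data.frame(stop_trials)
  stopifnot(all(c("ssd_ms", "responded") %in% names(stop_trials)))
  if (nrow(stop_trials) == 0L) stop("no stop trials supplied", call. = FALSE)
  p_by_ssd <- tapply(as.numeric(stop_trials$responded), stop_trials$ssd_ms, mean)
  ssds <- as.numeric(names(p_by_ssd))
  est <- rep(NA_real_, length(ssds))
  for (i in seq_along(ssds)) {
    ft <- finishing_time(go_rts, p_by_ssd[[i]])
    if (!is.na(ft)) est[i] <- ft - ssds[i]
  }
  dropped <- sum(is.na(est))
  out <- if (all(is.na(est))) NA_real_ else mean(est, na.rm = TRUE)
  attr(out, "dropped_levels") <- dropped
  out
}

#' Integration-method SSRT with staircase stop-signal delays
#'
#' The overall finishing time (at the overall response proportion) minus the
#' mean SSD over all stop trials.
#'
#' @inheritParams ssrt_preset
#' @return SSRT in ms, or `NA` when the overall response proportion is 0 or 1.
#' @export
ssrt_staircase <- function(go_rts, stop_trials) {
  stop_trials <- as.data.frame(stop_trials)
  stopifnot(all(c("ssd_ms", "responded") %in% names(stop_trials)))
  if (nrow(stop_trials) == 0L) stop("no stop trials supplied", call. = FALSE)
  p <- mean(as.numeric(stop_trials$responded))
  ft <- finishing_time(go_rts, p)
  if (is.na(ft)) return(NA_real_)
  ft - mean(stop_trials$ssd_ms)
}

# SSRT under the regime the design prescribes.
ssrt_for_design <- function(go_rts, stop_trials, design) {
  if (length(go_rts) == 0L || nrow(stop_trials) == 0L) return(NA_real_)
  if (design$ssd_policy == "preset") {
    as.numeric(ssrt_preset(go_rts, stop_trials))
  } else {
    ssrt_staircase(go_rts, stop_trials)
  }
}

#' Summarize a session into the participant feature vector
#'
#' Computes every RT-, accuracy- and (in mouse mode) kinematics-based measure
#' for one participant's session: mean/SD of go and stop RTs (responded
#' trials only), go and stop accuracy, direction discrimination accuracy,
#' the probability of responding on stop trials, integration-method SSRT
#' under the design's SSD regime, mean maximum velocity / maximum
#' acceleration / total distance separately for go and stop trials, average
#' stopping distance (per-SSD means averaged), movement initiation time and
#' movement time on go trials -- plus per-coherence variants (suffixes `_c10`,
#' `_c50`, `_c80` for the 10/50/80% coherence levels).
#'
#' On stop trials a "response" for SSRT and accuracy purposes is the trial's
#' inhibition-failure flag (click or cutoff crossing, per the design).
#'
#' @param session An [simulate_session()] result, or a list with `trials`,
#'   `trajectories` and `design`.
#' @param split_by_coherence Compute per-coherence variants? Default `TRUE`.
#' @param move_threshold Movement-initiation threshold in screen units.
#' @return A one-row data frame of class `sst_features`. Undefined cells
#'   (e.g. SSRT at a boundary response proportion) are `NA`.
#' @export
summarize_performance <- function(session, split_by_coherence = TRUE,
                                  move_threshold = 0.01) {
  trials <- session$trials
  design <- session$design
  if (nrow(trials) == 0L) stop("empty session", call. = FALSE)
  mouse <- design$response_mode == "mouse"

  kin <- NULL
  if (mouse && length(session$trajectories) > 0) {
    ids <- trials$trajectory_id
    rows <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- session$trajectories[[ids[i]]]
      if (is.null(tr)) next
      sig <- if (trials$trial_type[i] == "stop") trials$ssd_ms[i] else NA
      end_ms <- if (isTRUE(trials$responded[i])) trials$rt_ms[i] else
        design$response_window_ms
      rows[[i]] <- trial_kinematics(tr, stop_signal_time_ms = sig,
                                    response_or_end_ms = end_ms,
                                    move_threshold = move_threshold)
    }
    kin <- do.call(rbind, rows)
  }

  block <- function(tr, kin_tr, suffix = "") {
    go <- tr[tr$trial_type == "go", , drop = FALSE]
    st <- tr[tr$trial_type == "stop", , drop = FALSE]
    go_resp <- go[go$responded %in% TRUE, , drop = FALSE]
    st_resp <- st[st$responded %in% TRUE, , drop = FALSE]
    go_rts <- go_resp$rt_ms
    p_resp <- if (nrow(st) > 0) mean(st$inhibition_failure) else NA_real_
    correct_go <- go$responded %in% TRUE &
      go$response_direction == go$direction
    out <- data.frame(
      rt_go = if (nrow(go_resp)) mean(go_rts) else NA_real_,
      sd_rt_go = if (nrow(go_resp) > 1) stats::sd(go_rts) else NA_real_,
      acc_go = if (nrow(go)) mean(correct_go) else NA_real_,
      rt_stop = if (nrow(st_resp)) mean(st_resp$rt_ms) else NA_real_,
      sd_rt_stop = if (nrow(st_resp) > 1) stats::sd(st_resp$rt_ms) else NA_real_,
      acc_stop = if (nrow(st)) 1 - p_resp else NA_real_,
      direction_discrimination_acc = if (nrow(go_resp))
        mean(go_resp$response_direction == go_resp$direction) else NA_real_,
      p_respond_stop = p_resp,
      ssrt = if (nrow(st) > 0 && length(go_rts) > 0)
        ssrt_for_design(go_rts, data.frame(ssd_ms = st$ssd_ms,
                                           responded = st$inhibition_failure),
                        design) else NA_real_
    )
    if (!is.null(kin_tr)) {
      kg <- kin_tr[tr$trial_type == "go", , drop = FALSE]
      ks <- kin_tr[tr$trial_type == "stop", , drop = FALSE]
      out$velocity_go <- mean(kg$max_velocity)
      out$acceleration_go <- mean(kg$max_acceleration)
      out$distance_go <- mean(kg$total_distance)
      out$velocity_stop <- if (nrow(ks)) mean(ks$max_velocity) else NA_real_
      out$acceleration_stop <- if (nrow(ks)) mean(ks$max_acceleration) else NA_real_
      out$distance_stop <- if (nrow(ks)) mean(ks$total_distance) else NA_real_
      out$stopping_distance <- if (nrow(st))
        average_stopping_distance(data.frame(ssd_ms = st$ssd_ms,
                                             delta = ks$stopping_distance)) else NA_real_
      out$initiation_go <- mean(kg$initiation_time_ms, na.rm = TRUE)
      out$movement_time_go <- mean(kg$movement_time_ms, na.rm = TRUE)
    }
    if (nzchar(suffix)) names(out) <- paste0(names(out), suffix)
    out
  }

  res <- block(trials, kin)
  if (split_by_coherence) {
    for (coh in sort(unique(trials$coherence))) {
      sel <- trials$coherence == coh
      res <- cbind(res, block(trials[sel, , drop = FALSE],
                              if (is.null(kin)) NULL else kin[sel, , drop = FALSE],
                              suffix = sprintf("_c%d", round(100 * coh))))
    }
  }
  class(res) <- c("sst_features", "data.frame")
  res
}
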