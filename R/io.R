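# File formats and the pipeline driver. One CSV dialect throughout: comma
# separated, UTF-8, header row, "." decimal; durations in ms, coordinates in
# centered normalized screen units.

#' Write / read the trial table
#'
#' One row per trial with participant and outcome metadata:
#' `participant_id, trial_index, trial_type, coherence, direction, ssd_ms,
#' responded, response_direction, rt_ms, inhibition_failure, points,
#' trajectory_id`.
#'
#' @param sessions A list of `sst_session` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(sessions, path) {
  if (inherits(sessions, "sst_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    tr <- s$trials
    data.frame(participant_id = s$participant_id,
               trial_index = tr$index,
               trial_type = tr$trial_type,
               coherence = tr$coherence,
               direction = tr$direction,
               ssd_ms = tr$ssd_ms,
               responded = as.integer(tr$responded),
               response_direction = tr$response_direction,
               rt_ms = tr$rt_ms,
               inhibition_failure = ifelse(is.na(tr$inhibition_failure), NA,
                                           as.integer(tr$inhibition_failure)),
               points = tr$points,
               trajectory_id = tr$trajectory_id)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "trial_index", "trial_type", "coherence",
              "responded")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("trial table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$responded <- df$responded == 1
  if ("inhibition_failure" %in% names(df)) {
    df$inhibition_failure <- ifelse(is.na(df$inhibition_failure), NA,
                                    df$inhibition_failure == 1)
  }
  df
}

#' Write cursor trajectories to CSV
#'
#' Long format: `participant_id, trial_index, t_ms, x, y`, one row per
#' recorded sample.
#'
#' @param sessions A list of `sst_session` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(sessions, path) {
  if (inherits(sessions, "sst_session")) sessions <- list(sessions)
  rows <- list()
  for (s in sessions) {
    for (id in names(s$trajectories)) {
      tr <- s$trajectories[[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = s$participant_id,
        trial_index = as.integer(id),
        t_ms = tr$t_ms, x = tr$x, y = tr$y)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read cursor trajectories from CSV
#'
#' Groups samples by participant and trial and checks that each trial's
#' timestamps are strictly increasing; a violation is reported with the
#' offending participant and trial.
#'
#' @param path CSV with header `participant_id, trial_index, t_ms, x, y`.
#' @return A nested list: `result[[participant]][[trial]]` is an
#'   `sst_trajectory` (keys are the character ids).
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "trial_index", "t_ms", "x", "y")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("trajectory file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !stats::complete.cases(df[needed])
  if (any(bad)) {
    stop("malformed trajectory rows at lines: ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (pid in unique(df$participant_id)) {
    sub <- df[df$participant_id == pid, ]
    trials <- list()
    for (tid in unique(sub$trial_index)) {
      tt <- sub[sub$trial_index == tid, ]
      if (any(diff(tt$t_ms) <= 0)) {
        stop(sprintf("non-monotone timestamps in participant %s, trial %s",
                     pid, tid), call. = FALSE)
      }
      trials[[as.character(tid)]] <- trajectory(tt$t_ms, tt$x, tt$y)
    }
    out[[as.character(pid)]] <- trials
  }
  out
}

#' Run the full simulate-to-predict pipeline
#'
#' Executes the enabled stages in order -- simulate (sessions + scores),
#' features (participant feature table), associate (Spearman/BH tables) and
#' predict (nested-CV bootstrap ridge) -- writing each stage's CSV/JSON
#' outputs and a manifest with the configuration, per-stage seeds and MD5
#' content hashes of every output file. Identical configurations produce
#' byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_participants Number of simulated participants.
#' @param profile,response_mode Passed to [session_design()].
#' @param scenario Passed to [population_config()].
#' @param seed Master seed; every stage seed is derived from it.
#' @param stages Character subset of
#'   `c("simulate", "features", "associate", "predict")`.
#' @param n_boot Bootstrap replicates for the predict stage.
#' @param predict_subscale Subscale predicted in the predict stage.
#' @param design Optional [session_design()] overriding the profile default
#'   (e.g. a session with fewer trials).
#' @return The output directory path, invisibly; the manifest lists all files.
#' @export
run_pipeline <- function(out_dir, n_participants = 50,
                         profile = "exp1", response_mode = "mouse",
                         scenario = "adhd_gradient", seed = 1,
                         stages = c("simulate", "features", "associate",
                                    "predict"),
                         n_boot = 200, predict_subscale = "C",
                         design = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design)) design <- session_design(profile, response_mode)
  geometry <- sst_geometry()
  population <- population_config(scenario)
  files <- character(0)

  study <- simulate_study(n_participants, design, geometry, population,
                          seed = seed, keep_sessions = "simulate" %in% stages)
  if ("simulate" %in% stages) {
    f1 <- file.path(out_dir, "trial_table.csv")
    write_trial_table(study$sessions, f1)
    files <- c(files, f1)
    if (response_mode == "mouse") {
      f2 <- file.path(out_dir, "trajectories.csv")
      write_trajectories(study$sessions, f2)
      files <- c(files, f2)
    }
    f3 <- file.path(out_dir, "questionnaire_scores.csv")
    utils::write.csv(study$scores, f3, row.names = FALSE)
    files <- c(files, f3)
  }
  if ("features" %in% stages) {
    f <- file.path(out_dir, "participant_features.csv")
    utils::write.csv(study$features, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("associate" %in% stages) {
    tabs <- build_association_tables(study$features, study$scores)
    flat <- do.call(rbind, lapply(tabs, as.data.frame))
    f <- file.path(out_dir, "association_tables.csv")
    utils::write.csv(flat, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("predict" %in% stages) {
    Xcols <- c("velocity_go", "acceleration_go", "distance_go",
               "velocity_stop", "acceleration_stop", "distance_stop",
               "stopping_distance", "initiation_go", "movement_time_go")
    Xcols <- intersect(Xcols, names(study$features))
    if (length(Xcols) == 0L) {
      Xcols <- c("rt_go", "sd_rt_go", "acc_go", "rt_stop", "sd_rt_stop",
                 "acc_stop", "direction_discrimination_acc", "ssrt")
      Xcols <- intersect(Xcols, names(study$features))
    }
    keep <- stats::complete.cases(study$features[Xcols])
    rep <- nested_cv_bootstrap(as.matrix(study$features[keep, Xcols]),
                               study$scores[[predict_subscale]][keep],
                               n_boot = n_boot, seed = stage_seed(seed, 9))
    f <- file.path(out_dir, "prediction_report.json")
    jsonlite::write_json(list(subscale = predict_subscale,
                              rho_median = rep$rho_median,
                              rho_mad = rep$rho_mad,
                              n_replicates = rep$n_replicates,
                              n_missing = rep$n_missing,
                              rho = rep$rho),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  manifest <- list(
    config = list(n_participants = n_participants, profile = profile,
                  response_mode = response_mode, scenario = scenario,
                  seed = seed, stages = stages, n_boot = n_boot,
                  predict_subscale = predict_subscale),
    package_version = as.character(utils::packageVersion("sstmouse")),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
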