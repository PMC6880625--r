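# Latent-trait population model: participant parameters and questionnaire
# scores. Two latent z-scored traits -- impulsivity and inattention -- jointly
# drive (a) race-model finishing times, (b) cursor kinematics and (c) noisy
# questionnaire subscale scores, giving the synthetic data the correlational
# structure the downstream analyses look for.

#' Population configuration for the trait-driven simulator
#'
#' Defines the latent-trait distribution, the monotone links from traits to
#' task parameters, and the subscale loadings of the questionnaire generator.
#' Two named scenarios are provided:
#'
#' * `"adhd_gradient"`: impulsivity loads on subscales C and F, inattention on
#'   A and E; impulsivity raises peak cursor speed and weakens braking
#'   (lengthening the post-signal stopping distance); inattention inflates
#'   go-RT dispersion and the lapse rate.
#' * `"null"`: identical task generation but all questionnaire loadings are
#'   zero, so scores are pure noise -- the calibration scenario.
#'
#' @param scenario `"adhd_gradient"` or `"null"`.
#' @param trait_correlation Correlation between impulsivity and inattention.
#' @param reliability Questionnaire score reliability (signal variance
#'   fraction) used to set the noise SD; ignored for zero-loading subscales.
#' @param ... Named overrides of any configuration entry.
#' @return An object of class `sst_population` (a named list).
#' @export
population_config <- function(scenario = c("adhd_gradient", "null"),
                              trait_correlation = 0.3,
                              reliability = 0.8, ...) {
  scenario <- match.arg(scenario)
  loadings <- if (scenario == "null") {
    matrix(0, nrow = 4, ncol = 2,
           dimnames = list(c("C", "F", "A", "E"), c("impulsivity", "inattention")))
  } else {
    matrix(c(1.0, 0.2,   # C: Impulsivity/Emotional lability
             0.9, 0.3,   # F: Hyperactive/Impulsive
             0.15, 1.0,  # A: Inattention/Memory problems
             0.25, 0.9), # E: Inattentive
           nrow = 4, byrow = TRUE,
           dimnames = list(c("C", "F", "A", "E"), c("impulsivity", "inattention")))
  }
  cfg <- list(
    scenario = scenario,
    trait_correlation = trait_correlation,
    # keypress go process: lognormal finishing times, slower at low coherence
    rt_median_ms = 650,        # median go RT at the easiest coherence
    coh_slowing = 0.35,        # relative slowing per unit coherence below 0.8
    go_sigma_log = 0.22,       # baseline lognormal sigma of go RTs
    rt_person_sd_log = 0.08,   # between-participant RT level variation
    ssrt_mean_ms = 250,        # mean true stop-process latency
    ssrt_sd_ms = 30,           # between-participant SSRT variation
    direction_slope = 5.5,     # logistic slope of direction accuracy in coherence
    # mouse movement parameters
    init_mu_ms = 300,          # mean movement initiation time
    init_sd_ms = 80,           # within-participant initiation SD
    init_person_sd_log = 0.12, # between-participant initiation variation
    # 3.6 units/s puts the deterministic braking margin at zero for a stop
    # signal finishing at 850 ms (SSD 600 + SSRT 250): failures are ~50%
    # there, the anchor the staircase profile starts from
    peak_speed = 3.6,          # screen units / s
    peak_trial_sd_log = 0.12,  # within-participant peak-speed variation
    brake_decel = 15,          # screen units / s^2
    param_person_sd_log = 0.1, # between-participant kinematic variation
    lapse_base = 0.02,         # baseline attentional lapse probability
    jitter_sd = 0.002,         # per-sample cursor jitter while moving
    # trait -> parameter gains (log scale unless stated)
    gain_imp_speed = 0.15,     # impulsivity -> peak speed
    gain_imp_brake = 0.15,     # impulsivity -> weaker braking
    gain_inatt_sigma = 0.2,    # inattention -> go-RT dispersion
    gain_inatt_lapse = 0.5,    # inattention -> lapse log-odds
    # questionnaire generator
    loadings = loadings,
    reliability = reliability,
    score_mean = 50,
    score_sd = 10
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown population settings: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "sst_population")
}

#' Draw a participant sample from the trait population
#'
#' Latent traits come from a bivariate standard normal with the configured
#' correlation; every task parameter is a monotone (log-linear or logistic)
#' function of the traits plus independent person-level noise.
#'
#' @param n Number of participants.
#' @param population A [population_config()].
#' @param seed Integer seed.
#' @return A data frame of class `sst_traits`, one row per participant, with
#'   the latent traits and all derived simulator parameters.
#' @export
sample_participants <- function(n, population = population_config(), seed = NULL) {
  stopifnot(is_count(n), n >= 1)
  p <- population
  r <- p$trait_correlation
  if (abs(r) >= 1) stop("trait covariance is not positive definite", call. = FALSE)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    out <- data.frame(
      participant_id = seq_len(n),
      impulsivity = z1,
      inattention = z2,
      ssrt_true_ms = pmax(50, stats::rnorm(n, p$ssrt_mean_ms, p$ssrt_sd_ms)),
      rt_level_log = stats::rnorm(n, 0, p$rt_person_sd_log),
      go_sigma_log = p$go_sigma_log * exp(p$gain_inatt_sigma * z2),
      init_mu_ms = p$init_mu_ms * exp(stats::rnorm(n, 0, p$init_person_sd_log)),
      peak_speed = p$peak_speed *
        exp(p$gain_imp_speed * z1 + stats::rnorm(n, 0, p$param_person_sd_log)),
      brake_decel = p$brake_decel *
        exp(-p$gain_imp_brake * z1 + stats::rnorm(n, 0, p$param_person_sd_log)),
      lapse_rate = stats::plogis(stats::qlogis(p$lapse_base) +
                                   p$gain_inatt_lapse * z2)
    )
    class(out) <- c("sst_traits", "data.frame")
    out
  })
}

# Median go finishing time (ms) for one participant at one coherence level.
go_median_ms <- function(population, traits_row, coherence) {
  population$rt_median_ms * (1 + population$coh_slowing * (0.8 - coherence)) *
    exp(traits_row$rt_level_log)
}

#' Generate questionnaire subscale scores
#'
#' Each subscale score is a linear combination of the two latent traits plus
#' Gaussian noise, rescaled to the configured mean and SD (T-score
#' convention). The noise SD is set from the configured reliability: for a
#' subscale with signal SD s and reliability r, noise SD = s * sqrt((1-r)/r),
#' so the score-trait correlation is about sqrt(r). Zero-loading subscales are
#' pure noise.
#'
#' @param traits An `sst_traits` data frame from [sample_participants()].
#' @param population A [population_config()] supplying loadings, reliability
#'   and score scale.
#' @param seed Integer seed.
#' @return A data frame with `participant_id` and columns `C`, `F`, `A`, `E`.
#' @export
questionnaire_scores <- function(traits, population = population_config(),
                                 seed = NULL) {
  L <- population$loadings
  tz <- as.matrix(traits[, c("impulsivity", "inattention")])
  with_seed(seed, {
    out <- data.frame(participant_id = traits$participant_id)
    for (s in rownames(L)) {
      signal <- as.numeric(tz %*% L[s, ])
      s_sd <- sqrt(sum(L[s, ]^2) + 2 * prod(L[s, ]) * population$trait_correlation)
      noise_sd <- if (s_sd > 0) {
        s_sd * sqrt((1 - population$reliability) / population$reliability)
      } else 1
      raw <- signal + stats::rnorm(nrow(traits), 0, noise_sd)
      tot_sd <- sqrt(s_sd^2 + noise_sd^2)
      out[[s]] <- population$score_mean + population$score_sd * raw / tot_sd
    }
    out
  })
}
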