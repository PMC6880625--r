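# Shared fixture builders. Everything is generated in code; no stored data.

# A small session design that keeps simulation cheap in tests.
tiny_design <- function(profile = "exp1", response_mode = "keypress",
                        n_trials = 48L, n_stop = 12L, ...) {
  session_design(profile, response_mode, n_trials = n_trials, n_stop = n_stop,
                 ...)
}

# Straight constant-speed trajectory from `from` to `to` over `dur_ms`.
line_trajectory <- function(from = c(0, -0.8), to = c(0.6, 0.7),
                            dur_ms = 1000, dt = 16, t_start = 0) {
  tt <- seq(0, dur_ms, by = dt)
  frac <- tt / dur_ms
  trajectory(t_start + tt, from[1] + frac * (to[1] - from[1]),
             from[2] + frac * (to[2] - from[2]))
}

# Random jagged trajectory with n samples (seeded by caller).
random_trajectory <- function(n, dt = 16) {
  trajectory(cumsum(stats::runif(n, 1, dt)),
             cumsum(stats::rnorm(n, 0, 0.02)),
             cumsum(stats::rnorm(n, 0, 0.02)))
}

# Brute-force total path length (independent loop oracle).
oracle_total_distance <- function(traj) {
  d <- 0
  for (i in seq_len(length(traj$t_ms) - 1)) {
    d <- d + sqrt((traj$x[i + 1] - traj$x[i])^2 + (traj$y[i + 1] - traj$y[i])^2)
  }
  d
}

oracle_max_velocity <- function(traj) {
  best <- -Inf
  for (i in seq_len(length(traj$t_ms) - 1)) {
    seg <- sqrt((traj$x[i + 1] - traj$x[i])^2 + (traj$y[i + 1] - traj$y[i])^2)
    best <- max(best, seg / ((traj$t_ms[i + 1] - traj$t_ms[i]) / 1000))
  }
  best
}

oracle_max_acceleration <- function(traj) {
  n <- length(traj$t_ms)
  v <- numeric(n - 1); mid <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    seg <- sqrt((traj$x[i + 1] - traj$x[i])^2 + (traj$y[i + 1] - traj$y[i])^2)
    v[i] <- seg / ((traj$t_ms[i + 1] - traj$t_ms[i]) / 1000)
    mid[i] <- (traj$t_ms[i] + traj$t_ms[i + 1]) / 2000
  }
  best <- -Inf
  for (i in seq_len(n - 2)) {
    best <- max(best, abs(v[i + 1] - v[i]) / (mid[i + 1] - mid[i]))
  }
  best
}

# Split-and-sum oracle for the path length after the stop signal.
oracle_stopping_distance <- function(traj, ts) {
  n <- length(traj$t_ms)
  if (n < 2 || ts >= traj$t_ms[n]) return(0)
  d <- 0
  for (i in seq_len(n - 1)) {
    seg <- sqrt((traj$x[i + 1] - traj$x[i])^2 + (traj$y[i + 1] - traj$y[i])^2)
    t0 <- traj$t_ms[i]; t1 <- traj$t_ms[i + 1]
    if (ts <= t0) {
      d <- d + seg
    } else if (ts < t1) {
      d <- d + seg * (t1 - ts) / (t1 - t0)
    }
  }
  d
}

# Sort-then-index oracle for the finishing-time order statistic.
oracle_finishing_time <- function(go_rts, p) {
  srt <- sort(go_rts)
  srt[ceiling(p * length(srt))]
}

# Rank-then-Pearson oracle for Spearman's rho (average ranks for ties),
# written as explicit loops so it shares no code with the implementation.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exhaustive BH step-up oracle: try every k and reject 1..k_max.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= k * q / m) k_max <- k
  flags <- rep(FALSE, m)
  if (k_max > 0) flags[ord[seq_len(k_max)]] <- TRUE
  flags
}

# Brute-force two-sample KS statistic: scan the ECDF gap at every data point.
oracle_ks_D <- function(x, y) {
  best <- 0
  for (v in c(x, y)) {
    best <- max(best, abs(mean(x <= v) - mean(y <= v)))
  }
  best
}

# Gradient-descent oracle for the ridge solution on standardized predictors.
oracle_ridge <- function(X, y, lambda, iters = 200000, lr = NULL) {
  Z <- scale(X)
  yc <- y - mean(y)
  p <- ncol(Z)
  beta <- rep(0, p)
  G <- crossprod(Z)
  if (is.null(lr)) lr <- 1 / (max(eigen(G, only.values = TRUE)$values) + lambda)
  for (i in seq_len(iters)) {
    grad <- -crossprod(Z, yc - Z %*% beta) + lambda * beta
    beta <- beta - lr * grad
  }
  as.numeric(beta)
}

# One participant with fixed, noise-free trait links for deterministic tests.
fixed_traits <- function(ssrt = 250, peak = 3.6, brake = 15, lapse = 0) {
  data.frame(participant_id = 1L, impulsivity = 0, inattention = 0,
             ssrt_true_ms = ssrt, rt_level_log = 0, go_sigma_log = 0.22,
             init_mu_ms = 300, peak_speed = peak, brake_decel = brake,
             lapse_rate = lapse)
}
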