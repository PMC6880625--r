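# Ridge regression with cross-validated regularization and the nested
# bootstrap evaluation protocol.

# Standardization learned on training rows only. Zero-variance columns are
# flagged: they standardize to 0 so their coefficient is exactly 0.
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  sds[zero] <- 1
  list(mu = mu, sd = sds, zero = zero)
}

standardize_apply <- function(X, sc) {
  Z <- sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
  Z[, sc$zero] <- 0
  Z
}

#' Fit a ridge regression model
#'
#' Standardizes the predictors (mean 0, SD 1, learned from the supplied
#' rows), then solves the penalized least-squares normal equations
#' `(Z'Z + lambda I) beta = Z'y` with an unpenalized intercept (the mean of
#' `y`, since the columns of `Z` are centered). Zero-variance predictors get
#' coefficient exactly 0 and are flagged.
#'
#' @param X Numeric feature matrix (rows = participants), no missing cells.
#' @param y Numeric outcome vector.
#' @param lambda Non-negative regularization weight.
#' @return An object of class `sst_ridge` with elements `lambda`,
#'   `coefficients` (standardized scale), `intercept`, `feature_means`,
#'   `feature_sds`, `zero_variance`.
#' @export
ridge_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing cells are not allowed", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("X and y sizes disagree", call. = FALSE)
  sc <- standardize_fit(X)
  Z <- standardize_apply(X, sc)
  p <- ncol(Z)
  A <- crossprod(Z) + diag(lambda, p)
  beta <- tryCatch(as.numeric(solve(A, crossprod(Z, y - mean(y)))),
                   error = function(e) as.numeric(qr.solve(A, crossprod(Z, y - mean(y)))))
  beta[sc$zero] <- 0
  names(beta) <- colnames(X)
  structure(list(lambda = lambda, coefficients = beta, intercept = mean(y),
                 feature_means = sc$mu, feature_sds = sc$sd,
                 zero_variance = sc$zero),
            class = "sst_ridge")
}

#' @export
coef.sst_ridge <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
predict.sst_ridge <- function(object, newdata, ...) {
  Z <- standardize_apply(as.matrix(newdata),
                         list(mu = object$feature_means,
                              sd = object$feature_sds,
                              zero = object$zero_variance))
  as.numeric(object$intercept + Z %*% object$coefficients)
}

#' @export
print.sst_ridge <- function(x, ...) {
  cat(sprintf("Ridge regression fit (lambda = %g, %d predictors%s)\n",
              x$lambda, length(x$coefficients),
              if (any(x$zero_variance))
                sprintf(", %d zero-variance", sum(x$zero_variance)) else ""))
  print(round(coef(x), 4))
  invisible(x)
}

# SVD path: coefficients for every lambda on one training set, plus held-out
# predictions. Used by the CV loops so each training set is factored once.
ridge_path_predict <- function(X_tr, y_tr, X_te, lambdas) {
  sc <- standardize_fit(X_tr)
  Z <- standardize_apply(X_tr, sc)
  Zt <- standardize_apply(X_te, sc)
  yc <- y_tr - mean(y_tr)
  sv <- svd(Z)
  uy <- crossprod(sv$u, yc)
  # beta(lambda) = V diag(d / (d^2 + lambda)) U'yc
  sapply(lambdas, function(l) {
    beta <- sv$v %*% (uy * sv$d / (sv$d^2 + l))
    as.numeric(mean(y_tr) + Zt %*% beta)
  })
}

default_lambda_grid <- function() exp(seq(log(1e-4), log(1e4), length.out = 60))

# Seeded fold labels for n rows, optionally constrained so rows with the
# same group label share a fold (uses the current RNG state).
assign_folds <- function(n, k, groups = NULL) {
  if (is.null(groups)) return(sample(rep_len(seq_len(k), n)))
  stopifnot(length(groups) == n)
  ids <- unique(groups)
  fold_of_id <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
  unname(fold_of_id[as.character(groups)])
}

#' Select the ridge penalty by k-fold cross-validation
#'
#' Partitions the rows into `k` seeded folds; for each candidate lambda the
#' mean squared prediction error over held-out folds is computed, with
#' standardization refit on every training split. Returns the lambda with
#' the smallest CV-MSE (the smallest such lambda on ties).
#'
#' @param X Feature matrix. @param y Outcome vector.
#' @param lambda_grid Candidate lambdas (default: 60 log-spaced values in
#'   `[1e-4, 1e4]`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param groups Optional grouping vector (length `nrow(X)`): rows sharing a
#'   group label are assigned to the same fold. Used when rows are bootstrap
#'   copies of the same participant, so a participant never sits on both
#'   sides of a split.
#' @return The selected lambda (invisibly carries the CV-MSE curve as
#'   attribute `cv_mse`).
#' @export
select_lambda_cv <- function(X, y, lambda_grid = default_lambda_grid(),
                             k = 10, seed = NULL, groups = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  if (length(lambda_grid) == 0L) stop("empty lambda grid", call. = FALSE)
  k <- min(k, n)  # small training sets fall back to leave-one-out
  lambda_grid <- sort(lambda_grid)
  folds <- with_seed(seed, assign_folds(n, k, groups))
  se <- matrix(NA_real_, n, length(lambda_grid))
  for (f in seq_len(k)) {
    te <- folds == f
    if (!any(te) || all(te)) next
    pred <- ridge_path_predict(X[!te, , drop = FALSE], y[!te],
                               X[te, , drop = FALSE], lambda_grid)
    se[te, ] <- (pred - y[te])^2
  }
  if (anyNA(se)) se <- se[stats::complete.cases(se), , drop = FALSE]
  mse <- colMeans(se)
  best <- lambda_grid[which.min(mse)]  # which.min takes the first = smallest
  attr(best, "cv_mse") <- stats::setNames(mse, signif(lambda_grid, 4))
  best
}

#' Nested cross-validated bootstrap evaluation of ridge prediction
#'
#' The prediction-performance protocol: in each of `n_boot` replicates the
#' participants are resampled with replacement, split into `outer_k` folds,
#' and for every outer fold the penalty is chosen by `inner_k`-fold CV on
#' the outer-training rows only, the model is fit there, and the outer-test
#' rows are predicted. Each replicate yields one Spearman correlation between
#' predictions and observed scores: the mean of the per-outer-fold
#' correlations (Spearman is invariant to the per-fold intercept, so this
#' measures predictive ordering rather than the fold-mean artifact that a
#' pooled correlation picks up). The report summarizes
#' the replicate correlations by their median and median absolute deviation
#' (raw MAD, no consistency scaling). Model selection and assessment are
#' fully separated: folds (outer and inner) are assigned at the level of the
#' original participants, so all bootstrap copies of a participant fall on
#' one side of every split and no participant's rows influence
#' standardization, lambda selection or fitting for their own prediction.
#'
#' @param X Feature matrix. @param y Outcome vector.
#' @param outer_k,inner_k Outer and inner fold counts (defaults 5 and 10).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param lambda_grid Candidate penalties.
#' @param seed Master integer seed.
#' @return An object of class `sst_prediction` with `rho` (per-replicate
#'   vector, `NA` where a replicate's pooled test outcomes were constant),
#'   `rho_median`, `rho_mad`, `n_replicates`, `n_missing`.
#' @export
nested_cv_bootstrap <- function(X, y, outer_k = 5, inner_k = 10, n_boot = 1000,
                                lambda_grid = default_lambda_grid(),
                                seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < outer_k) stop("need at least outer_k rows", call. = FALSE)
  rhos <- rep(NA_real_, n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      folds <- assign_folds(n, outer_k, groups = idx)
      fold_rho <- rep(NA_real_, outer_k)
      for (f in seq_len(outer_k)) {
        te <- folds == f
        if (!any(te) || all(te)) next
        lam <- select_lambda_cv(Xb[!te, , drop = FALSE], yb[!te],
                                lambda_grid, k = inner_k,
                                groups = idx[!te])
        fit <- ridge_fit(Xb[!te, , drop = FALSE], yb[!te], lam)
        pred <- predict(fit, Xb[te, , drop = FALSE])
        obs <- yb[te]
        if (length(obs) >= 4 && stats::sd(obs) > 0 && stats::sd(pred) > 0) {
          fold_rho[f] <- spearman_rho(pred, obs)$rho
        }
      }
      if (any(!is.na(fold_rho))) rhos[b] <- mean(fold_rho, na.rm = TRUE)
    }
  })
  structure(list(rho = rhos,
                 rho_median = stats::median(rhos, na.rm = TRUE),
                 rho_mad = stats::mad(rhos, constant = 1, na.rm = TRUE),
                 n_replicates = n_boot,
                 n_missing = sum(is.na(rhos)),
                 outer_k = outer_k, inner_k = inner_k),
            class = "sst_prediction")
}

#' @export
print.sst_prediction <- function(x, ...) {
  cat(sprintf(
    "Nested-CV bootstrap prediction report (%d-in-%d-fold, %d replicates%s)\n",
    x$inner_k, x$outer_k, x$n_replicates,
    if (x$n_missing > 0) sprintf(", %d undefined", x$n_missing) else ""))
  cat(sprintf("  median rho = %.3f (MAD %.3f)\n", x$rho_median, x$rho_mad))
  invisible(x)
}

#' Ridge coefficient profile at the cross-validated penalty
#'
#' Selects the penalty by [select_lambda_cv()], fits on the full data, and
#' returns the standardized-scale coefficients ranked by absolute value --
#' a coefficient nearer zero indicates a less important feature.
#'
#' @inheritParams select_lambda_cv
#' @return A data frame with `feature`, `coefficient`, `abs_coefficient`,
#'   ordered by decreasing importance; the selected lambda is attached as
#'   attribute `lambda`.
#' @export
coefficient_profile <- function(X, y, lambda_grid = default_lambda_grid(),
                                seed = NULL) {
  lam <- select_lambda_cv(X, y, lambda_grid, seed = seed)
  fit <- ridge_fit(X, y, as.numeric(lam))
  ord <- order(abs(fit$coefficients), decreasing = TRUE)
  out <- data.frame(feature = names(fit$coefficients)[ord],
                    coefficient = unname(fit$coefficients[ord]),
                    abs_coefficient = unname(abs(fit$coefficients[ord])))
  attr(out, "lambda") <- as.numeric(lam)
  out
}
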