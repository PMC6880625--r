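# Association statistics: Spearman rank correlation, Benjamini-Hochberg FDR
# control, two-sample Kolmogorov-Smirnov comparison, and the feature-by-
# subscale association tables.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks both vectors (average ranks for ties) over pairwise-complete
#' observations and computes the Pearson correlation of the ranks. The
#' two-sided p-value comes from the t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 4 complete pairs).
#' @return A list with `rho`, `p` and `n` (complete pairs). Zero rank
#'   variance in either vector gives `rho = NA` with `p = NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Applies the BH step-up rule at level `q`: with the m p-values sorted
#' ascending, the largest k with p(k) <= k q / m is found and hypotheses
#' 1..k are rejected. Flags are returned in input order; `NA` p-values are
#' never rejected and do not count toward m.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param q Target false-discovery rate (default 0.05).
#' @return Logical vector of rejections.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(is.numeric(pvals))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(FALSE, length(pvals))
  if (any(ok)) out[ok] <- stats::p.adjust(pvals[ok], method = "BH") <= q
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over thresholds of the absolute difference between the
#' two empirical CDFs; the p-value uses the asymptotic Kolmogorov
#' distribution evaluated at sqrt(n_eff) * D with effective sample size
#' n_eff = n_x n_y / (n_x + n_y).
#'
#' @param x,y Nonempty numeric vectors.
#' @return A list with `D`, `p`, and `n_eff`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty",
                                               call. = FALSE)
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  D <- max(abs(Fx - Fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  t <- sqrt(n_eff) * D
  # asymptotic Kolmogorov survival function: 2 * sum (-1)^(k-1) exp(-2 k^2 t^2)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(D = D, p = clamp(p, 0, 1), n_eff = n_eff)
}

#' Build feature-by-subscale association tables
#'
#' Computes Spearman correlations between every participant feature and every
#' questionnaire subscale, with BH false-discovery-rate control applied
#' within each table family (one printed table = one family). The default
#' families are the overall measures and the per-coherence variants.
#'
#' @param features Data frame with `participant_id` and numeric feature
#'   columns (e.g. from [simulate_study()]).
#' @param scores Data frame with `participant_id` and subscale columns.
#' @param families Named list mapping a family label to the feature columns
#'   of that table. `NULL` builds the default families from the columns
#'   present: `overall` (unsuffixed measures) plus one per coherence suffix.
#' @param subscales Score columns to use (default: all but `participant_id`).
#' @param q FDR level (default 0.05).
#' @return A list of `sst_assoc` objects (one per family), each with matrices
#'   `rho`, `p`, `fdr_significant`, the family label and the FDR level.
#' @export
build_association_tables <- function(features, scores, families = NULL,
                                     subscales = NULL, q = 0.05) {
  merged <- merge(features, scores, by = "participant_id")
  if (nrow(merged) < 4L) stop("fewer than 4 aligned participants", call. = FALSE)
  if (is.null(subscales)) subscales <- setdiff(names(scores), "participant_id")
  feat_cols <- setdiff(names(features), "participant_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  if (is.null(families)) {
    suffixes <- unique(regmatches(feat_cols, regexpr("_c[0-9]+$", feat_cols)))
    base_cols <- feat_cols[!grepl("_c[0-9]+$", feat_cols)]
    families <- list(overall = base_cols)
    for (s in suffixes) {
      families[[sub("^_", "", s)]] <- feat_cols[endsWith(feat_cols, s)]
    }
  }
  lapply(names(families), function(fam) {
    cols <- intersect(families[[fam]], feat_cols)
    rho <- p <- nmat <- matrix(NA_real_, length(cols), length(subscales),
                               dimnames = list(cols, subscales))
    for (f in cols) for (s in subscales) {
      # cells with fewer than 4 complete pairs stay NA (pairwise deletion)
      res <- tryCatch(spearman_rho(merged[[f]], merged[[s]]),
                      error = function(e) list(rho = NA_real_, p = NA_real_,
                                               n = NA_real_))
      rho[f, s] <- res$rho; p[f, s] <- res$p; nmat[f, s] <- res$n
    }
    flags <- matrix(bh_fdr(as.vector(p), q), nrow(p), ncol(p),
                    dimnames = dimnames(p))
    structure(list(rho = rho, p = p, fdr_significant = flags, n = nmat,
                   family = fam, q = q),
              class = "sst_assoc")
  }) -> out
  names(out) <- names(families)
  out
}

#' @export
print.sst_assoc <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman association table (family '%s', BH FDR q = %g)\n",
              x$family, x$q))
  stars <- ifelse(is.na(x$p), "", ifelse(x$p < .001, "***",
                  ifelse(x$p < .01, "**", ifelse(x$p < .05, "*", ""))))
  cells <- matrix(paste0(format(round(x$rho, digits), nsmall = digits), stars,
                         ifelse(x$fdr_significant, " [FDR]", "")),
                  nrow(x$rho), ncol(x$rho), dimnames = dimnames(x$rho))
  print(cells, quote = FALSE)
  cat("* p < .05, ** p < .01, *** p < .001; [FDR] significant after BH control\n")
  invisible(x)
}

#' @export
as.data.frame.sst_assoc <- function(x, ...) {
  data.frame(family = x$family,
             feature = rep(rownames(x$rho), ncol(x$rho)),
             subscale = rep(colnames(x$rho), each = nrow(x$rho)),
             rho = as.vector(x$rho),
             p = as.vector(x$p),
             n = as.vector(x$n),
             fdr_significant = as.vector(x$fdr_significant))
}
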