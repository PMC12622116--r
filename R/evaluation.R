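#' Genomic inflation factor
#'
#' Ratio of the median observed test statistic to the median of the null
#' chi-square distribution with the stated degrees of freedom. Values above
#' 1 indicate inflation, below 1 deflation. Either statistics or p-values
#' may be supplied; p-values are converted through the upper-tail chi-square
#' quantile function at `df`.
#'
#' @param stats nonnegative chi-square statistics (ignored if `pvalues`
#'   given).
#' @param df degrees of freedom of the null distribution.
#' @param pvalues optional p-values in (0, 1].
#' @return the inflation factor (a positive scalar).
#' @export
genomicInflation <- function(stats = NULL, df, pvalues = NULL) {
  stopifnot(df >= 1)
  if (!is.null(pvalues)) {
    pvalues <- pvalues[!is.na(pvalues)]
    if (!length(pvalues)) stop("no p-values supplied")
    stats <- stats::qchisq(pvalues, df, lower.tail = FALSE)
  }
  stats <- stats[!is.na(stats)]
  if (!length(stats)) stop("no statistics supplied")
  stats::median(stats) / stats::qchisq(0.5, df)
}

#' Empirical type I error relative to a significance level
#'
#' Computes the fraction of p-values at or below `alpha` divided by `alpha`
#' (so a calibrated test gives 1) and a binomial standard error on the same
#' ratio scale.
#'
#' @param pvalues p-values under the null.
#' @param alpha significance level in (0, 1).
#' @return named numeric `c(ratio, se, n, exceedances)`.
#' @export
empiricalTypeIError <- function(pvalues, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  pvalues <- pvalues[!is.na(pvalues)]
  n <- length(pvalues)
  if (!n) stop("no p-values supplied")
  if (n < 1 / alpha)
    warning("fewer than 1/alpha tests; the empirical rate is unstable")
  k <- sum(pvalues <= alpha)
  phat <- k / n
  c(ratio = phat / alpha, se = sqrt(phat * (1 - phat) / n) / alpha,
    n = n, exceedances = k)
}

#' QQ points on the -log10 scale
#'
#' Expected quantiles are `-log10((i - 0.5) / n)` against the sorted
#' observed `-log10` p-values. Optional thinning subsamples the bulk of the
#' distribution while keeping the `tailKeep` smallest p-values exact.
#'
#' @param pvalues p-values.
#' @param thin keep roughly this many bulk points (`Inf` = no thinning).
#' @param tailKeep number of extreme points always kept exactly.
#' @return data.frame with `expected` and `observed` columns, ascending in
#'   `expected`.
#' @export
qqPoints <- function(pvalues, thin = Inf, tailKeep = 1000L) {
  pvalues <- sort(pvalues[!is.na(pvalues)], decreasing = TRUE)
  n <- length(pvalues)
  if (!n) stop("no p-values supplied")
  expected <- -log10((n:1 - 0.5) / n)
  observed <- -log10(pvalues)
  keep <- seq_len(n)
  if (is.finite(thin) && n > thin + tailKeep) {
    bulk <- seq_len(n - tailKeep)
    keep <- c(bulk[unique(round(seq(1, length(bulk), length.out = thin)))],
              (n - tailKeep + 1L):n)
  }
  data.frame(expected = expected[keep], observed = observed[keep])
}

#' Summarize a scan into calibration metrics
#'
#' Convenience wrapper computing, per strategy and test type present in a
#' scan result (or a pooled set of them), the genomic inflation factor, the
#' empirical type I error ratio at `alpha`, and QQ points.
#'
#' @param scan data.frame from [scanVariants()] (rows may be pooled across
#'   replicates).
#' @param alpha significance level for the empirical type I error.
#' @param thin passed to [qqPoints()].
#' @return list with a `summary` data.frame (strategy, test, lambda_gc,
#'   t1e_ratio, t1e_se, n_tests) and a named list `qq` of QQ point tables.
#' @export
evaluateScan <- function(scan, alpha = 0.01, thin = 5000L) {
  rows <- list(); qq <- list()
  for (strat in unique(scan$strategy)) {
    sub <- scan[scan$strategy == strat, , drop = FALSE]
    tests <- if (strat == "marginal") {
      list(M = list(p = sub$p_M, T = sub$T_M, df = sub$df_M[1L]))
    } else {
      list(I = list(p = sub$p_I, T = sub$T_I, df = sub$df_I[1L]),
           J = list(p = sub$p_J, T = sub$T_J, df = sub$df_J[1L]))
    }
    for (tn in names(tests)) {
      tt <- tests[[tn]]
      ok <- !is.na(tt$p)
      if (!any(ok)) next
      lam <- genomicInflation(tt$T[ok], df = tt$df)
      t1e <- empiricalTypeIError(tt$p[ok], alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = strat, test = tn, lambda_gc = lam,
                   t1e_ratio = t1e[["ratio"]], t1e_se = t1e[["se"]],
                   n_tests = as.integer(t1e[["n"]]), alpha = alpha,
                   stringsAsFactors = FALSE)
      qq[[paste(strat, tn, sep = ".")]] <- qqPoints(tt$p[ok], thin = thin)
    }
  }
  list(summary = do.call(rbind, rows), qq = qq)
}
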