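#' Build the per-variant design (genotype and interaction columns)
#'
#' The interaction design `K` has one column `g * E_m` per tested exposure;
#' `W = (g, K)`. Missing genotypes are mean-imputed per variant before
#' products are formed. By default each tested exposure must already appear
#' as a column of the null-model design, so the interaction is never tested
#' without its environmental main effect.
#'
#' @param g numeric genotype vector (allele counts or dosages; may contain
#'   `NA`).
#' @param exposures numeric vector or N x q matrix of exposures.
#' @param X null-model design to check exposures against, or `NULL` to skip.
#' @param override allow exposures absent from `X`.
#' @return list with `g` (imputed), `K`, `W` and `q`.
#' @export
buildVariantDesign <- function(g, exposures, X = NULL, override = FALSE) {
  E <- as.matrix(exposures)
  if (is.null(colnames(E))) colnames(E) <- paste0("E", seq_len(ncol(E)))
  g <- as.numeric(g)
  stopifnot(nrow(E) == length(g))
  if (!is.null(X) && !override) {
    X <- as.matrix(X)
    for (m in seq_len(ncol(E))) {
      found <- FALSE
      for (j in seq_len(ncol(X)))
        if (isTRUE(all.equal(as.numeric(X[, j]), as.numeric(E[, m]),
                             check.attributes = FALSE))) { found <- TRUE; break }
      if (!found)
        stop("exposure '", colnames(E)[m], "' is not a column of the null ",
             "covariate design; add its main effect or set override = TRUE")
    }
  }
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  K <- g * E
  colnames(K) <- paste0("g_x_", colnames(E))
  list(g = g, K = K, W = cbind(g = g, K), q = ncol(E))
}

# covariate-adjusted test design: W - X (X' Si X)^-1 X' Si W. The per-subject
# score rows of the sandwich meat are R_i * Wadj_i; they sum to the same
# score W' R (X' R = 0) but, unlike raw W_i rows, their empirical covariance
# is a consistent estimate of the score variance when W correlates with the
# null covariates (as g * E always does with E).
.covariateAdjust <- function(fit, W) {
  W - fit@X %*% (fit@XtSiXinv %*% crossprod(fit@SiX, W))
}

.clusterId <- function(clusters, n) {
  id <- integer(n)
  for (j in seq_along(clusters)) id[clusters[[j]]] <- j
  if (any(id == 0L)) stop("sample(s) with no cluster assignment")
  id
}

.skipRow <- function(variant, strategy, q, reason) {
  row <- data.frame(variant = variant, n = NA_integer_, af = NA_real_,
                    beta = NA_real_, stringsAsFactors = FALSE)
  for (m in seq_len(q)) row[[paste0("gamma", m)]] <- NA_real_
  row$T_I <- NA_real_; row$df_I <- q; row$p_I <- NA_real_
  row$T_J <- NA_real_; row$df_J <- q + 1L; row$p_J <- NA_real_
  row$neglog10_p_I <- NA_real_; row$neglog10_p_J <- NA_real_
  row$strategy <- strategy; row$skip_reason <- reason
  row
}

# core single-variant computation shared by all strategies.
# meat = "cluster" uses the given clusters; "none" gives the model-based test
# (bread-only variance).
.variantTest <- function(fit, vd, clusters, strategy, meat = "cluster",
                         variant = "v1") {
  q <- vd$q
  n <- length(fit@y)
  g <- vd$g
  mac <- min(sum(g), sum(2 - g))
  if (!is.finite(mac) || mac < 1 || stats::var(g) == 0)
    return(.skipRow(variant, strategy, q, "zero genetic variance"))
  W <- vd$W
  PW <- applyProjection(fit, W)
  Gram <- crossprod(W, PW)
  a <- Gram[1L, 1L]
  if (a <= 1e-8 * n)
    return(.skipRow(variant, strategy, q, "zero genetic variance"))
  BJ <- tryCatch(solve(Gram), error = function(e) NULL)
  if (is.null(BJ))
    return(.skipRow(variant, strategy, q, "singular bread"))
  Rt <- fit@residuals
  s <- drop(crossprod(W, Rt))
  zeta <- drop(BJ %*% s)
  Schur <- Gram[-1L, -1L, drop = FALSE] -
    tcrossprod(Gram[-1L, 1L, drop = FALSE]) / a
  BI <- tryCatch(solve(Schur), error = function(e) NULL)
  if (is.null(BI) || any(!is.finite(BI)))
    return(.skipRow(variant, strategy, q, "interaction collinear with genotype"))
  gamma <- zeta[-1L]

  if (meat == "none") {
    TJ <- drop(crossprod(zeta, Gram %*% zeta))
    TI <- drop(crossprod(gamma, Schur %*% gamma))
  } else {
    cid <- .clusterId(clusters, n)
    Wadj <- .covariateAdjust(fit, W)
    Sc <- rowsum(Rt * Wadj, cid)
    MJ <- crossprod(Sc)
    covJ <- BJ %*% MJ %*% BJ
    MI <- MJ[-1L, -1L, drop = FALSE]
    covI <- BI %*% MI %*% BI
    TJ <- tryCatch(drop(crossprod(zeta, solve(covJ, zeta))),
                   error = function(e) NA_real_)
    TI <- tryCatch(drop(crossprod(gamma, solve(covI, gamma))),
                   error = function(e) NA_real_)
    if (!is.finite(TJ) || !is.finite(TI) || TJ < 0 || TI < 0)
      return(.skipRow(variant, strategy, q, "non-positive-definite sandwich"))
  }
  row <- data.frame(variant = variant, n = n, af = mean(g) / 2,
                    beta = zeta[1L], stringsAsFactors = FALSE)
  for (m in seq_len(q)) row[[paste0("gamma", m)]] <- gamma[m]
  row$T_I <- TI; row$df_I <- q
  row$p_I <- stats::pchisq(TI, q, lower.tail = FALSE)
  row$T_J <- TJ; row$df_J <- q + 1L
  row$p_J <- stats::pchisq(TJ, q + 1L, lower.tail = FALSE)
  row$neglog10_p_I <- -stats::pchisq(TI, q, lower.tail = FALSE, log.p = TRUE) / log(10)
  row$neglog10_p_J <- -stats::pchisq(TJ, q + 1L, lower.tail = FALSE, log.p = TRUE) / log(10)
  row$strategy <- strategy; row$skip_reason <- NA_character_
  attr(row, "detail") <- list(zeta = zeta, BJ = BJ, BI = BI,
                              MJ = if (meat == "cluster") MJ else NULL,
                              covJ = if (meat == "cluster") covJ else NULL,
                              covI = if (meat == "cluster") covI else NULL)
  row
}

#' Bread, meat and effect estimates of the sandwich test
#'
#' `breadJoint` returns `B_J = (W' P W)^-1`; `breadInteraction` returns
#' `B_I = (K' H K)^-1`, the inverse Schur complement with the genotype
#' projected out (equal to the `K` block of `B_J`); `meatJoint` returns the
#' cluster-sum outer-product matrix `M_J`; `estimateEffects` returns
#' `zeta = B_J W' R` (genetic main effect first, then interaction effects).
#' These are the building blocks of [romTest()] exposed individually;
#' untestable variants (monomorphic genotype, interaction collinear with
#' genotype) raise an error where the scan would record a skip.
#'
#' @param fit a [NullModelFit-class].
#' @param vd a variant design from [buildVariantDesign()].
#' @param clusters sandwich clusters; defaults to the fit's.
#' @return a matrix (breads, meat) or named numeric vector (effects).
#' @export
breadJoint <- function(fit, vd) {
  PW <- applyProjection(fit, vd$W)
  Gram <- crossprod(vd$W, PW)
  if (Gram[1L, 1L] <= 1e-8 * length(fit@y)) stop("zero genetic variance")
  out <- tryCatch(solve(Gram), error = function(e) stop("singular bread"))
  dimnames(out) <- list(colnames(vd$W), colnames(vd$W))
  out
}

#' @rdname breadJoint
#' @export
breadInteraction <- function(fit, vd) {
  PW <- applyProjection(fit, vd$W)
  Gram <- crossprod(vd$W, PW)
  a <- Gram[1L, 1L]
  if (a <= 1e-8 * length(fit@y)) stop("zero genetic variance")
  Schur <- Gram[-1L, -1L, drop = FALSE] -
    tcrossprod(Gram[-1L, 1L, drop = FALSE]) / a
  out <- tryCatch(solve(Schur), error = function(e)
    stop("interaction collinear with genotype"))
  if (any(!is.finite(out))) stop("interaction collinear with genotype")
  dimnames(out) <- list(colnames(vd$K), colnames(vd$K))
  out
}

#' @rdname breadJoint
#' @export
meatJoint <- function(fit, vd, clusters = fit@clusters) {
  cid <- .clusterId(clusters, length(fit@y))
  Wadj <- .covariateAdjust(fit, vd$W)
  Sc <- rowsum(fit@residuals * Wadj, cid)
  out <- crossprod(Sc)
  dimnames(out) <- list(colnames(vd$W), colnames(vd$W))
  out
}

#' @rdname breadJoint
#' @export
estimateEffects <- function(fit, vd) {
  BJ <- breadJoint(fit, vd)
  structure(drop(BJ %*% crossprod(vd$W, fit@residuals)),
            names = colnames(vd$W))
}

#' Robust mixed-model GEI and joint test (family-clustered sandwich)
#'
#' Score tests of the interaction effect (`T_I`, chi-square with q df) and
#' of the joint genetic/interaction effect (`T_J`, q+1 df) with the
#' family-clustered Huber-White sandwich variance `B M B`: bread
#' `B_J = (W' P W)^-1`, meat `M_J = sum_j (sum_{i in c_j} R_i W_i)'
#' (sum_{i in c_j} R_i W_i)` over clusters `c_j`.
#'
#' @param fit a [NullModelFit-class] from [fitNullModel()].
#' @param vd a variant design from [buildVariantDesign()].
#' @param clusters sandwich clusters (list of index vectors); defaults to
#'   the fit's clusters.
#' @param variant variant label for the output row.
#' @return one-row data.frame with effect estimates, statistics, p-values
#'   and a skip reason when the variant cannot be tested.
#' @export
romTest <- function(fit, vd, clusters = fit@clusters, variant = "v1")
  .variantTest(fit, vd, clusters, "RoM", "cluster", variant)

#' Model-based mixed-model test (bread-only variance)
#'
#' The non-robust counterpart: `t_J = zeta' B_J^-1 zeta` and
#' `t_I = gamma' B_I^-1 gamma`, i.e. the model-implied variance with no
#' sandwich. Inflates under environmental main-effect misspecification.
#'
#' @inheritParams romTest
#' @export
modelBasedTest <- function(fit, vd, variant = "v1")
  .variantTest(fit, vd, NULL, "LMM-MB", "none", variant)

#' Individual-cluster sandwich test from a mixed-model fit
#'
#' Identical to [romTest()] with every individual its own cluster, so the
#' meat is `sum_i R_i^2 W_i' W_i`. Misspecifies the clustering for related
#' samples.
#'
#' @inheritParams romTest
#' @export
icbTest <- function(fit, vd, variant = "v1")
  .variantTest(fit, vd, as.list(seq_along(fit@y)), "LMM-ICB", "cluster", variant)

#' Two-step residual-outcome test with individual-cluster sandwich
#'
#' Step 1 fits the covariates-only mixed model and extracts residuals
#' (conditional residuals `y - X alpha - u` with `u` the BLUP of the random
#' effects by default, or marginal residuals `y - X alpha`). Step 2 treats
#' the residuals as the outcome of an ordinary linear model with the same
#' covariates and applies the individual-cluster sandwich score test.
#'
#' @param y,X,components as in [fitNullModel()].
#' @param vd variant design from [buildVariantDesign()].
#' @param step1 optionally a prefitted step-1 [NullModelFit-class] (reused
#'   across variants).
#' @param residualType `"conditional"` (default) or `"marginal"`.
#' @param variant variant label.
#' @export
twoStepTest <- function(y, X, components, vd, step1 = NULL,
                        residualType = c("conditional", "marginal"),
                        variant = "v1") {
  residualType <- match.arg(residualType)
  if (is.null(step1)) step1 <- fitNullModel(y, X, components)
  res <- twoStepResiduals(step1, residualType)
  fit2 <- fitNullModel(res, step1@X, list())
  .variantTest(fit2, vd, as.list(seq_along(y)), "Two-step-ICB", "cluster",
               variant)
}

#' Residuals used as the step-2 outcome of the two-step strategy
#'
#' Conditional residuals subtract the BLUP of the random effects; for
#' `Sigma = sigma_e^2 I + sum lambda_l Psi_l` they equal
#' `sigma_e^2 Sigma^-1 (y - X alpha)`, i.e. `sigma_e^2` times the scaled
#' residuals. Marginal residuals are `y - X alpha`.
#'
#' @param fit step-1 [NullModelFit-class].
#' @param residualType `"conditional"` or `"marginal"`.
#' @export
twoStepResiduals <- function(fit, residualType = c("conditional", "marginal")) {
  residualType <- match.arg(residualType)
  if (residualType == "conditional")
    as.numeric(fit@lambda[["residual"]] * fit@residuals)
  else
    fit@y - drop(fit@X %*% fit@alpha)
}

#' Plain linear-model test with individual-cluster sandwich
#'
#' Fits an ordinary linear null model on the covariates (no random effects)
#' and applies the individual-cluster sandwich score test.
#'
#' @inheritParams twoStepTest
#' @export
lmIcbTest <- function(y, X, vd, variant = "v1") {
  fit <- fitNullModel(y, X, list())
  .variantTest(fit, vd, as.list(seq_along(y)), "LM-ICB", "cluster", variant)
}

#' Marginal genetic score test
#'
#' Tests the genetic main effect alone under the covariates-only null:
#' statistic `(g' R)^2 / (g' P g)`, chi-square with 1 df.
#'
#' @param fit a [NullModelFit-class].
#' @param g genotype vector.
#' @param variant variant label.
#' @export
marginalTest <- function(fit, g, variant = "v1") {
  g <- as.numeric(g)
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  n <- length(fit@y)
  Pg <- drop(applyProjection(fit, g))
  a <- sum(g * Pg)
  if (stats::var(g) == 0 || a <= 1e-8 * n)
    return(data.frame(variant = variant, n = n, af = mean(g) / 2,
                      T_M = NA_real_, df_M = 1L, p_M = NA_real_,
                      strategy = "marginal",
                      skip_reason = "zero genetic variance",
                      stringsAsFactors = FALSE))
  Tm <- sum(g * fit@residuals)^2 / a
  data.frame(variant = variant, n = n, af = mean(g) / 2, T_M = Tm, df_M = 1L,
             p_M = stats::pchisq(Tm, 1, lower.tail = FALSE),
             strategy = "marginal", skip_reason = NA_character_,
             stringsAsFactors = FALSE)
}
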