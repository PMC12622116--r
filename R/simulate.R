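#' Simulate genotypes by gene dropping
#'
#' Founder haplotype alleles are i.i.d. Bernoulli(MAF); each offspring
#' inherits one uniformly chosen haplotype from each parent, independently
#' per variant (variants are unlinked). The returned genotype is the allele
#' count (0/1/2). Variants are processed in fixed-size internal chunks so the
#' result is deterministic given (`ped`, `mafs`, `seed`).
#'
#' @param ped a [FamilyPedigree-class].
#' @param mafs per-variant minor allele frequencies, each in (0, 0.5].
#' @param seed integer RNG seed.
#' @return integer matrix, individuals x variants, with `rownames` the
#'   individual ids and attribute `mafs`.
#' @export
simulateGenotypes <- function(ped, mafs, seed = 1L) {
  stopifnot(all(mafs > 0), all(mafs <= 0.5))
  m <- ped@members
  n <- nrow(m); V <- length(mafs)
  fa <- match(m$father, m$id)
  mo <- match(m$mother, m$id)
  founder <- is.na(fa)
  # topological levels: all individuals of a level draw transmissions at once
  level <- integer(n)
  for (i in seq_len(n))
    level[i] <- if (founder[i]) 1L else 1L + max(level[fa[i]], level[mo[i]])
  levels <- sort(unique(level[!founder]))
  G <- matrix(NA_integer_, n, V, dimnames = list(m$id, NULL))
  set.seed(as.integer(seed))
  chunk <- 1024L
  nf <- sum(founder)
  for (start in seq(1L, V, by = chunk)) {
    cols <- start:min(start + chunk - 1L, V)
    nc <- length(cols)
    p <- mafs[cols]
    H1 <- H2 <- matrix(0L, n, nc)
    H1[founder, ] <- rbinom(nf * nc, 1L, rep(p, each = nf))
    H2[founder, ] <- rbinom(nf * nc, 1L, rep(p, each = nf))
    for (lv in levels) {
      idx <- which(!founder & level == lv)
      k <- length(idx)
      hf <- H1[fa[idx], , drop = FALSE]
      sel <- matrix(runif(k * nc) < 0.5, k, nc)
      hf[sel] <- H2[fa[idx], , drop = FALSE][sel]
      hm <- H1[mo[idx], , drop = FALSE]
      sel <- matrix(runif(k * nc) < 0.5, k, nc)
      hm[sel] <- H2[mo[idx], , drop = FALSE][sel]
      H1[idx, ] <- hf
      H2[idx, ] <- hm
    }
    G[, cols] <- H1 + H2
  }
  attr(G, "mafs") <- mafs
  G
}

#' Draw uniform minor allele frequencies for a common-variant panel
#'
#' @param nVariants number of variants.
#' @param lower,upper MAF bounds; default common variants in (0.05, 0.5].
#' @param seed integer RNG seed.
#' @export
drawMafs <- function(nVariants, lower = 0.05, upper = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  runif(nVariants, lower, upper)
}

# sample one N(0, s2 * 2 Psi) vector, cluster block by cluster block
.sampleFamilyNormal <- function(km, s2 = 1) {
  n <- length(km@ids)
  out <- numeric(n)
  R2 <- 2 * km@kinship
  labels <- names(km@clusters)
  if (is.null(labels)) labels <- as.character(seq_along(km@clusters))
  for (f in seq_along(km@clusters)) {
    idx <- km@clusters[[f]]
    B <- as.matrix(R2[idx, idx, drop = FALSE])
    L <- tryCatch(chol(B), error = function(e)
      stop(sprintf("relationship block for family '%s' is not positive definite",
                   labels[f])))
    out[idx] <- drop(crossprod(L, rnorm(length(idx)))) * sqrt(s2)
  }
  out
}

#' Simulate environmental exposures
#'
#' Draws a heritable exposure `x1 ~ N(0, 2 Psi)` (family-block multivariate
#' normal, so `Var(x1_i) = 1` for non-inbred individuals and parent-child /
#' sibling covariance 0.5) and a non-heritable exposure `x2 ~ N(0, 2)`.
#'
#' @param km a [KinshipModel-class].
#' @param seed integer RNG seed.
#' @return list with numeric vectors `x1` and `x2`.
#' @export
simulateExposures <- function(km, seed = 1L) {
  set.seed(as.integer(seed))
  x1 <- .sampleFamilyNormal(km, 1)
  x2 <- rnorm(length(km@ids), 0, sqrt(2))
  list(x1 = x1, x2 = x2)
}

#' Calibrate quadratic exposure effect sizes to target variance shares
#'
#' The trait model is `y = 1 + a1 x1 + a2 x1^2 + a3 x2 + a4 x2^2 + r + eps`
#' with `Var(x1) = 1`, `Var(x2) = 2`, `Var(r) = 1`, `Var(eps) = 1`. All five
#' random terms are mutually uncorrelated (for centered normals,
#' `Cov(x, x^2) = 0` and `Var(x^2) = 2 sigma^4`), so the total variance
#' solves `Var(y) = 2 + sum(props) * Var(y)` and each effect is
#' `a_j = sqrt(prop_j * Var(y) / v_j)` with term variances
#' `v = (1, 2, 2, 8)` at unit effect.
#'
#' @param targetProps length-4 vector of variance proportions for the
#'   x1, x1^2, x2, x2^2 terms; defaults to (0.1, 0.05, 0.1, 0.05).
#' @return named numeric `(alpha1..alpha4)` with attribute `varY`, the
#'   implied total trait variance.
#' @export
calibrateEffects <- function(targetProps = c(0.1, 0.05, 0.1, 0.05)) {
  stopifnot(length(targetProps) == 4, all(targetProps >= 0))
  s <- sum(targetProps)
  if (s >= 1) stop("variance proportions must sum to less than 1")
  varY <- 2 / (1 - s)
  termVar <- c(1, 2, 2, 8)  # Var(x1), Var(x1^2), Var(x2), Var(x2^2)
  alphas <- sqrt(targetProps * varY / termVar)
  names(alphas) <- paste0("alpha", 1:4)
  attr(alphas, "varY") <- varY
  alphas
}

#' Simulate one trait replicate
#'
#' Assembles `y = 1 + a1 x1 + a2 x1^2 + a3 x2 + a4 x2^2 + r + eps` with
#' `r ~ N(0, sigmaR2 * 2 Psi)` sampled family block by family block and
#' `eps ~ N(0, sigmaE2 I)`.
#'
#' @param km a [KinshipModel-class].
#' @param x1,x2 exposure vectors from [simulateExposures()].
#' @param alphas effect sizes from [calibrateEffects()].
#' @param seed integer RNG seed.
#' @param sigmaR2,sigmaE2 variances of the polygenic and residual terms.
#' @return list with `y`, `x1`, `x2`, `alphas`, `seed`.
#' @export
simulateTrait <- function(km, x1, x2, alphas, seed = 1L,
                          sigmaR2 = 1, sigmaE2 = 1) {
  n <- length(km@ids)
  stopifnot(length(x1) == n, length(x2) == n, length(alphas) == 4)
  set.seed(as.integer(seed))
  r <- if (sigmaR2 > 0) .sampleFamilyNormal(km, sigmaR2) else numeric(n)
  eps <- rnorm(n, 0, sqrt(sigmaE2))
  y <- 1 + x1 * alphas[1] + x1^2 * alphas[2] + x2 * alphas[3] +
    x2^2 * alphas[4] + r + eps
  list(y = as.numeric(y), x1 = x1, x2 = x2, alphas = alphas,
       seed = as.integer(seed))
}

#' Covariate design for the null model
#'
#' The misspecified null drops the quadratic exposure terms: intercept plus
#' linear `x1`, `x2` only. With `correct = TRUE` the quadratic terms are
#' included, which makes the null model correctly specified for the
#' simulated trait.
#'
#' @param x1,x2 exposure vectors.
#' @param correct include `x1^2`, `x2^2` columns.
#' @return numeric design matrix with named columns.
#' @export
nullDesign <- function(x1, x2, correct = FALSE) {
  X <- cbind(intercept = 1, x1 = x1, x2 = x2)
  if (correct) X <- cbind(X, x1sq = x1^2, x2sq = x2^2)
  X
}
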