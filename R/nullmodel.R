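#' Fit the covariates-only linear mixed model by REML
#'
#' Fits `y = X alpha + r + eps` with `r ~ N(0, sum_l lambda_l Psi_l)` and
#' `eps ~ N(0, lambda_0 I)` by average-information (AI) REML. All solves are
#' block-wise over the connected components of the combined relatedness
#' pattern, so cost is linear in sample size for bounded block sizes; no
#' N x N projection matrix is ever formed. With an empty component list the
#' model degenerates to ordinary least squares (`Sigma = sigma^2 I`), fitted
#' in closed form.
#'
#' @param y numeric trait vector.
#' @param X covariate design matrix including the intercept.
#' @param components a [KinshipModel-class] (uses its relationship matrix
#'   `2 Psi` as a single component named `kinship`), or a named list of
#'   symmetric positive semidefinite relatedness matrices.
#' @param clusters sandwich clusters: named list of index vectors, a
#'   factor/vector of cluster labels, or `NULL` to use the relatedness
#'   blocks (singletons when `components` is empty).
#' @param tol relative-change convergence tolerance.
#' @param maxIter maximum AI-REML iterations.
#' @param verbose print per-iteration REML log-likelihood.
#' @return a [NullModelFit-class].
#' @export
fitNullModel <- function(y, X, components = list(), clusters = NULL,
                         tol = 1e-6, maxIter = 100L, verbose = FALSE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  if (is(components, "KinshipModel")) {
    km <- components
    components <- list(kinship = relationshipMatrix(km))
    if (is.null(clusters)) clusters <- km@clusters
  }
  stopifnot(is.list(components))
  L <- length(components)
  if (L > 0 && is.null(names(components)))
    names(components) <- paste0("vc", seq_len(L))
  for (Ps in components) stopifnot(nrow(Ps) == n, ncol(Ps) == n)

  blocks <- .relatednessBlocks(components, n)
  clusters <- .normalizeClusters(clusters, blocks, n)

  # dense per-block copies of each component
  Pblk <- lapply(components, function(Ps) {
    Ps <- as(Ps, "CsparseMatrix")
    lapply(blocks, function(idx) as.matrix(Ps[idx, idx, drop = FALSE]))
  })

  if (L == 0L) {
    fitls <- lm.fit(X, y)
    alpha <- fitls$coefficients
    res <- y - drop(X %*% alpha)
    s2 <- sum(res^2) / (n - p)
    Vinv <- Matrix::Diagonal(n) / s2
    SiX <- X / s2
    XtSiXinv <- chol2inv(qr.R(qrX)) * s2
    rl <- -0.5 * ((n - p) * log(s2) + determinant(crossprod(X) / s2)$modulus +
                    sum(res^2) / s2)
    fit <- new("NullModelFit", alpha = structure(as.numeric(alpha), names = colnames(X)),
               lambda = c(residual = s2), y = y, X = X,
               Vinv = Vinv, SiX = SiX, XtSiXinv = XtSiXinv,
               residuals = res / s2, clusters = clusters,
               converged = TRUE, niter = 0L, logLik = as.numeric(rl))
    return(fit)
  }

  varY <- stats::var(y)
  floorVal <- 1e-10 * varY
  theta <- rep(varY / (L + 1), L + 1L)
  names(theta) <- c("residual", names(components))

  Xblk <- lapply(blocks, function(idx) X[idx, , drop = FALSE])
  yblk <- lapply(blocks, function(idx) y[idx])

  st <- .remlState(theta, blocks, Pblk, Xblk, yblk, X, y)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    sa <- .remlScoreAI(st, theta, blocks, Pblk, Xblk)
    step <- tryCatch(solve(sa$AI, sa$score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) step <- sa$score / max(diag(sa$AI), 1)
    ok <- FALSE
    fac <- 1
    for (h in seq_len(12L)) {
      thNew <- pmax(theta + fac * step, floorVal)
      stNew <- tryCatch(.remlState(thNew, blocks, Pblk, Xblk, yblk, X, y),
                        error = function(e) NULL)
      if (!is.null(stNew) && is.finite(stNew$loglik) &&
          stNew$loglik >= st$loglik - 1e-10 * abs(st$loglik)) {
        ok <- TRUE; break
      }
      fac <- fac / 2
    }
    if (!ok) break
    rel <- max(abs(thNew - theta) / pmax(abs(theta), floorVal))
    theta <- thNew; st <- stNew
    if (verbose)
      message(sprintf("iter %d: logLik %.8f, theta = %s", it, st$loglik,
                      paste(signif(theta, 6), collapse = " ")))
    if (rel < tol) { converged <- TRUE; break }
  }

  if (!converged) {
    # derivative-free polish of the same block-wise REML criterion
    nm <- stats::optim(log(pmax(theta, floorVal)), function(lt) {
      s <- tryCatch(.remlState(exp(lt), blocks, Pblk, Xblk, yblk, X, y),
                    error = function(e) NULL)
      if (is.null(s) || !is.finite(s$loglik)) 1e10 else -s$loglik
    }, method = "Nelder-Mead", control = list(maxit = 500))
    thNM <- pmax(exp(nm$par), floorVal)
    stNM <- tryCatch(.remlState(thNM, blocks, Pblk, Xblk, yblk, X, y),
                     error = function(e) NULL)
    if (!is.null(stNM) && stNM$loglik >= st$loglik) {
      theta <- thNM; st <- stNM
      converged <- nm$convergence == 0
    }
    if (!converged)
      warning("REML did not converge in ", maxIter, " iterations")
  }

  Vinv <- .assembleBlockInverse(st$Vinvblk, blocks, n)
  SiX <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  for (b in seq_along(blocks)) SiX[blocks[[b]], ] <- st$T[[b]]
  new("NullModelFit",
      alpha = structure(as.numeric(st$alpha), names = colnames(X)),
      lambda = theta, y = y, X = X, Vinv = Vinv, SiX = SiX,
      XtSiXinv = st$XtSiXinv, residuals = st$Rtilde, clusters = clusters,
      converged = converged, niter = it, logLik = st$loglik)
}

# connected components of the union nonzero pattern of all components
.relatednessBlocks <- function(components, n) {
  if (length(components) == 0L) return(as.list(seq_len(n)))
  pat <- NULL
  for (Ps in components) {
    Ps <- as(as(Ps, "CsparseMatrix"), "generalMatrix")
    ij <- Matrix::which(Ps != 0, arr.ind = TRUE)
    pat <- rbind(pat, ij)
  }
  # union-find over the pattern
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(pat) && nrow(pat)) {
    for (k in seq_len(nrow(pat))) {
      a <- find(pat[k, 1L]); b <- find(pat[k, 2L])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), match(root, unique(root))))
}

.normalizeClusters <- function(clusters, blocks, n) {
  if (is.null(clusters)) {
    cl <- blocks
    names(cl) <- paste0("c", seq_along(cl))
    return(cl)
  }
  if (!is.list(clusters)) {
    if (length(clusters) != n)
      stop("cluster labels must have one entry per sample")
    if (anyNA(clusters)) stop("sample(s) with no cluster assignment")
    cl <- split(seq_len(n), factor(clusters, levels = unique(clusters)))
    return(cl)
  }
  idx <- sort(unlist(clusters, use.names = FALSE))
  if (!identical(idx, seq_len(n))) stop("clusters must partition the samples")
  if (is.null(names(clusters))) names(clusters) <- paste0("c", seq_along(clusters))
  clusters
}

# factorize Sigma(theta) per block and compute GLS quantities + REML loglik
.remlState <- function(theta, blocks, Pblk, Xblk, yblk, X, y) {
  n <- length(y); p <- ncol(X); L <- length(Pblk)
  nb <- length(blocks)
  Vinvblk <- vector("list", nb); Tlist <- vector("list", nb)
  XtSiX <- matrix(0, p, p); XtSiy <- numeric(p)
  logdetV <- 0
  for (b in seq_len(nb)) {
    idx <- blocks[[b]]
    s <- length(idx)
    Vb <- diag(theta[1L], s)
    for (l in seq_len(L)) Vb <- Vb + theta[l + 1L] * Pblk[[l]][[b]]
    Rb <- chol(Vb)
    logdetV <- logdetV + 2 * sum(log(diag(Rb)))
    Vib <- chol2inv(Rb)
    Tb <- Vib %*% Xblk[[b]]
    XtSiX <- XtSiX + crossprod(Xblk[[b]], Tb)
    XtSiy <- XtSiy + drop(crossprod(Tb, yblk[[b]]))
    Vinvblk[[b]] <- Vib; Tlist[[b]] <- Tb
  }
  XtSiXch <- chol(XtSiX)
  XtSiXinv <- chol2inv(XtSiXch)
  alpha <- drop(XtSiXinv %*% XtSiy)
  res <- y - drop(X %*% alpha)
  Rtilde <- numeric(n)
  for (b in seq_len(nb)) Rtilde[blocks[[b]]] <- Vinvblk[[b]] %*% res[blocks[[b]]]
  yPy <- sum(res * Rtilde)
  loglik <- -0.5 * (logdetV + 2 * sum(log(diag(XtSiXch))) + yPy)
  list(loglik = loglik, alpha = alpha, Rtilde = Rtilde, Vinvblk = Vinvblk,
       T = Tlist, XtSiX = XtSiX, XtSiXinv = XtSiXinv)
}

# REML score vector and average-information matrix for (residual, lambda_1..L)
.remlScoreAI <- function(st, theta, blocks, Pblk, Xblk) {
  L <- length(Pblk); m <- L + 1L
  nb <- length(blocks)
  n <- length(st$Rtilde)
  trVP <- numeric(m)            # tr(V^-1 Psi_l)
  A <- vector("list", m)        # X' V^-1 Psi_l V^-1 X
  U <- matrix(0, n, m)          # Psi_l %*% Rtilde
  for (l in seq_len(m)) A[[l]] <- matrix(0, ncol(Xblk[[1L]]), ncol(Xblk[[1L]]))
  for (b in seq_len(nb)) {
    idx <- blocks[[b]]
    Vib <- st$Vinvblk[[b]]; Tb <- st$T[[b]]
    rb <- st$Rtilde[idx]
    trVP[1L] <- trVP[1L] + sum(diag(Vib))
    A[[1L]] <- A[[1L]] + crossprod(Tb)
    U[idx, 1L] <- rb
    for (l in seq_len(L)) {
      Pb <- Pblk[[l]][[b]]
      trVP[l + 1L] <- trVP[l + 1L] + sum(Vib * Pb)
      A[[l + 1L]] <- A[[l + 1L]] + crossprod(Tb, Pb %*% Tb)
      U[idx, l + 1L] <- Pb %*% rb
    }
  }
  score <- numeric(m)
  for (l in seq_len(m)) {
    trP <- trVP[l] - sum(st$XtSiXinv * A[[l]])
    score[l] <- -0.5 * (trP - sum(st$Rtilde * U[, l]))
  }
  # PU = V^-1 U - V^-1 X (X'V^-1X)^-1 X'V^-1 U, block-wise
  PU <- matrix(0, n, m)
  C <- matrix(0, ncol(Xblk[[1L]]), m)
  for (b in seq_len(nb)) {
    idx <- blocks[[b]]
    PU[idx, ] <- st$Vinvblk[[b]] %*% U[idx, , drop = FALSE]
    C <- C + crossprod(st$T[[b]], U[idx, , drop = FALSE])
  }
  corr <- st$XtSiXinv %*% C
  for (b in seq_len(nb)) {
    idx <- blocks[[b]]
    PU[idx, ] <- PU[idx, ] - st$T[[b]] %*% corr
  }
  AI <- 0.5 * crossprod(U, PU)
  AI <- (AI + t(AI)) / 2
  list(score = score, AI = AI)
}

.assembleBlockInverse <- function(Vinvblk, blocks, n) {
  ii <- jj <- xx <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    s <- length(idx)
    ii[[b]] <- rep(idx, times = s)
    jj[[b]] <- rep(idx, each = s)
    xx[[b]] <- as.vector(Vinvblk[[b]])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

#' Scaled residuals of a null model fit
#'
#' Returns `R = Sigma^-1 (y - X alpha)`, which equals `P y` for the
#' covariate projection `P = Sigma^-1 - Sigma^-1 X (X' Sigma^-1 X)^-1 X'
#' Sigma^-1` without ever forming `P`.
#'
#' @param fit a [NullModelFit-class].
#' @export
scaledResiduals <- function(fit) fit@residuals

#' Apply the null-model projection to a matrix
#'
#' Computes `P V` for an N x k matrix `V` using the cached factorization:
#' `P V = Sigma^-1 V - Sigma^-1 X (X' Sigma^-1 X)^-1 (X' Sigma^-1 V)`.
#' Cost is linear in N for bounded relatedness blocks and fixed k.
#'
#' @param fit a [NullModelFit-class].
#' @param V numeric vector or N x k matrix.
#' @return matrix `P V` (N x k).
#' @export
applyProjection <- function(fit, V) {
  V <- as.matrix(V)
  if (nrow(V) != length(fit@y)) stop("V must have one row per sample")
  SiV <- as.matrix(fit@Vinv %*% V)
  SiV - fit@SiX %*% (fit@XtSiXinv %*% crossprod(fit@SiX, V))
}

#' @describeIn NullModelFit-class estimated variance components.
#' @param object,fit a `NullModelFit`.
#' @export
varianceComponents <- function(object) object@lambda

#' @describeIn NullModelFit-class GLS covariate effect estimates.
#' @export
fixedEffects <- function(object) object@alpha

#' @describeIn NullModelFit-class sandwich cluster map used for testing.
#' @export
fitClusters <- function(object) object@clusters

setMethod("show", "NullModelFit", function(object) {
  cat(sprintf("NullModelFit: N = %d, p = %d, %s (%d iterations)\n",
              length(object@y), ncol(object@X),
              if (object@converged) "converged" else "NOT converged",
              object@niter))
  cat("variance components:\n")
  print(signif(object@lambda, 6))
})

#' Random-slope variance component for an exposure
#'
#' Builds `Psi_slope = D Psi0 D` with `D = diag(exposure)`, the component
#' induced by giving each individual's relatedness-correlated random effect a
#' slope in the exposure. Supplying it as an extra component to
#' [fitNullModel()] fits the random-slope mixed model with no special-case
#' code path.
#'
#' @param Psi0 base relatedness matrix (e.g. `2 Psi`).
#' @param exposure numeric exposure vector.
#' @export
randomSlopeComponent <- function(Psi0, exposure) {
  D <- Matrix::Diagonal(x = as.numeric(exposure))
  as(D %*% Psi0 %*% D, "CsparseMatrix")
}

#' Repeated-measures (random intercept) variance component
#'
#' Block-diagonal matrix of ones within subject: a random intercept per
#' subject, for longitudinal data in long format.
#'
#' @param subject vector of subject ids, one per observation.
#' @export
repeatedMeasuresComponent <- function(subject) {
  f <- factor(subject, levels = unique(subject))
  Z <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                            dims = c(length(f), nlevels(f)))
  Matrix::tcrossprod(Z)
}
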