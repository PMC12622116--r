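# Dense reference implementations used as independent oracles. Everything
# here assembles full N x N matrices and explicit loops; nothing is shared
# with the package's block-wise/vectorized code paths.

denseSigma <- function(theta, components, n) {
  V <- diag(theta[1L], n)
  for (l in seq_along(components))
    V <- V + theta[l + 1L] * as.matrix(components[[l]])
  V
}

denseProjection <- function(Sigma, X) {
  Si <- solve(Sigma)
  Si - Si %*% X %*% solve(t(X) %*% Si %*% X) %*% t(X) %*% Si
}

denseRemlLoglik <- function(theta, y, X, components) {
  n <- length(y)
  V <- denseSigma(theta, components, n)
  Si <- solve(V)
  XtSiX <- t(X) %*% Si %*% X
  P <- denseProjection(V, X)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtSiX)$modulus +
                       drop(t(y) %*% P %*% y)))
}

# all five strategies from explicit dense matrices; `Sigma` is the fitted
# covariance of whichever null model the strategy uses, `y` its outcome.
denseStrategy <- function(y, X, Sigma, g, E, clusterId,
                          meat = c("cluster", "none")) {
  meat <- match.arg(meat)
  E <- as.matrix(E)
  K <- g * E
  W <- cbind(g, K)
  n <- length(y)
  Si <- solve(Sigma)
  XtSiXi <- solve(t(X) %*% Si %*% X)
  P <- Si - Si %*% X %*% XtSiXi %*% t(X) %*% Si
  Rt <- drop(P %*% y)
  Gram <- t(W) %*% P %*% W
  BJ <- solve(Gram)
  zeta <- drop(BJ %*% t(W) %*% Rt)
  Pg <- P %*% g
  H <- P - Pg %*% t(Pg) / drop(t(g) %*% Pg)
  BI <- solve(t(K) %*% H %*% K)
  gamma <- zeta[-1L]
  if (meat == "none") {
    TJ <- drop(t(zeta) %*% Gram %*% zeta)
    TI <- drop(t(gamma) %*% solve(BI) %*% gamma)
    return(list(zeta = zeta, BJ = BJ, BI = BI, T_J = TJ, T_I = TI))
  }
  Wadj <- W - X %*% XtSiXi %*% t(X) %*% Si %*% W
  MJ <- matrix(0, ncol(W), ncol(W))
  for (j in unique(clusterId)) {
    Sj <- rep(0, ncol(W))
    for (i in which(clusterId == j)) Sj <- Sj + Rt[i] * Wadj[i, ]
    MJ <- MJ + Sj %o% Sj
  }
  covJ <- BJ %*% MJ %*% BJ
  MI <- MJ[-1L, -1L, drop = FALSE]
  covI <- BI %*% MI %*% BI
  TJ <- drop(t(zeta) %*% solve(covJ) %*% zeta)
  TI <- drop(t(gamma) %*% solve(covI) %*% gamma)
  list(zeta = zeta, BJ = BJ, BI = BI, MJ = MJ, covJ = covJ, covI = covI,
       T_J = TJ, T_I = TI)
}

# path-counting kinship for loop-free pedigrees with unrelated, non-inbred
# founders: phi(i,j) = sum over common ancestors A and pairs of ancestral
# chains meeting only at A of (1/2)^(len_i + len_j + 1).
pathKinship <- function(members) {
  n <- nrow(members)
  pos <- seq_len(n); names(pos) <- members$id
  # all chains from i up to each ancestor, INCLUDING the trivial chain (i);
  # a chain is the vector of positions (i, parent, ..., ancestor)
  chains <- function(i) {
    out <- list(i)
    fa <- members$father[i]; mo <- members$mother[i]
    if (!is.na(fa)) {
      for (p in c(pos[[fa]], pos[[mo]]))
        for (ch in chains(p)) out[[length(out) + 1L]] <- c(i, ch)
    }
    out
  }
  allch <- lapply(seq_len(n), chains)
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tot <- 0
      for (ci in allch[[i]]) for (cj in allch[[j]]) {
        A <- ci[length(ci)]
        if (cj[length(cj)] != A) next
        # the two descent paths may share no individual except A
        if (length(intersect(ci[-length(ci)], cj[-length(cj)])) > 0L) next
        tot <- tot + 0.5^((length(ci) - 1L) + (length(cj) - 1L) + 1L)
      }
      phi[i, j] <- tot
    }
  }
  for (i in seq_len(n)) {
    fa <- members$father[i]
    Fi <- if (is.na(fa)) 0 else phi[pos[[fa]], pos[[members$mother[i]]]]
    phi[i, i] <- 0.5 * (1 + Fi)
  }
  phi
}

# textbook HC0-robust linear-model score pieces, assembled by brute force
# from the centered design (intercept-only covariates)
hc0Oracle <- function(y, W) {
  n <- length(y)
  Wc <- sweep(W, 2, colMeans(W))
  e <- y - mean(y)
  s2 <- sum(lm(y ~ 1)$residuals^2) / (n - 1)
  bread <- solve(t(Wc) %*% Wc / s2)
  meat <- matrix(0, ncol(W), ncol(W))
  for (i in seq_len(n)) meat <- meat + (e[i] / s2)^2 * Wc[i, ] %o% Wc[i, ]
  zeta <- drop(bread %*% t(Wc) %*% e / s2)
  covZ <- bread %*% meat %*% bread
  list(zeta = zeta, cov = covZ,
       T_J = drop(t(zeta) %*% solve(covZ) %*% zeta))
}
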