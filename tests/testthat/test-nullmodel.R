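test_that("with no relatedness the fit degenerates to ordinary least squares", {
  set.seed(21)
  n <- 60
  X <- cbind(intercept = 1, x = rnorm(n), z = rnorm(n))
  y <- drop(X %*% c(1, 0.5, -0.2)) + rnorm(n)
  fit <- fitNullModel(y, X, list())
  ls <- lm(y ~ 0 + X)
  expect_equal(unname(fixedEffects(fit)), unname(coef(ls)), tolerance = 1e-10)
  expect_equal(unname(varianceComponents(fit)[["residual"]]),
               sum(resid(ls)^2) / (n - 3), tolerance = 1e-10)
  expect_true(fit@converged)
})

test_that("REML criterion and residuals match a dense oracle on a toy family", {
  toy <- makeToyCohort(nNuclear = 5, nExtended = 0, seed = 31)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  comps <- list(as.matrix(relationshipMatrix(toy$km)))
  theta <- unname(varianceComponents(fit))
  expect_equal(fit@logLik,
               denseRemlLoglik(theta, toy$trait$y, toy$X, comps),
               tolerance = 1e-8)
  # the fitted theta is a local optimum of the dense criterion
  for (d in list(c(0.02, 0), c(-0.02, 0), c(0, 0.02), c(0, -0.02)))
    expect_gt(fit@logLik,
              denseRemlLoglik(pmax(theta + d, 1e-8), toy$trait$y, toy$X, comps))
  # scaled residuals equal dense P y
  V <- denseSigma(theta, comps, length(toy$trait$y))
  P <- denseProjection(V, toy$X)
  expect_equal(scaledResiduals(fit), drop(P %*% toy$trait$y),
               tolerance = 1e-8)
})

test_that("residuals are orthogonal to covariates and vanish for fitted y", {
  toy <- makeToyCohort(nNuclear = 8, nExtended = 1, seed = 41)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  expect_lt(max(abs(crossprod(toy$X, scaledResiduals(fit)))),
            1e-8 * sqrt(sum(toy$trait$y^2)))
  # outcome inside the covariate span gives zero residuals
  y0 <- drop(toy$X %*% c(2, 1, -1))
  fit0 <- fitNullModel(y0, toy$X, toy$km)
  expect_lt(max(abs(scaledResiduals(fit0))), 1e-4)
})

test_that("applyProjection matches the dense projection and annihilates X", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 0, seed = 51)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  n <- length(toy$trait$y)
  expect_lt(max(abs(applyProjection(fit, toy$X))), 1e-10)
  V <- matrix(rnorm(n * 3), n, 3)
  theta <- unname(varianceComponents(fit))
  Sig <- denseSigma(theta, list(as.matrix(relationshipMatrix(toy$km))), n)
  P <- denseProjection(Sig, toy$X)
  expect_equal(applyProjection(fit, V), P %*% V, tolerance = 1e-8,
               ignore_attr = TRUE)
  # P is idempotent in the Sigma inner product
  expect_equal(P %*% Sig %*% P, P, tolerance = 1e-8)
  expect_error(applyProjection(fit, V[-1, ]), "row")
})

test_that("REML estimates are invariant to affine reparameterization of X", {
  toy <- makeToyCohort(nNuclear = 12, nExtended = 1, seed = 61)
  fit1 <- fitNullModel(toy$trait$y, toy$X, toy$km)
  A <- matrix(c(1, 0.3, -0.2, 0, 2, 0.1, 0, 0, -1.5), 3, 3)
  fit2 <- fitNullModel(toy$trait$y, toy$X %*% A, toy$km)
  expect_equal(unname(varianceComponents(fit1)),
               unname(varianceComponents(fit2)), tolerance = 1e-4)
  expect_equal(scaledResiduals(fit1), scaledResiduals(fit2),
               tolerance = 1e-5)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  set.seed(71)
  n <- 30
  X <- cbind(intercept = 1, a = rnorm(n))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fitNullModel(rnorm(n), X, list()), "dup")
})

test_that("variance-component helpers build the documented structures", {
  Psi0 <- Matrix::Diagonal(4)
  e <- c(1, 2, 0.5, -1)
  Ps <- randomSlopeComponent(Psi0, e)
  expect_equal(as.matrix(Ps), diag(e^2), ignore_attr = TRUE)
  Pr <- repeatedMeasuresComponent(c("a", "a", "b", "b", "b"))
  expect_equal(as.matrix(Pr)[1:2, 1:2], matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(as.matrix(Pr)[1, 3], 0)
  # a repeated-measures fit recovers a sensible intercept variance
  set.seed(81)
  subj <- rep(1:80, each = 3)
  u <- rnorm(80)[subj]
  y <- 2 + u + rnorm(240, sd = 0.5)
  X <- cbind(intercept = rep(1, 240))
  fit <- fitNullModel(y, X, list(subject = repeatedMeasuresComponent(subj)))
  expect_equal(unname(varianceComponents(fit)[["subject"]]), 1,
               tolerance = 0.4)
  expect_equal(unname(varianceComponents(fit)[["residual"]]), 0.25,
               tolerance = 0.15)
})
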