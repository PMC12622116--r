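test_that("variant designs form interaction columns and guard exposures", {
  n <- 20
  X <- cbind(intercept = 1, e1 = rnorm(n))
  g <- rbinom(n, 2, 0.3)
  vd <- buildVariantDesign(g, cbind(e1 = X[, "e1"]), X)
  expect_equal(vd$K[, 1], g * X[, "e1"], ignore_attr = TRUE)
  expect_equal(vd$W, cbind(g = g, g_x_e1 = g * X[, "e1"]))
  # zero genotype gives zero interaction
  vd0 <- buildVariantDesign(rep(0, n), cbind(e1 = X[, "e1"]), X)
  expect_true(all(vd0$K == 0))
  # unit exposure reproduces the genotype
  vd1 <- buildVariantDesign(g, cbind(e1 = rep(1, n)), X, override = TRUE)
  expect_equal(vd1$K[, 1], as.numeric(g), ignore_attr = TRUE)
  # missing genotypes are mean-imputed before products
  gm <- g; gm[3] <- NA
  vdm <- buildVariantDesign(gm, cbind(e1 = X[, "e1"]), X)
  expect_equal(vdm$g[3], mean(gm, na.rm = TRUE))
  expect_equal(vdm$K[3, 1], mean(gm, na.rm = TRUE) * X[3, "e1"],
               ignore_attr = TRUE)
  # exposures must carry a main effect in the null design
  expect_error(buildVariantDesign(g, cbind(other = rnorm(n)), X),
               "not a column")
  expect_silent(buildVariantDesign(g, cbind(other = rnorm(n)), X,
                                   override = TRUE))
})

test_that("all strategies match the dense reference implementation", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 0, nVariants = 6, seed = 91)
  n <- length(toy$trait$y)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  theta <- unname(varianceComponents(fit))
  Sig <- denseSigma(theta, list(as.matrix(relationshipMatrix(toy$km))), n)
  E <- cbind(x1 = toy$trait$x1)
  fitLM <- fitNullModel(toy$trait$y, toy$X, list())
  s2 <- varianceComponents(fitLM)[["residual"]]
  res2 <- twoStepResiduals(fit)
  fitTS <- fitNullModel(res2, toy$X, list())
  s2ts <- varianceComponents(fitTS)[["residual"]]
  for (v in seq_len(ncol(toy$G))) {
    g <- toy$G[, v]
    if (var(g) == 0) next
    vd <- buildVariantDesign(g, E, toy$X)
    # RoM vs dense family-cluster sandwich
    o <- denseStrategy(toy$trait$y, toy$X, Sig, g, E, toy$clusterId)
    r <- romTest(fit, vd)
    expect_equal(r$T_I, o$T_I, tolerance = 1e-8)
    expect_equal(r$T_J, o$T_J, tolerance = 1e-8)
    expect_equal(c(r$beta, r$gamma1), unname(o$zeta), tolerance = 1e-8)
    d <- attr(r, "detail")
    expect_equal(d$covJ, o$covJ, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(d$covI, o$covI, tolerance = 1e-8, ignore_attr = TRUE)
    # model-based
    ob <- denseStrategy(toy$trait$y, toy$X, Sig, g, E, toy$clusterId, "none")
    rb <- modelBasedTest(fit, vd)
    expect_equal(rb$T_I, ob$T_I, tolerance = 1e-8)
    expect_equal(rb$T_J, ob$T_J, tolerance = 1e-8)
    # individual clusters from the same mixed model
    oi <- denseStrategy(toy$trait$y, toy$X, Sig, g, E, seq_len(n))
    ri <- icbTest(fit, vd)
    expect_equal(ri$T_I, oi$T_I, tolerance = 1e-8)
    expect_equal(ri$T_J, oi$T_J, tolerance = 1e-8)
    # two-step: dense oracle on the residual outcome with sigma^2 I
    ot <- denseStrategy(res2, toy$X, diag(s2ts, n), g, E, seq_len(n))
    rt <- twoStepTest(toy$trait$y, toy$X, toy$km, vd, step1 = fit)
    expect_equal(rt$T_I, ot$T_I, tolerance = 1e-8)
    expect_equal(rt$T_J, ot$T_J, tolerance = 1e-8)
    # plain linear model with individual clusters
    ol <- denseStrategy(toy$trait$y, toy$X, diag(s2, n), g, E, seq_len(n))
    rl <- lmIcbTest(toy$trait$y, toy$X, vd)
    expect_equal(rl$T_I, ol$T_I, tolerance = 1e-8)
    expect_equal(rl$T_J, ol$T_J, tolerance = 1e-8)
    # marginal genetic score test
    Rt <- drop(denseProjection(Sig, toy$X) %*% toy$trait$y)
    Pg <- drop(denseProjection(Sig, toy$X) %*% g)
    expect_equal(marginalTest(fit, g)$T_M, sum(g * Rt)^2 / sum(g * Pg),
                 tolerance = 1e-8)
  }
})

test_that("bread and meat obey the partitioned-matrix block identities", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 1, nVariants = 4, seed = 101)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  E <- cbind(x1 = toy$trait$x1, x2 = toy$trait$x2)
  for (v in 1:4) {
    g <- toy$G[, v]
    if (var(g) == 0) next
    vd <- buildVariantDesign(g, E, toy$X)
    r <- romTest(fit, vd)
    d <- attr(r, "detail")
    # B_I equals the K-block of B_J (Schur-complement inverse identity)
    expect_equal(d$BI, d$BJ[-1, -1], tolerance = 1e-10, ignore_attr = TRUE)
    # cov(gamma) is assembled from exactly the K-block of the joint meat
    expect_equal(d$covI, d$BI %*% d$MJ[-1, -1] %*% d$BI, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("singleton clustering makes RoM identical to the ICB strategy", {
  toy <- makeToyCohort(nNuclear = 8, nExtended = 1, nVariants = 5, seed = 111)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  for (v in 1:5) {
    if (var(toy$G[, v]) == 0) next
    vd <- buildVariantDesign(toy$G[, v], cbind(x1 = toy$trait$x1), toy$X)
    a <- romTest(fit, vd, clusters = as.list(seq_along(toy$trait$y)))
    b <- icbTest(fit, vd)
    expect_equal(a$T_I, b$T_I, tolerance = 1e-12)
    expect_equal(a$T_J, b$T_J, tolerance = 1e-12)
  }
})

test_that("with unrelated samples and intercept-only covariates the sandwich is textbook HC0", {
  set.seed(121)
  n <- 80
  y <- rnorm(n)
  X <- cbind(intercept = rep(1, n))
  g <- rbinom(n, 2, 0.4)
  e <- rnorm(n)
  vd <- buildVariantDesign(g, cbind(e = e), X, override = TRUE)
  fit <- fitNullModel(y, X, list())
  r <- romTest(fit, vd, clusters = as.list(seq_len(n)))
  o <- hc0Oracle(y, vd$W)
  expect_equal(c(r$beta, r$gamma1), unname(o$zeta), tolerance = 1e-10)
  expect_equal(attr(r, "detail")$covJ, o$cov, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(r$T_J, o$T_J, tolerance = 1e-10)
})

test_that("degenerate variants are skipped with machine-readable reasons", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 0, nVariants = 2, seed = 131)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  n <- length(toy$trait$y)
  # monomorphic
  vd <- buildVariantDesign(rep(0, n), cbind(x1 = toy$trait$x1), toy$X)
  expect_equal(romTest(fit, vd)$skip_reason, "zero genetic variance")
  # interaction exactly collinear with genotype (constant exposure)
  g <- toy$G[, 1]
  vd <- buildVariantDesign(g, cbind(c = rep(2, n)), toy$X, override = TRUE)
  expect_match(romTest(fit, vd)$skip_reason, "collinear|singular")
  # zero score: model-based statistic is 0 with p = 1
  y0 <- drop(toy$X %*% c(1, 2, 3))
  fit0 <- fitNullModel(y0, toy$X, toy$km)
  vd <- buildVariantDesign(g, cbind(x1 = toy$trait$x1), toy$X)
  rb <- modelBasedTest(fit0, vd)
  expect_equal(rb$T_J, 0, tolerance = 1e-10)
  expect_equal(rb$p_J, 1, tolerance = 1e-10)
})

test_that("statistics are invariant to affine rescaling of the exposure", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 1, nVariants = 3, seed = 141)
  y <- toy$trait$y
  X1 <- toy$X
  X2 <- X1; X2[, "x1"] <- 3 * X1[, "x1"]
  fit1 <- fitNullModel(y, X1, toy$km)
  fit2 <- fitNullModel(y, X2, toy$km)
  for (v in 1:3) {
    g <- toy$G[, v]
    if (var(g) == 0) next
    vd1 <- buildVariantDesign(g, cbind(x1 = X1[, "x1"]), X1)
    vd2 <- buildVariantDesign(g, cbind(x1 = X2[, "x1"]), X2)
    a <- romTest(fit1, vd1); b <- romTest(fit2, vd2)
    expect_equal(a$T_I, b$T_I, tolerance = 1e-6)
    expect_equal(a$T_J, b$T_J, tolerance = 1e-6)
  }
})

test_that("two-step on independent samples equals the plain linear-model test", {
  set.seed(151)
  n <- 100
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 0.3 * x1 + rnorm(n)
  X <- nullDesign(x1, x2)
  g <- rbinom(n, 2, 0.3)
  vd <- buildVariantDesign(g, cbind(x1 = x1), X)
  ts <- twoStepTest(y, X, list(), vd)
  lm <- lmIcbTest(y, X, vd)
  expect_equal(ts$T_I, lm$T_I, tolerance = 1e-10)
  expect_equal(ts$T_J, lm$T_J, tolerance = 1e-10)
  # and with an (irrelevant) kinship component the fit floors lambda and
  # the two agree to optimizer tolerance
  km <- computeKinship(buildPedigree(25, 0))
  yind <- 1 + 0.3 * x1 + rnorm(n)  # no familial component
  ts2 <- twoStepTest(yind, X, km, vd)
  lm2 <- lmIcbTest(yind, X, vd)
  expect_equal(ts2$T_J, lm2$T_J, tolerance = 1e-2)
})

test_that("marginal statistic vanishes when the genotype is orthogonal to the residuals", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 0, nVariants = 2, seed = 161)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  Rt <- scaledResiduals(fit)
  g <- toy$G[, 1]
  g0 <- g - sum(g * Rt) / sum(Rt * Rt) * Rt  # project out the residuals
  expect_lt(marginalTest(fit, g0)$T_M, 1e-16)
})
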