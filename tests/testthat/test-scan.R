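test_that("scan reproduces single-variant calls for every strategy", {
  toy <- makeToyCohort(nNuclear = 12, nExtended = 2, nVariants = 15, seed = 171)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  E <- cbind(x1 = toy$trait$x1)
  all <- c("RoM", "LMM-MB", "LMM-ICB", "Two-step-ICB", "LM-ICB", "marginal")
  res <- scanVariants(fit, toy$G, E, strategies = all, blockSize = 4)
  for (v in seq_len(ncol(toy$G))) {
    g <- toy$G[, v]
    id <- paste0("v", v)
    if (var(g) == 0) next
    vd <- buildVariantDesign(g, E, toy$X)
    single <- list(
      "RoM" = romTest(fit, vd),
      "LMM-MB" = modelBasedTest(fit, vd),
      "LMM-ICB" = icbTest(fit, vd),
      "Two-step-ICB" = twoStepTest(toy$trait$y, toy$X, toy$km, vd, step1 = fit),
      "LM-ICB" = lmIcbTest(toy$trait$y, toy$X, vd))
    for (st in names(single)) {
      row <- res[res$strategy == st & res$variant == id, ]
      expect_equal(row$T_I, single[[st]]$T_I, tolerance = 1e-10)
      expect_equal(row$T_J, single[[st]]$T_J, tolerance = 1e-10)
      expect_equal(row$beta, single[[st]]$beta, tolerance = 1e-10)
    }
    mrow <- res[res$strategy == "marginal" & res$variant == id, ]
    expect_equal(mrow$T_M, marginalTest(fit, g)$T_M, tolerance = 1e-10)
  }
})

test_that("scan results are invariant to block size and to streaming input", {
  toy <- makeToyCohort(nNuclear = 15, nExtended = 1, nVariants = 23, seed = 181)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  E <- cbind(x1 = toy$trait$x1)
  r1 <- scanVariants(fit, toy$G, E, strategies = c("RoM", "LMM-MB"),
                     blockSize = 23)
  r2 <- scanVariants(fit, toy$G, E, strategies = c("RoM", "LMM-MB"),
                     blockSize = 5)
  expect_equal(r1, r2, tolerance = 1e-12)
  # streaming source function yields the same results
  k <- 0
  src <- function() {
    k <<- k + 1
    if (k > 3) return(NULL)
    cols <- switch(k, 1:10, 11:20, 21:23)
    out <- toy$G[, cols, drop = FALSE]
    colnames(out) <- paste0("v", cols)
    out
  }
  r3 <- scanVariants(fit, src, E, strategies = c("RoM", "LMM-MB"))
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("multi-exposure scans agree with the generic per-variant route", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 1, nVariants = 8, seed = 191)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  E <- cbind(x1 = toy$trait$x1, x2 = toy$trait$x2)
  res <- scanVariants(fit, toy$G, E, strategies = c("RoM", "LMM-ICB"))
  expect_equal(unique(res$df_I), 2)
  expect_equal(unique(res$df_J), 3)
  for (v in seq_len(8)) {
    if (var(toy$G[, v]) == 0) next
    vd <- buildVariantDesign(toy$G[, v], E, toy$X)
    row <- res[res$strategy == "RoM" & res$variant == paste0("v", v), ]
    single <- romTest(fit, vd)
    expect_equal(row$T_I, single$T_I, tolerance = 1e-10)
    expect_equal(row$T_J, single$T_J, tolerance = 1e-10)
    expect_equal(c(row$gamma1, row$gamma2),
                 c(single$gamma1, single$gamma2), tolerance = 1e-10)
  }
})

test_that("empty input, missing genotypes and skips are handled", {
  toy <- makeToyCohort(nNuclear = 10, nExtended = 0, nVariants = 4, seed = 201)
  fit <- fitNullModel(toy$trait$y, toy$X, toy$km)
  E <- cbind(x1 = toy$trait$x1)
  empty <- scanVariants(fit, toy$G[, 0, drop = FALSE], E)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("variant", "T_I", "p_J", "strategy") %in% names(empty)))
  # missing genotypes are mean-imputed, matching the single-variant policy
  G <- toy$G
  G[c(2, 9), 1] <- NA
  res <- scanVariants(fit, G, E, strategies = "RoM")
  vd <- buildVariantDesign(G[, 1], E, toy$X)
  expect_equal(res$T_J[res$variant == "v1"], romTest(fit, vd)$T_J,
               tolerance = 1e-10)
  # monomorphic column is reported, not dropped
  G[, 2] <- 0
  res <- scanVariants(fit, G, E, strategies = "RoM")
  expect_equal(res$skip_reason[res$variant == "v2"], "zero genetic variance")
  expect_true(is.na(res$p_J[res$variant == "v2"]))
})

test_that("projection cost scales about linearly with sample size", {
  cost <- vapply(c(1, 2), function(s) {
    ped <- buildPedigree(150 * s, 25 * s)
    km <- computeKinship(ped)
    expo <- simulateExposures(km, seed = 3)
    tr <- simulateTrait(km, expo$x1, expo$x2, calibrateEffects(), seed = 4)
    fit <- fitNullModel(tr$y, nullDesign(tr$x1, tr$x2), km)
    V <- matrix(rnorm(length(tr$y) * 50), ncol = 50)
    t0 <- proc.time()
    for (i in 1:20) invisible(applyProjection(fit, V))
    (proc.time() - t0)[[3]]
  }, 0)
  # doubling N should not blow past a generous linearity envelope
  expect_lt(cost[2], 6 * max(cost[1], 0.02))
})
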