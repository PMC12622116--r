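#' Genome-wide scan over variant blocks
#'
#' Streams variants in blocks and computes, for every requested strategy,
#' the GEI statistic `T_I` (chi-square, q df) and the joint statistic `T_J`
#' (q+1 df). The mixed-model strategies (`"RoM"`, `"LMM-MB"`, `"LMM-ICB"`,
#' `"marginal"`) share one null fit; `"Two-step-ICB"` reuses the same fit as
#' its first step and `"LM-ICB"` refits a plain linear model, both built
#' once per scan. All per-variant work is vectorized across a block, so the
#' scan costs O(N) per variant for bounded cluster sizes.
#'
#' @param fit covariates-only [NullModelFit-class] (the mixed-model null).
#' @param genotypes an individuals x variants matrix, or a no-argument
#'   function returning successive genotype blocks (`NULL` when exhausted)
#'   for streaming scans.
#' @param exposures vector or N x q matrix of tested exposures.
#' @param strategies subset of `c("RoM", "LMM-MB", "LMM-ICB",
#'   "Two-step-ICB", "LM-ICB", "marginal")`.
#' @param clusters sandwich clusters for `"RoM"`; defaults to the fit's.
#' @param blockSize variants per block when `genotypes` is a matrix.
#' @param twoStepResidualType passed to [twoStepResiduals()].
#' @param override allow exposures absent from the null design.
#' @return data.frame, one row per variant x strategy, in input variant
#'   order; skipped variants carry a `skip_reason` and `NA` statistics.
#' @export
scanVariants <- function(fit, genotypes, exposures,
                         strategies = "RoM", clusters = fit@clusters,
                         blockSize = 1024L,
                         twoStepResidualType = c("conditional", "marginal"),
                         override = FALSE) {
  twoStepResidualType <- match.arg(twoStepResidualType)
  known <- c("RoM", "LMM-MB", "LMM-ICB", "Two-step-ICB", "LM-ICB", "marginal")
  if (!all(strategies %in% known))
    stop("unknown strategy: ", paste(setdiff(strategies, known), collapse = ", "))
  E <- as.matrix(exposures)
  if (is.null(colnames(E))) colnames(E) <- paste0("E", seq_len(ncol(E)))
  n <- length(fit@y)
  stopifnot(nrow(E) == n)
  if (!override) buildVariantDesign(rep(1, n), E, fit@X, override = FALSE)

  contexts <- list()
  lmmStrats <- intersect(strategies, c("RoM", "LMM-MB", "LMM-ICB", "marginal"))
  if (length(lmmStrats))
    contexts$lmm <- list(fit = fit, strategies = lmmStrats,
                         cid = .clusterId(clusters, n))
  if ("Two-step-ICB" %in% strategies) {
    res <- twoStepResiduals(fit, twoStepResidualType)
    contexts$twostep <- list(fit = fitNullModel(res, fit@X, list()),
                             strategies = "Two-step-ICB", cid = NULL)
  }
  if ("LM-ICB" %in% strategies)
    contexts$lm <- list(fit = fitNullModel(fit@y, fit@X, list()),
                        strategies = "LM-ICB", cid = NULL)

  nextBlock <- if (is.function(genotypes)) {
    genotypes
  } else {
    Gall <- as.matrix(genotypes)
    stopifnot(nrow(Gall) == n)
    starts <- seq(1L, max(ncol(Gall), 1L), by = blockSize)
    k <- 0L
    function() {
      k <<- k + 1L
      if (ncol(Gall) == 0L || k > length(starts)) return(NULL)
      cols <- starts[k]:min(starts[k] + blockSize - 1L, ncol(Gall))
      Gall[, cols, drop = FALSE]
    }
  }

  out <- list()
  offset <- 0L
  repeat {
    Gb <- nextBlock()
    if (is.null(Gb)) break
    if (nrow(Gb) != n) stop("genotype block has wrong number of rows")
    storage.mode(Gb) <- "double"
    ids <- colnames(Gb)
    if (is.null(ids)) ids <- paste0("v", offset + seq_len(ncol(Gb)))
    for (ctx in contexts)
      out[[length(out) + 1L]] <- .scanBlock(ctx, Gb, E, ids)
    offset <- offset + ncol(Gb)
  }
  if (!length(out)) return(.emptyScan(ncol(E), any(strategies == "marginal")))
  res <- .rbindFill(out)
  res <- res[order(match(res$variant, unique(res$variant)),
                   match(res$strategy, known)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.emptyScan <- function(q, marginal = FALSE) {
  proto <- .skipRow("x", "RoM", q, "x")[0, ]
  proto
}

# vectorized block computation for one fit context
.scanBlock <- function(ctx, G, E, ids) {
  fit <- ctx$fit
  n <- nrow(G); B <- ncol(G); q <- ncol(E)
  Rt <- fit@residuals
  if (anyNA(G)) {
    na <- which(is.na(G))
    cm <- colMeans(G, na.rm = TRUE)
    G[na] <- cm[(na - 1L) %/% n + 1L]
  }
  mac <- pmin(colSums(G), colSums(2 - G))
  Gadj <- .covariateAdjust(fit, G)
  PG <- as.matrix(fit@Vinv %*% Gadj)  # P G = Sigma^-1 Gadj
  a <- colSums(G * PG)
  Ks <- vector("list", q); Kadj <- vector("list", q); PKs <- vector("list", q)
  for (m in seq_len(q)) {
    Ks[[m]] <- G * E[, m]
    Kadj[[m]] <- .covariateAdjust(fit, Ks[[m]])
    PKs[[m]] <- as.matrix(fit@Vinv %*% Kadj[[m]])
  }
  b <- matrix(0, q, B)
  Cm <- array(0, c(q, q, B))
  sk <- matrix(0, q, B)
  for (m in seq_len(q)) {
    b[m, ] <- colSums(Ks[[m]] * PG)
    sk[m, ] <- colSums(Ks[[m]] * Rt)
    for (mm in m:q) {
      v <- colSums(Ks[[m]] * PKs[[mm]])
      Cm[m, mm, ] <- v; Cm[mm, m, ] <- v
    }
  }
  sg <- colSums(G * Rt)

  needFam <- "RoM" %in% ctx$strategies
  needInd <- any(c("LMM-ICB", "Two-step-ICB", "LM-ICB") %in% ctx$strategies)
  meats <- list()
  if (needFam) {
    SGc <- rowsum(Gadj * Rt, ctx$cid)
    SKc <- lapply(Kadj, function(K) rowsum(K * Rt, ctx$cid))
    meats$fam <- .meatEntries(SGc, SKc, q, B)
  }
  if (needInd) {
    SGi <- Gadj * Rt
    SKi <- lapply(Kadj, function(K) K * Rt)
    meats$ind <- .meatEntries(SGi, SKi, q, B)
  }

  rows <- vector("list", length(ctx$strategies))
  names(rows) <- ctx$strategies
  for (strat in ctx$strategies) {
    if (strat == "marginal") {
      Tm <- ifelse(mac >= 1 & a > 1e-8 * n, sg^2 / a, NA_real_)
      df <- data.frame(variant = ids, n = n, af = colMeans(G) / 2, T_M = Tm,
                       df_M = 1L,
                       p_M = stats::pchisq(Tm, 1, lower.tail = FALSE),
                       strategy = "marginal",
                       skip_reason = ifelse(is.na(Tm), "zero genetic variance",
                                            NA_character_),
                       stringsAsFactors = FALSE)
      rows[[strat]] <- df
      next
    }
    meat <- switch(strat, "RoM" = meats$fam, "LMM-MB" = NULL, meats$ind)
    rows[[strat]] <- .assembleStats(strat, ids, n, q, mac, a, b, Cm, sg, sk,
                                    meat, colMeans(G) / 2)
  }
  .rbindFill(rows[!vapply(rows, is.null, logical(1))])
}

# rbind data.frames with differing columns, padding with NA
.rbindFill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols, drop = FALSE]
  }))
}

.meatEntries <- function(SG, SK, q, B) {
  Mgg <- colSums(SG^2)
  MgK <- matrix(0, q, B)
  MKK <- array(0, c(q, q, B))
  for (m in seq_len(q)) {
    MgK[m, ] <- colSums(SG * SK[[m]])
    for (mm in m:q) {
      v <- colSums(SK[[m]] * SK[[mm]])
      MKK[m, mm, ] <- v; MKK[mm, m, ] <- v
    }
  }
  list(Mgg = Mgg, MgK = MgK, MKK = MKK)
}

# per-variant small-matrix assembly from precomputed block entries
.assembleStats <- function(strategy, ids, n, q, mac, a, b, Cm, sg, sk, meat,
                           af) {
  if (q == 1L)
    return(.assembleStatsQ1(strategy, ids, n, mac, a, drop(b), drop(Cm),
                            sg, drop(sk), meat, af))
  B <- length(a)
  beta <- TI <- TJ <- rep(NA_real_, B)
  gam <- matrix(NA_real_, q, B)
  skip <- rep(NA_character_, B)
  for (v in seq_len(B)) {
    if (mac[v] < 1 || a[v] <= 1e-8 * n) { skip[v] <- "zero genetic variance"; next }
    Gram <- rbind(c(a[v], b[, v]), cbind(b[, v], Cm[, , v]))
    BJ <- tryCatch(solve(Gram), error = function(e) NULL)
    if (is.null(BJ)) { skip[v] <- "singular bread"; next }
    s <- c(sg[v], sk[, v])
    zeta <- drop(BJ %*% s)
    Schur <- Cm[, , v, drop = FALSE]
    dim(Schur) <- c(q, q)
    Schur <- Schur - tcrossprod(b[, v, drop = FALSE]) / a[v]
    BI <- tryCatch(solve(Schur), error = function(e) NULL)
    if (is.null(BI) || any(!is.finite(BI))) {
      skip[v] <- "interaction collinear with genotype"; next
    }
    gm <- zeta[-1L]
    if (is.null(meat)) {
      tj <- drop(crossprod(zeta, Gram %*% zeta))
      ti <- drop(crossprod(gm, Schur %*% gm))
    } else {
      MJ <- rbind(c(meat$Mgg[v], meat$MgK[, v]),
                  cbind(meat$MgK[, v], matrix(meat$MKK[, , v], q, q)))
      covJ <- BJ %*% MJ %*% BJ
      covI <- BI %*% MJ[-1L, -1L, drop = FALSE] %*% BI
      tj <- tryCatch(drop(crossprod(zeta, solve(covJ, zeta))),
                     error = function(e) NA_real_)
      ti <- tryCatch(drop(crossprod(gm, solve(covI, gm))),
                     error = function(e) NA_real_)
      if (!is.finite(tj) || !is.finite(ti) || tj < 0 || ti < 0) {
        skip[v] <- "non-positive-definite sandwich"; next
      }
    }
    beta[v] <- zeta[1L]; gam[, v] <- gm; TI[v] <- ti; TJ[v] <- tj
  }
  df <- data.frame(variant = ids, n = ifelse(is.na(skip), n, NA_integer_),
                   af = af, beta = beta, stringsAsFactors = FALSE)
  for (m in seq_len(q)) df[[paste0("gamma", m)]] <- gam[m, ]
  df$T_I <- TI; df$df_I <- q
  df$p_I <- stats::pchisq(TI, q, lower.tail = FALSE)
  df$T_J <- TJ; df$df_J <- q + 1L
  df$p_J <- stats::pchisq(TJ, q + 1L, lower.tail = FALSE)
  df$neglog10_p_I <- -stats::pchisq(TI, q, lower.tail = FALSE, log.p = TRUE) / log(10)
  df$neglog10_p_J <- -stats::pchisq(TJ, q + 1L, lower.tail = FALSE, log.p = TRUE) / log(10)
  df$strategy <- strategy
  df$skip_reason <- skip
  df
}

# closed-form vectorized assembly for the single-exposure case (q = 1)
.assembleStatsQ1 <- function(strategy, ids, n, mac, a, b, C, sg, sk, meat, af) {
  B <- length(a)
  det <- a * C - b^2
  s1 <- C - b^2 / a                      # Schur complement (1/B_I)
  okG <- mac >= 1 & a > 1e-8 * n
  okB <- okG & is.finite(det) & det > 0 & s1 > 0
  beta <- gamma <- TI <- TJ <- rep(NA_real_, B)
  skip <- rep(NA_character_, B)
  skip[!okG] <- "zero genetic variance"
  skip[okG & !okB] <- "interaction collinear with genotype"
  beta[okB] <- ((C * sg - b * sk) / det)[okB]
  gamma[okB] <- ((a * sk - b * sg) / det)[okB]
  if (is.null(meat)) {
    TJ[okB] <- (a * beta^2 + 2 * b * beta * gamma + C * gamma^2)[okB]
    TI[okB] <- (gamma^2 * s1)[okB]
  } else {
    m11 <- meat$Mgg; m12 <- drop(meat$MgK); m22 <- drop(meat$MKK)
    # covJ = BJ %*% M %*% BJ with BJ = [C,-b;-b,a]/det, closed form
    c11 <- (C^2 * m11 - 2 * b * C * m12 + b^2 * m22) / det^2
    c12 <- (-b * C * m11 + (a * C + b^2) * m12 - a * b * m22) / det^2
    c22 <- (b^2 * m11 - 2 * a * b * m12 + a^2 * m22) / det^2
    dcov <- c11 * c22 - c12^2
    covI <- m22 / s1^2
    okS <- okB & is.finite(dcov) & dcov > 0 & c11 > 0 & c22 > 0 & covI > 0
    skip[okB & !okS] <- "non-positive-definite sandwich"
    TJ[okS] <- ((beta^2 * c22 - 2 * beta * gamma * c12 + gamma^2 * c11) /
                  dcov)[okS]
    TI[okS] <- (gamma^2 / covI)[okS]
    bad <- okS & (!is.finite(TJ) | !is.finite(TI) | TJ < 0 | TI < 0)
    if (any(bad)) {
      skip[bad] <- "non-positive-definite sandwich"
      TJ[bad] <- TI[bad] <- beta[bad] <- gamma[bad] <- NA_real_
    }
    beta[!okS] <- gamma[!okS] <- NA_real_
  }
  df <- data.frame(variant = ids, n = ifelse(is.na(skip), n, NA_integer_),
                   af = af, beta = beta, gamma1 = gamma,
                   stringsAsFactors = FALSE)
  df$T_I <- TI; df$df_I <- 1L
  df$p_I <- stats::pchisq(TI, 1, lower.tail = FALSE)
  df$T_J <- TJ; df$df_J <- 2L
  df$p_J <- stats::pchisq(TJ, 2, lower.tail = FALSE)
  df$neglog10_p_I <- -stats::pchisq(TI, 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  df$neglog10_p_J <- -stats::pchisq(TJ, 2, lower.tail = FALSE, log.p = TRUE) / log(10)
  df$strategy <- strategy
  df$skip_reason <- skip
  df
}
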