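# robustGEI

Robust mixed-model score tests for gene-environment interaction (GEI) and
joint genetic/GEI effects in samples with **related individuals** or
**repeated measures**.

## Why

Genome-wide GEI tests on family or longitudinal data are usually run from a
linear mixed model (LMM), but the model-implied (bread-only) variance of the
score is wrong whenever the environmental main effect is misspecified — a
quadratic BMI effect fitted as linear, say — and the resulting tests inflate
badly at genome-wide thresholds. The popular workaround of residualizing on
an LMM and testing in an ordinary linear model ("two-step") is not robust
either: for heritable exposures its joint test is systematically *deflated*.

`robustGEI` fits one covariates-only LMM by REML and then tests each variant
with a **family-clustered Huber-White sandwich** variance, which is robust to
mean-model misspecification while respecting relatedness. Cost per variant is
O(N) for bounded family sizes; no N x N matrix is ever formed.

## Model

For trait `y`, covariates `X` (exposures included), genotype `g` and
interaction design `K = g * E` over `q` exposures (`W = (g, K)`):

    y = X alpha + g beta + K gamma + r + eps,   r ~ N(0, sum_l lambda_l Psi_l)

With `P` the covariate-projected inverse of the fitted null covariance and
`R = P y` the scaled residuals:

    bread  B_J = (W' P W)^-1,   effects  zeta = B_J W' R
    meat   M_J = sum over families j of S_j' S_j,  S_j = sum_{i in j} R_i W~_i
    T_J = zeta' (B_J M_J B_J)^-1 zeta   ~  chi-square(q + 1)
    T_I = gamma' (B_I M_I B_I)^-1 gamma ~  chi-square(q)

where `W~` is the covariate-adjusted test design (see the methods vignette).
The comparison strategies `LMM-MB` (model-based), `LMM-ICB` (individual
clusters), `Two-step-ICB` and `LM-ICB`, plus the marginal genetic test, come
out of the same scan.

The package also ships the family-based simulation study the method is
validated on: nuclear + three-generation pedigrees (default 85,000
individuals in 14,750 families), gene-dropped genotypes, a heritable
exposure `x1 ~ N(0, 2 Psi)`, a non-heritable `x2 ~ N(0, 2)`, and a trait
with quadratic exposure effects calibrated to fixed variance shares —
dropping the quadratic terms from the null design reproduces the
misspecification scenario.

## Worked example

```r
library(robustGEI)

ped    <- buildPedigree(150, 24)            # 1,008 individuals, 174 families
km     <- computeKinship(ped)
G      <- simulateGenotypes(ped, drawMafs(500, seed = 1), seed = 2)
expo   <- simulateExposures(km, seed = 3)
alphas <- calibrateEffects()                # shares (0.1, 0.05, 0.1, 0.05)
trait  <- simulateTrait(km, expo$x1, expo$x2, alphas, seed = 4)

X   <- nullDesign(trait$x1, trait$x2)       # misspecified: quadratics dropped
fit <- fitNullModel(trait$y, X, km)
fit
#> NullModelFit: N = 1008, p = 3, converged (8 iterations)
#> variance components:
#> residual  kinship
#> 1.460860 0.625936

res <- scanVariants(fit, G, cbind(x1 = trait$x1),
                    strategies = c("RoM", "LMM-MB"))
head(res[res$strategy == "RoM",
         c("variant", "af", "beta", "gamma1", "T_I", "p_I", "T_J", "p_J")], 3)
#>   variant    af   beta  gamma1    T_I   p_I   T_J   p_J
#> 1      v1 0.170 0.0337  0.0974 1.2153 0.270 1.477 0.478
#> 3      v2 0.221 0.0995 -0.0410 0.2379 0.626 1.772 0.412
#> 5      v3 0.346 0.0327  0.0198 0.0468 0.829 0.266 0.875

evaluateScan(res, alpha = 0.01)$summary
#>   strategy test lambda_gc t1e_ratio t1e_se n_tests alpha
#> 1      RoM    I     1.003       0.8  0.398     500  0.01
#> 2      RoM    J     0.908       1.4  0.525     500  0.01
#> 3   LMM-MB    I     1.252       4.0  0.876     500  0.01
#> 4   LMM-MB    J     1.074       2.6  0.712     500  0.01
```

Under the misspecified null the model-based GEI statistics are already
inflated (`lambda_gc` 1.25; at this small scale the medians are noisy)
while the robust GEI test sits at 1.003. `beta`/`gamma1` are the
genetic main and interaction effect estimates, `T_I`/`T_J` the GEI (1 df)
and joint (2 df) statistics. Variants that cannot be tested carry a
`skip_reason` instead of statistics.

Real data goes through the same surface: `readGenotypes()` (VCF or PLINK1
bed/bim/fam), `readPhenotypes()`, `readRelatedness()` (GRM triplets or a
pedigree file), `alignSamples()`, then `fitNullModel()` + `scanVariants()`.
Repeated measures and random exposure slopes are extra variance components
(`repeatedMeasuresComponent()`, `randomSlopeComponent()`). A thin CLI over
the same functions is at `inst/cli/robustgei.R`
(`simulate` / `fit-null` / `test` / `evaluate` / `pipeline`).

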