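---
title: "Robust mixed-model tests for gene-environment interaction: models, design choices and limitations"
author: "robustGEI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust mixed-model tests for gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide tests of gene-environment interaction (GEI) ask whether a
variant's effect on a quantitative trait is modified by an exposure such as
BMI or sex, and joint tests ask whether the variant matters at all once such
modification is allowed. Two practical difficulties collide in cohorts with
related individuals. First, the trait is familially correlated, which a
linear mixed model (LMM) handles through kinship-structured random effects.
Second, the environmental main effect is almost never modeled exactly right
— a quadratic BMI effect fitted as linear is the canonical example — and a
misspecified mean model makes the model-implied variance of the score wrong,
inflating type I error at genome-wide thresholds precisely where it matters.

`robustGEI` implements a single-variant score test that addresses both at
once: one covariates-only LMM fit by REML, then per-variant statistics whose
variance is estimated by a Huber-White sandwich clustered on families. The
sandwich makes the test robust to mean-model misspecification; clustering on
families (rather than individuals) keeps it valid under relatedness. The
per-variant cost is linear in sample size when family sizes are bounded.

## Model and statistics

The null model is `y = X alpha + r + eps` with
`r ~ N(0, sum_l lambda_l Psi_l)` and `eps ~ N(0, lambda_0 I)`; the `Psi_l`
are block-diagonal relatedness matrices (typically `2 Psi` with `Psi` the
kinship matrix), fitted by average-information REML. Writing
`Sigma = lambda_0 I + sum_l lambda_l Psi_l`,
`P = Sigma^-1 - Sigma^-1 X (X' Sigma^-1 X)^-1 X' Sigma^-1` and
`R = P y` (the scaled residuals), a variant with genotype `g` and
interaction design `K = g * E` over `q` exposures yields `W = (g, K)` and

* bread: `B_J = (W' P W)^-1`, and `B_I` the inverse Schur complement with
  the genotype projected out;
* effects: `zeta = B_J W' R`, with `beta` the genetic main effect and
  `gamma` the interaction effects;
* meat: `M_J = sum_j S_j' S_j`, where `S_j` sums the per-subject score rows
  over family `j`; `M_I` is the `K` block of `M_J`;
* statistics: `T_J = zeta' (B_J M_J B_J)^-1 zeta` on `q + 1` df and
  `T_I = gamma' (B_I M_I B_I)^-1 gamma` on `q` df.

No N x N matrix is formed: `P V` is always computed as
`Sigma^-1 V - Sigma^-1 X (X' Sigma^-1 X)^-1 (X' Sigma^-1 V)` from cached
per-family Cholesky factors, and the meat from cluster sums.

### The per-subject score rows

The score `W' R` decomposes over subjects in more than one way, and the
choice changes the meat. The obvious `S_i = R_i W_i` sums correctly but its
empirical covariance is *not* a consistent estimate of the score variance
whenever `W` correlates with the null covariates — and `K = g * E` always
correlates with `E`, which sits in `X`. We validated both candidates
against the simulation behavior the method is supposed to reproduce: with
raw rows the plain linear-model comparison strategy came out deflated where
it must be grossly inflated, and the family-clustered test itself deflated
to an inflation factor near 0.6. The package therefore uses the
covariate-adjusted rows

```
S_i = R_i * (W - X (X' Sigma^-1 X)^-1 X' Sigma^-1 W)_i ,
```

which sum to the identical score (because `X' R = 0`), are the standard
construction for robust score tests, and reproduce every reported
qualitative behavior. With an identity working covariance and
intercept-only covariates this reduces exactly to the textbook HC0
heteroskedasticity-robust computation on the centered design, which the
test suite checks to machine precision.

## Comparison strategies

Four alternatives frame the main test, all computed from the same scan:

* **LMM-MB** — model-based variance (`B^-1` in place of the sandwich); the
  negative control that inflates under mean misspecification.
* **LMM-ICB** — same LMM, sandwich with every individual its own cluster;
  misspecifies the clustering for family data.
* **Two-step-ICB** — fits the covariates-only LMM, takes its residuals as
  the outcome of an ordinary linear model with the same covariates, then
  applies the individual-cluster sandwich. Default residuals are
  conditional (BLUP of the random effects subtracted), which for
  `Sigma = lambda_0 I + ...` equal `lambda_0` times the scaled residuals; a
  flag switches to marginal residuals for sensitivity analysis.
* **LM-ICB** — ordinary linear null model, individual clusters.

A marginal genetic score test (`(g' R)^2 / (g' P g)`, 1 df) is included for
completeness.

## The simulation module

The synthetic cohort mirrors a family-based GWAS design: 12,750 nuclear
families (2 founder parents, 2 offspring) and 2,000 three-generation
extended families, 85,000 individuals with 35,500 founders in total. The
extended-family shape — 2 founder grandparents, 3 second-generation
offspring each married to a founder spouse, 3 children per couple (17
members, 5 founders) — is the unique simple three-generation,
three-offspring-per-generation structure consistent with both printed
totals; we fix it as such.

Genotypes are produced by gene dropping: founder haplotype alleles i.i.d.
Bernoulli(MAF), each offspring inheriting one uniformly chosen haplotype
per parent, independently per variant (no linkage). MAFs are drawn
Uniform(0.05, 0.5) per variant, a flat default for a common-variant panel
since no distribution is prescribed. The trait model is

```
y = 1 + a1 x1 + a2 x1^2 + a3 x2 + a4 x2^2 + r + eps
```

with a heritable exposure `x1 ~ N(0, 2 Psi)`, a non-heritable exposure
`x2 ~ N(0, 2)`, polygenic `r ~ N(0, 2 Psi)` and unit-variance noise. The
kinship convention has `diag(Psi) = 0.5`, so every `2 Psi` covariance has
unit diagonal: `Var(x1) = 1` while `Var(x2) = 2` as literally specified,
and the calibration respects that asymmetry. Effects are calibrated in
closed form to variance shares (0.1, 0.05, 0.1, 0.05): for centered
normals `Cov(x, x^2) = 0` and `Var(x^2) = 2 sigma^4`, so all five random
terms are orthogonal, `Var(y) = 2 / 0.7`, and
`a_j = sqrt(share_j Var(y) / v_j)` with `v = (1, 2, 2, 8)`. The test suite
verifies the shares empirically rather than trusting the algebra.

The misspecification scenario drops the quadratic terms from the null
design (intercept + linear `x1` + linear `x2`); `nullDesign(..., correct =
TRUE)` restores them for calibration checks.

What the generator does *not* emulate: linkage disequilibrium, sex
chromosomes, genotyping error and missingness, ascertainment, population
stratification, binary traits. Passing tests therefore demonstrate correct
behavior under clean family structure and exchangeable common variants, not
robustness to those additional features of real cohorts.

## Numerical choices

* **REML**: average-information updates with step-halving so the restricted
  likelihood never decreases on accepted steps; relative-change tolerance
  1e-6, at most 100 iterations; on failure a Nelder-Mead polish of the same
  criterion on log-variances. Components are floored at `1e-10 Var(y)`
  rather than zero so `Sigma` stays invertible. Non-convergence is flagged
  on the returned object, never silent.
* **Factorization**: dense Cholesky per relatedness block (connected
  components of the combined `Psi_l` pattern; at most 17 individuals in the
  simulated design, subjects in the repeated-measures case). The inverse
  blocks are also assembled into one sparse matrix so genome scans can
  project whole variant blocks with a single sparse-dense product.
* **Skip policy**: variants with minor allele count below 1, `g' P g <=
  1e-8 N`, a singular bread, or a non-positive-definite sandwich are
  reported with machine-readable `skip_reason` and `NA` statistics, never
  with fabricated p-values.
* **Missing genotypes** are mean-imputed per variant before interaction
  columns are formed, matching common GWAS practice; tested exposures must
  already appear in the null design unless explicitly overridden, so an
  interaction is never tested without its main effect.
* **P-values** are upper-tail chi-square probabilities; `-log10 p` is also
  emitted from the log-scale survival function to avoid underflow.
* **Random slopes / repeated measures** need no special code path:
  `randomSlopeComponent()` builds `D Psi D` with `D = diag(exposure)` and
  `repeatedMeasuresComponent()` a within-subject block of ones, both just
  extra variance components.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed, and genotypes are
simulated in fixed-size internal chunks so results do not depend on how
many variants are requested per call. Scan output is ordered by variant
then strategy and is invariant to the scan block size; the pipeline writes
a seed and configuration hash into every output header and is
byte-reproducible under a fixed seed.

The packaged analyses run on a 1/10-scale cohort (1,275 nuclear + 200
extended families, 8,500 individuals) chosen to preserve the family-type
proportions of the full design. Calibration under the correctly specified
null uses 1e5 streamed variants pooled over 4 trait replicates (pooling
replicates is also how the full-scale study reports QQ and inflation); the
misspecification study pools 20 trait
replicates of 10,000 variants for the two-step strategy and 2,000 variants
per replicate for the remaining strategies, sizes at which the pooled
median-based inflation factors are stable to well under 0.01. The
strategy-ordering check at significance level 1e-4 reuses those pooled
scans.

## Known limitations

* Gaussian traits only; no generalized (logistic) mixed models.
* Single-variant tests only; no rare-variant aggregation or meta-analysis
  output formats.
* The sandwich is asymptotic in the number of clusters: with few families,
  or very unbalanced cluster sizes, tail calibration degrades (visible as
  inflated QQ tails at smaller sample sizes).
* The interaction-test meat uses the raw `K` block of the joint meat; the
  `H`-projected alternative (projecting the genotype out of the score rows
  as well) differs and was not adopted.
* No multiple-testing machinery is provided: analyses are expected to use
  fixed genome-wide thresholds on the raw p-values.
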