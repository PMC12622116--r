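# Small simulated cohorts shared across test files; everything is built in
# code with fixed seeds.

makeToyCohort <- function(nNuclear = 10, nExtended = 0, nVariants = 12,
                          seed = 7, correct = FALSE) {
  ped <- buildPedigree(nNuclear, nExtended)
  km <- computeKinship(ped)
  G <- simulateGenotypes(ped, drawMafs(nVariants, seed = seed), seed = seed + 1)
  expo <- simulateExposures(km, seed = seed + 2)
  alphas <- calibrateEffects()
  trait <- simulateTrait(km, expo$x1, expo$x2, alphas, seed = seed + 3)
  X <- nullDesign(trait$x1, trait$x2, correct = correct)
  list(ped = ped, km = km, G = G, trait = trait, X = X,
       clusterId = rep(seq_along(km@clusters), lengths(km@clusters))[
         order(unlist(km@clusters))])
}

# cohort preserving the default design's family-type proportions at 1/10 scale
makeScaledCohort <- function(scale = 10, seed = 11) {
  ped <- buildPedigree(12750 / scale, 2000 / scale)
  km <- computeKinship(ped)
  list(ped = ped, km = km, seed = seed)
}
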