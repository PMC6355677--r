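# Shared fixture builders: all synthetic, generated in code at test time.

tinyDesign <- function(genotypes = c("gA", "gB"),
                       treatments = c("control", "drought"),
                       replicates = 3L,
                       timepoints = seq(55, 147, by = 2),
                       nBarePots = 0L) {
  ExperimentDesign(genotypes, treatments, replicates, timepoints, nBarePots)
}

tinyGrowth <- function(genotypes = c("gA", "gB"),
                       K = c(140000, 160000),
                       treatment_factor = c(0.6, 0.9),
                       cv_noise = 0) {
  data.frame(genotype = genotypes, K = K, r = 0.12, t_mid = 70,
             treatment_factor = treatment_factor, cv_noise = cv_noise)
}

tinyWater <- function(targetFraction = 0.9) {
  WaterParams(fcWeight = 1200, targetFraction = targetFraction,
              evapRate = 5, transpCoeff = 3e-4, weighInterval = 2)
}

tinyBundle <- function(seed = 1, cv_noise = 0, ...) {
  generateExperiment(tinyDesign(), tinyGrowth(cv_noise = cv_noise),
                     tinyWater(), seed = seed, stressStartDay = 104, ...)
}

# Independent closed-form evaluation of the piecewise logistic growth mean,
# written directly from the model definition (oracle for simulateGrowth).
refGrowthMean <- function(K, r, tMid, f, s, t) {
  logis <- function(tt, KK, rr) KK / (1 + exp(-rr * (tt - tMid)))
  vapply(t, function(tt) {
    if (tt < s || !is.finite(s)) return(logis(tt, K, r))
    As <- logis(s, K, r)
    K2 <- K * f
    r2 <- r * f
    K2 / (1 + ((K2 - As) / As) * exp(-r2 * (tt - s)))
  }, numeric(1))
}
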