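# Preset experimental designs: a durum-wheat drought screen (36 single-seed
# descent genotypes plus three reference varieties, control vs drought, three
# replicates, imaged every other day from 55 to 147 DAS with stress from 104
# DAS) and a tomato biostimulant trial (untreated control plus six prototype
# arms at 70% field capacity, five replicates, 22 days, ten bare-soil
# evaporation pots).

.wheatGenotypes <- c(
  "35", "44", "64", "69", "92", "96", "99", "109", "112", "116", "122",
  "135", "171", "178", "195", "231", "244", "253", "269", "278", "322",
  "325", "335", "343", "397", "409", "415", "416", "441", "451", "459",
  "467", "477", "487", "494", "511", "Cappelli", "Saragolla", "Svevo"
)

# End-of-run drought-to-control biovolume ratios per genotype; these set the
# per-genotype stress severity so the simulated panel spans the observed
# tolerant-to-susceptible range (~0.5 to ~1).
.wheatFactors <- c(
  0.69, 0.81, 0.67, 0.67, 0.72, 0.69, 0.52, 0.74, 0.66, 0.80, 0.68,
  0.53, 0.75, 0.56, 0.93, 0.80, 0.72, 0.62, 0.89, 0.64, 0.83,
  0.62, 0.69, 0.94, 0.69, 0.97, 0.71, 0.89, 0.69, 0.79, 0.56,
  0.79, 0.86, 0.76, 0.76, 0.64, 0.97, 0.60, 0.88
)

.tomatoArms <- c("UTC70", "2148", "2197", "2219", "2220", "2221", "2390")
# Relative growth boost of each biostimulant arm over the untreated control;
# 2148 is the strongest performer.
.tomatoBoost <- c(1.00, 1.30, 1.10, 1.08, 1.15, 1.12, 1.05)

#' Preset designs, growth tables and water parameters
#'
#' `wheatDesign()`/`tomatoDesign()` return the factorial layouts of the two
#' emulated trials; `wheatGrowthTable()`/`tomatoGrowthTable()` the matching
#' per-genotype logistic growth parameters; `wheatWaterParams()`/
#' `tomatoWaterParams()` the irrigation regimes (wheat: 1200 g pots, control
#' near field capacity vs drought held at 50% FC, no bare pots; tomato:
#' 1800 g pots restored to 70% FC, ten bare pots).
#'
#' @param nGenotypes optionally keep only the first `n` genotypes/arms
#'   (scaled-down designs for fast simulation studies).
#' @return A design object, growth data.frame or water-parameter list.
#' @name presets
NULL

#' @rdname presets
#' @export
wheatDesign <- function(nGenotypes = NULL) {
  g <- .wheatGenotypes
  if (!is.null(nGenotypes)) g <- g[seq_len(nGenotypes)]
  ExperimentDesign(g, c("control", "drought"), replicates = 3L,
                   timepoints = seq(55, 147, by = 2), nBarePots = 0L,
                   label = "wheat_ssd")
}

#' @rdname presets
#' @export
wheatGrowthTable <- function(nGenotypes = NULL) {
  n <- length(.wheatGenotypes)
  out <- data.frame(
    genotype = .wheatGenotypes,
    K = 150000 * seq(0.85, 1.15, length.out = n),
    r = 0.12, t_mid = 70,
    treatment_factor = .wheatFactors,
    cv_noise = 0.05
  )
  if (!is.null(nGenotypes)) out <- out[seq_len(nGenotypes), ]
  out
}

#' @rdname presets
#' @export
wheatWaterParams <- function() {
  list(
    control = WaterParams(fcWeight = 1200, targetFraction = 0.95,
                          evapRate = 5, transpCoeff = 3e-4,
                          weighInterval = 2),
    drought = WaterParams(fcWeight = 1200, targetFraction = 0.5,
                          evapRate = 5, transpCoeff = 3e-4,
                          weighInterval = 2)
  )
}

#' @rdname presets
#' @export
tomatoDesign <- function(nGenotypes = NULL) {
  g <- .tomatoArms
  if (!is.null(nGenotypes)) g <- g[seq_len(nGenotypes)]
  ExperimentDesign(g, "RWM70", replicates = 5L,
                   timepoints = seq(0, 22, by = 2), nBarePots = 10L,
                   label = "tomato_rwm")
}

#' @rdname presets
#' @export
tomatoGrowthTable <- function(nGenotypes = NULL) {
  out <- data.frame(
    genotype = .tomatoArms,
    K = 60000 * .tomatoBoost,
    r = 0.25, t_mid = 10,
    treatment_factor = 1,
    cv_noise = 0.05
  )
  if (!is.null(nGenotypes)) out <- out[seq_len(nGenotypes), ]
  out
}

#' @rdname presets
#' @export
tomatoWaterParams <- function() {
  WaterParams(fcWeight = 1800, targetFraction = 0.7, evapRate = 8,
              transpCoeff = 5e-4, weighInterval = 2)
}

#' Generate a preset synthetic experiment
#'
#' Convenience wrapper combining the preset design, growth table and water
#' parameters into one [generateExperiment()] call. The wheat preset imposes
#' stress at 104 DAS; the tomato preset runs unstressed arms whose growth
#' boosts encode the biostimulant effects.
#'
#' @param preset "wheat_ssd" or "tomato_rwm".
#' @param seed integer seed.
#' @param nGenotypes optional scaled-down genotype/arm count.
#' @param ... passed on to [generateExperiment()] (e.g. `withImages`,
#'   `outDir`, `weightNoiseSd`).
#' @return A [PhenoExperiment-class].
#' @examples
#' pe <- presetExperiment("tomato_rwm", seed = 7)
#' @export
presetExperiment <- function(preset = c("wheat_ssd", "tomato_rwm"), seed,
                             nGenotypes = NULL, ...) {
  preset <- match.arg(preset)
  if (preset == "wheat_ssd") {
    generateExperiment(wheatDesign(nGenotypes), wheatGrowthTable(nGenotypes),
                       wheatWaterParams(), seed = seed,
                       stressStartDay = 104, ...)
  } else {
    generateExperiment(tomatoDesign(nGenotypes), tomatoGrowthTable(nGenotypes),
                       tomatoWaterParams(), seed = seed, ...)
  }
}

#' Day at which drought stress is imposed in the wheat preset
#' @return 104 (days after sowing).
#' @export
wheatStressStart <- function() 104
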