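#' @import methods
NULL

#' Growth-curve parameters for one genotype or treatment arm
#'
#' Parameters of the logistic growth model used by the synthetic-experiment
#' generator. A plant's projected area (pixels) follows
#' \eqn{A(t) = K / (1 + e^{-r (t - t_{mid})})} until the stress-onset day;
#' from that day the trajectory is re-initialised under the stressed carrying
#' capacity \eqn{K \cdot f} and rate \eqn{r \cdot f} (see
#' [simulateGrowth()]), so a factor below one produces the growth gap and
#' eventual decline characteristic of drought-stressed canopies.
#'
#' @slot K asymptotic projected area (pixels), > 0.
#' @slot r relative growth rate (per day), >= 0.
#' @slot tMid inflection day of the unstressed curve.
#' @slot treatmentFactor multiplier in (0, 1] applied to both K and r after
#'   stress onset; 1 means no stress effect.
#' @slot stressStartDay day index at which the stressed branch starts
#'   (`Inf` for never).
#' @slot cvNoise lognormal coefficient of variation of the multiplicative
#'   observation noise, >= 0.
#' @export
setClass("GrowthParams",
  representation(
    K = "numeric", r = "numeric", tMid = "numeric",
    treatmentFactor = "numeric", stressStartDay = "numeric",
    cvNoise = "numeric"
  )
)

setValidity("GrowthParams", function(object) {
  msg <- character()
  if (length(object@K) != 1 || !is.finite(object@K) || object@K <= 0)
    msg <- c(msg, "K must be a single positive number")
  if (length(object@r) != 1 || object@r < 0)
    msg <- c(msg, "r must be a single non-negative number")
  if (length(object@tMid) != 1 || !is.finite(object@tMid))
    msg <- c(msg, "tMid must be a single finite number")
  f <- object@treatmentFactor
  if (length(f) != 1 || !(f > 0 && f <= 1))
    msg <- c(msg, "treatmentFactor must lie in (0, 1]")
  if (length(object@cvNoise) != 1 || object@cvNoise < 0)
    msg <- c(msg, "cvNoise must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct growth parameters
#'
#' @param K asymptotic projected area (pixels).
#' @param r relative growth rate (per day).
#' @param tMid inflection day.
#' @param treatmentFactor post-stress multiplier in (0, 1].
#' @param stressStartDay stress-onset day (`Inf` disables the stressed branch).
#' @param cvNoise lognormal coefficient of variation of observation noise.
#' @return A [GrowthParams-class] object.
#' @examples
#' gp <- GrowthParams(K = 150000, r = 0.12, tMid = 70,
#'                    treatmentFactor = 0.7, stressStartDay = 104)
#' @export
GrowthParams <- function(K, r, tMid, treatmentFactor = 1,
                         stressStartDay = Inf, cvNoise = 0) {
  new("GrowthParams",
    K = as.numeric(K), r = as.numeric(r), tMid = as.numeric(tMid),
    treatmentFactor = as.numeric(treatmentFactor),
    stressStartDay = as.numeric(stressStartDay),
    cvNoise = as.numeric(cvNoise)
  )
}

#' Gravimetric water-budget parameters for one pot group
#'
#' @slot fcWeight pot weight at field capacity (g), > 0.
#' @slot targetFraction irrigation restore target as a fraction of field
#'   capacity, in (0, 1].
#' @slot evapRate bare-soil evaporation (g/day), >= 0.
#' @slot transpCoeff transpiration per unit projected area (g/pixel/day), >= 0.
#' @slot weighInterval days between weighings, > 0.
#' @slot dryFloorFraction lower bound on pot weight as a fraction of field
#'   capacity; losses that would undershoot it are truncated and flagged.
#' @export
setClass("WaterParams",
  representation(
    fcWeight = "numeric", targetFraction = "numeric", evapRate = "numeric",
    transpCoeff = "numeric", weighInterval = "numeric",
    dryFloorFraction = "numeric"
  )
)

setValidity("WaterParams", function(object) {
  msg <- character()
  if (object@fcWeight <= 0) msg <- c(msg, "fcWeight must be > 0")
  tf <- object@targetFraction
  if (!(tf > 0 && tf <= 1)) msg <- c(msg, "targetFraction must lie in (0, 1]")
  if (object@evapRate < 0) msg <- c(msg, "evapRate must be >= 0")
  if (object@transpCoeff < 0) msg <- c(msg, "transpCoeff must be >= 0")
  if (object@weighInterval <= 0) msg <- c(msg, "weighInterval must be > 0")
  ff <- object@dryFloorFraction
  if (!(ff >= 0 && ff < 1)) msg <- c(msg, "dryFloorFraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct water-budget parameters
#'
#' @param fcWeight pot weight at field capacity (g).
#' @param targetFraction irrigation restore fraction of field capacity.
#' @param evapRate bare-soil evaporation (g/day).
#' @param transpCoeff transpiration per unit projected area (g/pixel/day).
#' @param weighInterval days between weighings.
#' @param dryFloorFraction dry-soil floor as a fraction of field capacity.
#' @return A [WaterParams-class] object.
#' @export
WaterParams <- function(fcWeight, targetFraction = 1, evapRate = 0,
                        transpCoeff = 0, weighInterval = 2,
                        dryFloorFraction = 0.4) {
  new("WaterParams",
    fcWeight = as.numeric(fcWeight),
    targetFraction = as.numeric(targetFraction),
    evapRate = as.numeric(evapRate),
    transpCoeff = as.numeric(transpCoeff),
    weighInterval = as.numeric(weighInterval),
    dryFloorFraction = as.numeric(dryFloorFraction)
  )
}

#' Factorial design of a pot phenotyping experiment
#'
#' @slot genotypes genotype (or treatment-arm) labels.
#' @slot treatments watering-treatment labels; the first is taken as control.
#' @slot replicates replicates per genotype-by-treatment cell, >= 1.
#' @slot timepoints strictly increasing imaging/weighing day indices.
#' @slot nBarePots number of plant-free evaporation control pots.
#' @slot label preset name or "custom".
#' @export
setClass("ExperimentDesign",
  representation(
    genotypes = "character", treatments = "character",
    replicates = "integer", timepoints = "numeric",
    nBarePots = "integer", label = "character"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (!length(object@genotypes) || anyDuplicated(object@genotypes))
    msg <- c(msg, "genotypes must be non-empty and unique")
  if (!length(object@treatments) || anyDuplicated(object@treatments))
    msg <- c(msg, "treatments must be non-empty and unique")
  if (length(object@replicates) != 1 || object@replicates < 1)
    msg <- c(msg, "replicates must be a single integer >= 1")
  tp <- object@timepoints
  if (length(tp) < 1 || any(diff(tp) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (object@nBarePots < 0) msg <- c(msg, "nBarePots must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an experiment design
#'
#' @param genotypes character vector of genotype or arm labels.
#' @param treatments character vector of treatment labels (first = control).
#' @param replicates replicates per cell.
#' @param timepoints strictly increasing day indices.
#' @param nBarePots number of bare-soil evaporation pots.
#' @param label free-text design label.
#' @return An [ExperimentDesign-class] object.
#' @export
ExperimentDesign <- function(genotypes, treatments, replicates, timepoints,
                             nBarePots = 0L, label = "custom") {
  new("ExperimentDesign",
    genotypes = as.character(genotypes),
    treatments = as.character(treatments),
    replicates = as.integer(replicates),
    timepoints = as.numeric(timepoints),
    nBarePots = as.integer(nBarePots),
    label = as.character(label)
  )
}

#' Digital Biovolume configuration
#'
#' The Digital Biovolume of one plant at one time point is
#' \eqn{DB = \Sigma_{side0} + \Sigma_{side90} + \log(\Sigma_{top} / d)}
#' where the sums are foreground pixel counts of the two side views and the
#' top view and \eqn{d} is `topDivisor`. The log term is orders of magnitude
#' smaller than the side sums for any grown plant, so the choice of log base
#' and divisor has negligible numerical effect; both are configurable.
#'
#' @slot logBase base of the logarithm (e or 10).
#' @slot topDivisor divisor applied to the top-view sum inside the log, > 0.
#' @slot zeroTopPolicy one of "omit_term" (drop the log term when the top
#'   count is zero, e.g. pre-emergence) or "error".
#' @export
setClass("DBConfig",
  representation(logBase = "numeric", topDivisor = "numeric",
                 zeroTopPolicy = "character")
)

setValidity("DBConfig", function(object) {
  msg <- character()
  if (object@topDivisor <= 0) msg <- c(msg, "topDivisor must be > 0")
  if (!object@zeroTopPolicy %in% c("omit_term", "error"))
    msg <- c(msg, "zeroTopPolicy must be 'omit_term' or 'error'")
  if (!object@logBase %in% c(exp(1), 10))
    msg <- c(msg, "logBase must be natural (exp(1)) or 10")
  if (length(msg)) msg else TRUE
})

#' Construct a Digital Biovolume configuration
#'
#' @param logBase "natural" or "10".
#' @param topDivisor divisor of the top-view sum inside the log (default 3).
#' @param zeroTopPolicy "omit_term" or "error" for a zero top-view count.
#' @return A [DBConfig-class] object.
#' @export
DBConfig <- function(logBase = c("natural", "10"), topDivisor = 3,
                     zeroTopPolicy = c("omit_term", "error")) {
  logBase <- match.arg(logBase)
  new("DBConfig",
    logBase = if (logBase == "natural") exp(1) else 10,
    topDivisor = as.numeric(topDivisor),
    zeroTopPolicy = match.arg(zeroTopPolicy)
  )
}

#' Result of segmenting one RGB view
#'
#' @slot mask logical H x W matrix, `TRUE` = plant foreground.
#' @slot pixelCount number of foreground pixels (equals `sum(mask)`).
#' @slot thresholdUsed excess-green threshold applied.
#' @slot nComponentsKept connected components retained after size filtering.
#' @export
setClass("SegmentationResult",
  representation(mask = "matrix", pixelCount = "integer",
                 thresholdUsed = "numeric", nComponentsKept = "integer")
)

setValidity("SegmentationResult", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@pixelCount != sum(object@mask))
    msg <- c(msg, "pixelCount must equal sum(mask)")
  if (object@pixelCount < 0) msg <- c(msg, "pixelCount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A complete (synthetic or loaded) phenotyping experiment
#'
#' Container binding the design, per-plant ground truth, observed pixel
#' counts, pot-weight logs and (optionally) a directory of rendered images.
#' Produced by [generateExperiment()] and consumed by the trait, water-budget
#' and statistics layers.
#'
#' @slot design the [ExperimentDesign-class].
#' @slot growth data.frame of per-genotype growth parameters.
#' @slot plants data.frame: plant_id, pot_id, genotype, treatment, replicate.
#' @slot truth data.frame: plant_id, day, true_area, fresh_weight_g.
#' @slot counts data.frame: plant_id, day, s0, s90, top.
#' @slot weights data.frame: pot_id, day, weight_pre_g, weight_post_g,
#'   is_bare, fc_weight, evap_true_g, transp_true_g, truncated.
#' @slot imageDir directory holding rendered images, or "" if none.
#' @slot seed integer seed the bundle was generated from.
#' @export
setClass("PhenoExperiment",
  representation(
    design = "ExperimentDesign", growth = "data.frame",
    plants = "data.frame", truth = "data.frame", counts = "data.frame",
    weights = "data.frame", imageDir = "character", seed = "integer"
  )
)

setValidity("PhenoExperiment", function(object) {
  msg <- character()
  cnt <- object@counts
  if (nrow(cnt)) {
    key <- paste(cnt$plant_id, cnt$day)
    if (anyDuplicated(key))
      msg <- c(msg, "counts must hold one record per (plant, day)")
  }
  tr <- object@truth
  if (nrow(tr) && nrow(cnt)) {
    if (!setequal(paste(tr$plant_id, tr$day), paste(cnt$plant_id, cnt$day)))
      msg <- c(msg, "truth and counts must share identical (plant, day) keys")
  }
  if (nrow(object@plants) &&
      !all(cnt$plant_id %in% object@plants$plant_id))
    msg <- c(msg, "counts reference unknown plant ids")
  if (length(msg)) msg else TRUE
})
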