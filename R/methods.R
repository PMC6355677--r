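#' @describeIn ExperimentDesign number of plants implied by the design
#' @param x,object an object of the documented class.
#' @export
setMethod("length", "ExperimentDesign", function(x) {
  length(x@genotypes) * length(x@treatments) * x@replicates
})

setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign <", object@label, ">\n", sep = "")
  cat("  ", length(object@genotypes), " genotypes/arms x ",
      length(object@treatments), " treatments x ",
      object@replicates, " replicates (", length(object), " plants)\n",
      sep = "")
  tp <- object@timepoints
  cat("  ", length(tp), " timepoints, days ", tp[1], "-", tp[length(tp)],
      "; ", object@nBarePots, " bare pots\n", sep = "")
})

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(
    "GrowthParams: K=%g px, r=%g /day, tMid=%g, factor=%g from day %g, cv=%g\n",
    object@K, object@r, object@tMid, object@treatmentFactor,
    object@stressStartDay, object@cvNoise))
})

setMethod("show", "WaterParams", function(object) {
  cat(sprintf(
    "WaterParams: FC=%g g, target=%g FC, evap=%g g/day, transp=%g g/px/day, weigh every %g d\n",
    object@fcWeight, object@targetFraction, object@evapRate,
    object@transpCoeff, object@weighInterval))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d foreground px in %dx%d mask (threshold %.2f, %d components)\n",
    object@pixelCount, nrow(object@mask), ncol(object@mask),
    object@thresholdUsed, object@nComponentsKept))
})

setMethod("show", "PhenoExperiment", function(object) {
  cat("PhenoExperiment (seed ", object@seed, ")\n", sep = "")
  show(object@design)
  cat("  counts: ", nrow(object@counts), " rows; weights: ",
      nrow(object@weights), " rows (",
      length(unique(object@weights$pot_id)), " pots)\n", sep = "")
  if (nzchar(object@imageDir))
    cat("  images: ", object@imageDir, "\n", sep = "")
})

#' Accessors for PhenoExperiment components
#'
#' @param x a [PhenoExperiment-class].
#' @return The requested component: the design object or a data.frame.
#' @name pheno-accessors
NULL

#' @rdname pheno-accessors
#' @export
expDesign <- function(x) x@design

#' @rdname pheno-accessors
#' @export
plantTable <- function(x) x@plants

#' @rdname pheno-accessors
#' @export
truthTable <- function(x) x@truth

#' @rdname pheno-accessors
#' @export
countTable <- function(x) x@counts

#' @rdname pheno-accessors
#' @export
weightTable <- function(x) x@weights

#' @rdname pheno-accessors
#' @export
imageDir <- function(x) x@imageDir
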