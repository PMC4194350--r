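#' @name accessors
#' @title Accessors for excretaScan objects
#' @description Slot accessors for [PlateAnalysis-class] and
#'   [ExperimentStore-class] objects.
#' @param object a `PlateAnalysis` or `ExperimentStore`.
#' @return `deposits()` the deposit table; `plateSummary()` /
#'   `plateSummaries()` the summary table(s); `detectionParams()` is the
#'   parameter constructor but also dispatches as an accessor on analysed
#'   plates via `params()`; `pixelSets()` the per-deposit pixel
#'   memberships; `plateId()` and `nFlies()` scalars; `auditTrail()` the
#'   audit table; `experimentPath()` the store directory.
NULL

#' @rdname accessors
#' @export
setGeneric("deposits", function(object) standardGeneric("deposits"))

#' @rdname accessors
#' @export
setGeneric("pixelSets", function(object) standardGeneric("pixelSets"))

#' @rdname accessors
#' @export
setGeneric("plateSummary", function(object) standardGeneric("plateSummary"))

#' @rdname accessors
#' @export
setGeneric("plateSummaries", function(object) standardGeneric("plateSummaries"))

#' @rdname accessors
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @rdname accessors
#' @export
setGeneric("nFlies", function(object) standardGeneric("nFlies"))

#' @rdname accessors
#' @export
setGeneric("params", function(object) standardGeneric("params"))

#' @rdname accessors
#' @export
setGeneric("auditTrail", function(object) standardGeneric("auditTrail"))

#' @rdname accessors
#' @export
setGeneric("experimentPath", function(object) standardGeneric("experimentPath"))

#' @rdname accessors
setMethod("deposits", "PlateAnalysis", function(object) object@deposits)

#' @rdname accessors
setMethod("pixelSets", "PlateAnalysis", function(object) object@pixelSets)

#' @rdname accessors
setMethod("plateSummary", "PlateAnalysis", function(object) object@summary)

#' @rdname accessors
setMethod("plateId", "PlateAnalysis", function(object) object@plateId)

#' @rdname accessors
setMethod("nFlies", "PlateAnalysis", function(object) object@nFlies)

#' @rdname accessors
setMethod("params", "PlateAnalysis", function(object) object@params)

#' @rdname accessors
setMethod("deposits", "ExperimentStore", function(object) object@deposits)

#' @rdname accessors
setMethod("plateSummaries", "ExperimentStore", function(object) object@summaries)

#' @rdname accessors
setMethod("auditTrail", "ExperimentStore", function(object) object@audit)

#' @rdname accessors
setMethod("experimentPath", "ExperimentStore", function(object) object@path)

setMethod("show", "DetectionParams", function(object) {
  cat("DetectionParams @", object@dpi, "dpi\n")
  cat(sprintf("  local-mean window %d px, offset %.3f, %d-connectivity%s\n",
              object@window, object@offset, object@connectivity,
              if (object@opening) ", opening on" else ""))
  cat(sprintf("  size filter [%g, %g] px, greyscale weights (%.3f, %.3f, %.3f)\n",
              object@minArea, object@maxArea,
              object@weights[1], object@weights[2], object@weights[3]))
  cat(sprintf("  ROD circularity cutoff %.2f\n", object@rodCutoff))
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf("SynthSpec %dx%d px, seed %d\n", object@width, object@height,
              object@seed))
  cat(sprintf("  %d round (r %g-%g px) + %d oblong (w %g-%g px, aspect %g-%g)\n",
              object@nRound, object@roundRadius[1], object@roundRadius[2],
              object@nOblong, object@oblongWidth[1], object@oblongWidth[2],
              object@oblongAspect[1], object@oblongAspect[2]))
  cat(sprintf("  background %.2f +/- %.2f, %d artefact specks, overlap %s\n",
              object@background, object@gradientAmplitude, object@nArtefacts,
              object@overlap))
})

setMethod("show", "PlateAnalysis", function(object) {
  d <- object@deposits
  cat(sprintf("PlateAnalysis '%s' (%dx%d px, %d flies)\n", object@plateId,
              object@dim[1], object@dim[2], object@nFlies))
  cat(sprintf("  %d deposits (%d ROD, %d excluded), processed %s\n",
              nrow(d), sum(d$is_rod), sum(!d$include), object@timestamp))
})

setMethod("show", "ExperimentStore", function(object) {
  cat(sprintf("ExperimentStore '%s' at %s\n", object@experimentId, object@path))
  ok <- sum(object@plates$status == "ok")
  cat(sprintf("  %d plates (%d processed, %d failed), %d audit entries\n",
              nrow(object@plates), ok, nrow(object@plates) - ok,
              nrow(object@audit)))
})
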