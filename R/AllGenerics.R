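#' @rdname accessors
#' @export
setGeneric("stayProb", function(x) standardGeneric("stayProb"))

#' @rdname accessors
#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))

#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname accessors
#' @export
setGeneric("boundaryPixels", function(x) standardGeneric("boundaryPixels"))

#' @rdname accessors
#' @export
setGeneric("boundarySeeds", function(x) standardGeneric("boundarySeeds"))

#' @rdname accessors
#' @export
setGeneric("lesionMatrix", function(x) standardGeneric("lesionMatrix"))

#' @rdname accessors
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))

#' @rdname accessors
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' Accessors for WMIdetect objects
#'
#' Read-only access to the slots of the package's S4 containers.
#' \code{stayProb} and \code{decayRate} return the transition model's
#' \eqn{q} and \eqn{\alpha}; \code{transitionProbs} its drop-size probability
#' vector; \code{nStates} the number of intensity states of a model, state
#' space or state image. \code{stateMatrix} returns the integer state matrix
#' (sentinel -1 outside the mask). \code{boundaryPixels}/\code{boundarySeeds}
#' return (row, col) coordinate matrices. \code{lesionMatrix},
#' \code{lesionLabels} and \code{componentTable} expose a detection's binary
#' mask, its 8-connected labels and the per-component summary.
#'
#' @param x an object of the matching class.
#' @return the slot value; see Details.
#' @name accessors
#' @aliases stayProb decayRate nStates transitionProbs stateMatrix
#'   boundaryPixels boundarySeeds lesionMatrix lesionLabels componentTable
NULL

#' @rdname accessors
setMethod("stayProb", "TransitionModel", function(x) x@q)
#' @rdname accessors
setMethod("decayRate", "TransitionModel", function(x) x@alpha)
#' @rdname accessors
setMethod("nStates", "TransitionModel", function(x) x@n + 1L)
#' @rdname accessors
setMethod("nStates", "StateSpace", function(x) x@nStates)
#' @rdname accessors
setMethod("nStates", "StateImage", function(x) x@space@nStates)
#' @rdname accessors
setMethod("transitionProbs", "TransitionModel", function(x) x@probs)
#' @rdname accessors
setMethod("stateMatrix", "StateImage", function(x) x@states)
#' @rdname accessors
setMethod("boundaryPixels", "BoundarySet", function(x) x@pixels)
#' @rdname accessors
setMethod("boundarySeeds", "BoundarySet", function(x) x@seeds)
#' @rdname accessors
setMethod("lesionMatrix", "LesionMask", function(x) x@mask)
#' @rdname accessors
setMethod("lesionLabels", "LesionMask", function(x) x@labels)
#' @rdname accessors
setMethod("componentTable", "LesionMask", function(x) x@perComponent)

setMethod("show", "TransitionModel", function(object) {
  cat("TransitionModel: q =", format(object@q, digits = 6),
      ", alpha =", format(object@alpha, digits = 6),
      ", N =", object@n, "\n")
  cat("  drop-size probabilities:",
      paste(format(object@probs, digits = 3), collapse = " "), "\n")
})

setMethod("show", "StateSpace", function(object) {
  cat("StateSpace with", object@nStates, "states over [0, 1]\n")
})

setMethod("show", "StateImage", function(object) {
  inm <- sum(object@states >= 0L)
  cat("StateImage:", paste(dim(object@states), collapse = " x "),
      "px,", inm, "in mask,", object@space@nStates, "states\n")
  cat("  stretch range:",
      paste(format(object@sourceStats, digits = 4), collapse = " .. "), "\n")
})

setMethod("show", "BoundarySet", function(object) {
  cat("BoundarySet:", nrow(object@pixels), "boundary pixels,",
      nrow(object@seeds), "seeds\n")
})

setMethod("show", "LesionMask", function(object) {
  cat("LesionMask:", sum(object@mask), "px in",
      nrow(object@perComponent), "component(s)\n")
  if (nrow(object@perComponent)) {
    print(utils::head(object@perComponent, 10L))
  }
})

setMethod("show", "DetectionConfig", function(object) {
  cat("DetectionConfig: threshold =", object@threshold,
      "| marginPx =", object@marginPx,
      "| minBoundaryPx =", object@minBoundaryPx,
      "| growthFraction =", object@growthFraction,
      "| maxRegionPx =",
      if (is.na(object@maxRegionPx)) "10% of mask" else object@maxRegionPx,
      "\n")
})

setMethod("show", "BlandAltmanSummary", function(object) {
  cat("Bland-Altman agreement over", nrow(object@perCase), "cases\n")
  cat("  bias (reference - automatic):", format(object@bias, digits = 4),
      "cm^2\n")
  cat("  limits of agreement:", format(object@loaLow, digits = 4), "to",
      format(object@loaHigh, digits = 4), "cm^2\n")
})
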