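#' @import methods
NULL

#' StateSpace: intensity intervals of the stochastic model
#'
#' The white-matter intensity range, after stretching to \eqn{[0, 1]}, is
#' divided into \eqn{N + 1} equal-width intervals; these are the states
#' \eqn{s_0, \dots, s_N} of the transition model. Intervals are half-open
#' \eqn{[a, b)} with the final interval closed, so every normalized intensity
#' maps to exactly one state.
#'
#' @slot nStates integer, number of states (\eqn{N + 1}), at least 2.
#' @slot edges numeric vector of length \code{nStates + 1}, strictly
#'   increasing interval boundaries from 0 to 1.
#'
#' @seealso [stateSpace()], [stretchAndQuantize()]
#' @export
setClass("StateSpace",
  representation(nStates = "integer", edges = "numeric"))

setValidity("StateSpace", function(object) {
  msg <- character()
  if (length(object@nStates) != 1L || is.na(object@nStates) ||
      object@nStates < 2L)
    msg <- c(msg, "nStates must be a single integer >= 2")
  e <- object@edges
  if (length(e) != object@nStates + 1L)
    msg <- c(msg, "edges must have length nStates + 1")
  else {
    if (any(diff(e) <= 0)) msg <- c(msg, "edges must be strictly increasing")
    if (abs(e[1L]) > 1e-12 || abs(e[length(e)] - 1) > 1e-12)
      msg <- c(msg, "edges must span [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' TransitionModel: geometric law for adjacent-pixel state drops
#'
#' Conditional on the current pixel being the brighter member of an adjacent
#' pair, the probability that its neighbour sits \eqn{k} states lower is
#' \eqn{q \alpha^k}, for \eqn{k = 0, \dots, N}. Normalization over the
#' \eqn{N + 1} possible drops forces \eqn{\alpha} to be the unique root in
#' \eqn{(0, 1)} of \eqn{q\alpha^{N+1} - \alpha + (1 - q) = 0}.
#'
#' @slot q numeric, probability that two adjacent in-mask pixels share a
#'   state; in \eqn{(0, 1)}.
#' @slot alpha numeric, geometric decay rate in \eqn{(0, 1)}.
#' @slot n integer, highest state index \eqn{N}.
#' @slot probs numeric vector of length \eqn{N + 1}; \code{probs[k + 1]} is
#'   the probability of a drop of exactly \eqn{k} states. Sums to 1.
#'
#' @seealso [transitionModel()], [solveAlpha()], [transitionProbabilities()]
#' @export
setClass("TransitionModel",
  representation(q = "numeric", alpha = "numeric", n = "integer",
                 probs = "numeric"))

setValidity("TransitionModel", function(object) {
  msg <- character()
  if (object@q <= 0 || object@q >= 1) msg <- c(msg, "q must be in (0, 1)")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(object@probs) != object@n + 1L)
    msg <- c(msg, "probs must have length n + 1")
  else if (abs(sum(object@probs) - 1) > 1e-9)
    msg <- c(msg, "probs must sum to 1 (within 1e-9)")
  resid <- object@q * object@alpha^(object@n + 1L) - object@alpha +
    (1 - object@q)
  if (abs(resid) > 1e-9)
    msg <- c(msg, "alpha does not satisfy the normalization polynomial")
  if (length(msg)) msg else TRUE
})

#' StateImage: per-pixel quantized states over a white-matter mask
#'
#' @slot states integer matrix; state index in \code{0:N} inside the
#'   white-matter mask, sentinel \code{-1L} outside.
#' @slot space the [StateSpace-class] used for binning.
#' @slot sourceStats numeric length-2, the (low, high) clip intensities used
#'   for histogram stretching, on the raw intensity scale.
#'
#' @seealso [stretchAndQuantize()]
#' @export
setClass("StateImage",
  representation(states = "matrix", space = "StateSpace",
                 sourceStats = "numeric"))

setValidity("StateImage", function(object) {
  s <- object@states
  msg <- character()
  if (!is.integer(s)) msg <- c(msg, "states must be an integer matrix")
  inm <- s[s >= 0L]
  if (length(inm) && max(inm) > object@space@nStates - 1L)
    msg <- c(msg, "in-mask states exceed the state space")
  if (any(s < -1L)) msg <- c(msg, "states below the -1 sentinel")
  if (length(object@sourceStats) != 2L)
    msg <- c(msg, "sourceStats must be length 2")
  if (length(msg)) msg else TRUE
})

#' BoundarySet: pixels flagged as rare-transition injury boundaries
#'
#' Both members of every rare (low-probability) adjacent transition are
#' boundary pixels; the strictly brighter member of at least one rare pair is
#' additionally a seed for region growing.
#'
#' @slot pixels integer matrix with columns \code{row}, \code{col}; 0 rows
#'   allowed.
#' @slot seeds integer matrix, subset of \code{pixels}, same columns.
#' @slot dim integer length-2, dimensions of the originating image.
#'
#' @seealso [markBoundaries()], [removeMarginFalseBoundaries()]
#' @export
setClass("BoundarySet",
  representation(pixels = "matrix", seeds = "matrix", dim = "integer"))

setValidity("BoundarySet", function(object) {
  msg <- character()
  if (ncol(object@pixels) != 2L || ncol(object@seeds) != 2L)
    msg <- c(msg, "pixels and seeds must be two-column (row, col) matrices")
  if (nrow(object@seeds)) {
    keyP <- paste(object@pixels[, 1L], object@pixels[, 2L])
    keyS <- paste(object@seeds[, 1L], object@seeds[, 2L])
    if (!all(keyS %in% keyP)) msg <- c(msg, "seeds must be a subset of pixels")
  }
  if (length(object@dim) != 2L) msg <- c(msg, "dim must be length 2")
  if (length(msg)) msg else TRUE
})

#' LesionMask: grown injury regions with connected-component labels
#'
#' @slot mask logical matrix of detected injury pixels.
#' @slot labels integer matrix, 8-connected component labels (0 = background).
#' @slot perComponent data.frame with one row per component: \code{label},
#'   \code{areaPx}, \code{centroidRow}, \code{centroidCol}.
#'
#' @seealso [growRegions()], [detectWMI()]
#' @export
setClass("LesionMask",
  representation(mask = "matrix", labels = "matrix",
                 perComponent = "data.frame"))

setValidity("LesionMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!identical(dim(object@mask), dim(object@labels)))
    msg <- c(msg, "mask and labels must share dimensions")
  if (any((object@labels > 0L) != object@mask))
    msg <- c(msg, "labels must cover exactly the mask pixels")
  if (nrow(object@perComponent) &&
      sum(object@perComponent$areaPx) != sum(object@mask))
    msg <- c(msg, "component areas must sum to the mask area")
  if (length(msg)) msg else TRUE
})

#' DetectionConfig: tunable parameters of the detector
#'
#' @slot threshold numeric, transition-probability cutoff below which an
#'   adjacent-pixel transition is called rare (default 0.01).
#' @slot marginPx numeric, width in pixels of the exclusion band at the
#'   white-matter mask border (default 2).
#' @slot minBoundaryPx integer, minimum size of an 8-connected boundary
#'   component (default 3).
#' @slot growthFraction numeric, region-growing acceptance fraction: a
#'   candidate joins when its intensity deviates from the region mean by less
#'   than this fraction of the region standard deviation (default 0.5).
#' @slot maxRegionPx numeric, safety cap on a grown region's size;
#'   \code{NA} means 10\% of the white-matter mask area, resolved at run time.
#'
#' @seealso [detectionConfig()], [detectWMI()]
#' @export
setClass("DetectionConfig",
  representation(threshold = "numeric", marginPx = "numeric",
                 minBoundaryPx = "integer", growthFraction = "numeric",
                 maxRegionPx = "numeric"))

setValidity("DetectionConfig", function(object) {
  msg <- character()
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must be in (0, 1)")
  if (object@marginPx < 0) msg <- c(msg, "marginPx must be >= 0")
  if (object@minBoundaryPx < 1L) msg <- c(msg, "minBoundaryPx must be >= 1")
  if (object@growthFraction < 0)
    msg <- c(msg, "growthFraction must be >= 0")
  if (!is.na(object@maxRegionPx) && object@maxRegionPx < 1)
    msg <- c(msg, "maxRegionPx must be >= 1 (or NA for 10% of the mask)")
  if (length(msg)) msg else TRUE
})

#' BlandAltmanSummary: agreement between automatic and reference lesion areas
#'
#' Per-case differences use the fixed sign convention
#' \code{diff = ground truth - automatic}, so a method that under-segments
#' relative to the reference shows a positive bias.
#'
#' @slot perCase data.frame with columns \code{meanArea} (cm^2, average of
#'   the two measurements) and \code{diffArea} (cm^2, reference minus
#'   automatic).
#' @slot bias numeric, mean of the differences.
#' @slot loaLow,loaHigh numeric, limits of agreement, bias -/+ 1.96 times
#'   the sample standard deviation of the differences.
#'
#' @seealso [blandAltman()], [binnedDifferenceTable()]
#' @export
setClass("BlandAltmanSummary",
  representation(perCase = "data.frame", bias = "numeric",
                 loaLow = "numeric", loaHigh = "numeric"))

setValidity("BlandAltmanSummary", function(object) {
  msg <- character()
  if (!all(c("meanArea", "diffArea") %in% names(object@perCase)))
    msg <- c(msg, "perCase needs meanArea and diffArea columns")
  if (object@loaLow > object@bias || object@bias > object@loaHigh)
    msg <- c(msg, "limits of agreement must bracket the bias")
  if (length(msg)) msg else TRUE
})
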