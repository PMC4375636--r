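#' Accuracy-distance histogram of a detection against ground truth
#'
#' For every detected lesion pixel, the Euclidean distance (in pixels) to the
#' nearest ground-truth lesion pixel is computed via the distance transform
#' of the truth mask and rounded half-up to an integer. Distance 0 means the
#' pixel lies inside the ground truth; a well-behaved detection concentrates
#' its mass at 0 with a short tail at 1-2 px, while margin false positives
#' show up as a secondary mode at larger distances.
#'
#' @param detected a [LesionMask-class] or logical matrix.
#' @param truth logical matrix of expert-delineated lesion pixels, same
#'   geometry.
#' @return data.frame with integer column \code{distance} and column
#'   \code{count}; rows sorted by distance. When the truth mask is empty but
#'   pixels were detected, a single distinguished row with
#'   \code{distance = Inf} (the "no-truth" bucket) carries all the mass.
#'   Counts always sum to the number of detected pixels.
#' @export
accuracyDistanceHistogram <- function(detected, truth) {
  dm <- if (is(detected, "LesionMask")) detected@mask else detected > 0
  truth <- truth > 0
  stopifnot(identical(dim(dm), dim(truth)))
  nDet <- sum(dm)
  if (!nDet)
    return(data.frame(distance = numeric(), count = integer()))
  if (!any(truth))
    return(data.frame(distance = Inf, count = nDet))
  # foreground = non-truth pixels: distmap gives their distance to the
  # nearest truth pixel; truth pixels themselves map to 0
  d <- distanceToBackground(!truth, pad = FALSE)
  dist <- floor(d[dm] + 0.5)  # round half-up to match integer bar bins
  tab <- table(dist)
  data.frame(distance = as.numeric(names(tab)), count = as.integer(tab))
}

#' Bland-Altman agreement of automatic vs reference lesion areas
#'
#' Classic limits-of-agreement analysis of two area measurements per case.
#' The per-case abscissa is the mean \eqn{(A_{auto} + A_{ref})/2} and the
#' ordinate the difference with the fixed sign convention
#' \eqn{A_{ref} - A_{auto}}: automatic under-segmentation relative to the
#' expert reference therefore appears as a positive bias. The limits are
#' bias \eqn{\pm 1.96} sample standard deviations of the differences.
#'
#' @param areasAuto numeric vector of automatically measured areas (cm^2).
#' @param areasGt numeric vector of reference (ground-truth) areas (cm^2),
#'   same length; at least 2 cases are needed for the limits.
#' @return a [BlandAltmanSummary-class].
#' @examples
#' blandAltman(c(1.0, 2.0), c(1.2, 2.6))  # bias 0.4
#' @export
blandAltman <- function(areasAuto, areasGt) {
  if (length(areasAuto) != length(areasGt))
    stop("areasAuto and areasGt must have equal length")
  if (!length(areasAuto)) stop("no cases supplied")
  if (length(areasAuto) < 2L)
    stop("need >= 2 cases for limits of agreement")
  diffs <- areasGt - areasAuto
  means <- (areasGt + areasAuto) / 2
  bias <- mean(diffs)
  s <- stats::sd(diffs)  # sample sd, ddof = 1
  new("BlandAltmanSummary",
      perCase = data.frame(meanArea = means, diffArea = diffs),
      bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s)
}

#' Binned area-difference table
#'
#' Buckets the per-case Bland-Altman points by their mean-area axis into
#' intervals \eqn{[k w, (k+1) w)} and reports the average difference and the
#' number of observations per occupied bin, mirroring the tabular summary of
#' agreement by lesion size. Empty bins are omitted.
#'
#' @param summary a [BlandAltmanSummary-class].
#' @param binWidth bin width \eqn{w} on the mean-area axis, cm^2 (default
#'   0.1).
#' @return data.frame with columns \code{binLow}, \code{binHigh},
#'   \code{meanDiff}, \code{count}, ordered by bin.
#' @export
binnedDifferenceTable <- function(summary, binWidth = 0.1) {
  stopifnot(is(summary, "BlandAltmanSummary"))
  if (!(binWidth > 0)) stop("binWidth must be positive")
  pc <- summary@perCase
  k <- floor(pc$meanArea / binWidth)
  md <- tapply(pc$diffArea, k, mean)
  cnt <- tapply(pc$diffArea, k, length)
  kk <- as.numeric(names(md))
  out <- data.frame(binLow = kk * binWidth, binHigh = (kk + 1) * binWidth,
                    meanDiff = as.numeric(md), count = as.integer(cnt))
  out[order(out$binLow), , drop = FALSE]
}

#' Physical area of a binary mask
#'
#' @param mask a [LesionMask-class] or logical matrix.
#' @param pixelSpacing length-2 numeric, (row mm, col mm) per pixel; taken
#'   from the image header for NIfTI input, and must be supplied for raster
#'   formats.
#' @return area in cm^2: pixel count x row_mm x col_mm / 100.
#' @examples
#' areaCm2(matrix(TRUE, 10, 10), c(1, 1))  # 1 cm^2
#' @export
areaCm2 <- function(mask, pixelSpacing) {
  if (missing(pixelSpacing) || is.null(pixelSpacing) ||
      any(is.na(pixelSpacing)))
    stop("pixelSpacing (row mm, col mm) is required to convert pixel ",
         "counts to cm^2; supply it explicitly for PNG/TIFF input")
  if (length(pixelSpacing) != 2L || any(pixelSpacing <= 0))
    stop("pixelSpacing must be two positive numbers (mm)")
  m <- if (is(mask, "LesionMask")) mask@mask else mask > 0
  sum(m) * pixelSpacing[1L] * pixelSpacing[2L] / 100
}
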