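#' Construct a StateSpace
#'
#' Equal-width intervals over the stretched intensity range \eqn{[0, 1]}.
#'
#' @param nStates number of states \eqn{N + 1}, at least 2.
#' @return a [StateSpace-class].
#' @export
stateSpace <- function(nStates) {
  nStates <- as.integer(nStates)
  new("StateSpace", nStates = nStates,
      edges = seq(0, 1, length.out = nStates + 1L))
}

#' Percentile histogram stretch of the white-matter intensities
#'
#' In-mask intensities are clipped to the given percentile range (computed
#' over in-mask pixels only) and linearly rescaled to \eqn{[0, 1]}. The
#' percentile clip absorbs affine intensity changes between scans and is
#' robust to hot pixels. Out-of-mask pixels become \code{NA}.
#'
#' @param image 2D numeric matrix of raw intensities.
#' @param mask logical matrix, the white-matter delineation.
#' @param clipPercentiles length-2 numeric, low/high percentiles in
#'   \eqn{[0, 100]} (default \code{c(1, 99)}).
#' @return list with \code{stretched} (numeric matrix, NA outside the mask)
#'   and \code{stats} (the low/high clip intensities on the raw scale).
#' @export
stretchIntensities <- function(image, mask, clipPercentiles = c(1, 99)) {
  stopifnot(is.matrix(image), is.matrix(mask),
            identical(dim(image), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty white-matter mask")
  cp <- clipPercentiles
  if (length(cp) != 2L || cp[1L] < 0 || cp[2L] > 100 || cp[1L] >= cp[2L])
    stop("clipPercentiles must satisfy 0 <= low < high <= 100")
  v <- image[mask]
  qs <- stats::quantile(v, cp / 100, names = FALSE, type = 7L)
  lo <- qs[1L]; hi <- qs[2L]
  out <- matrix(NA_real_, nrow(image), ncol(image))
  if (hi <= lo) {
    warning("zero dynamic range inside the mask; all states collapse to 0")
    out[mask] <- 0
  } else {
    out[mask] <- (pmin(pmax(image[mask], lo), hi) - lo) / (hi - lo)
  }
  list(stretched = out, stats = c(low = lo, high = hi))
}

#' Stretch and quantize a slice into intensity states
#'
#' The detector's first stage: percentile-stretch the white-matter histogram,
#' then bin the stretched intensities into \code{nStates} equal-width
#' intervals. Intervals are half-open \eqn{[a, b)} with the last interval
#' closed, so quantization is monotone in intensity and bit-reproducible.
#' Grouping small intensity ranges this way makes the transition statistics
#' robust across images with differing raw ranges.
#'
#' @inheritParams stretchIntensities
#' @param nStates number of states (default 7, i.e. \eqn{N = 6}).
#' @return a [StateImage-class]; sentinel -1 outside the mask.
#' @examples
#' img <- matrix(rep(seq(0, 1, length.out = 16), 16), 16, 16)
#' si <- stretchAndQuantize(img, matrix(TRUE, 16, 16), nStates = 4)
#' table(stateMatrix(si))
#' @export
stretchAndQuantize <- function(image, mask, nStates = 7L,
                               clipPercentiles = c(1, 99)) {
  nStates <- as.integer(nStates)
  if (nStates < 2L) stop("nStates must be >= 2")
  st <- stretchIntensities(image, mask, clipPercentiles)
  mask <- mask > 0
  states <- matrix(-1L, nrow(image), ncol(image))
  # floor() yields the half-open bins; pmin closes the final interval at 1
  states[mask] <- pmin(as.integer(floor(st$stretched[mask] * nStates)),
                       nStates - 1L)
  new("StateImage", states = states, space = stateSpace(nStates),
      sourceStats = as.numeric(st$stats))
}
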