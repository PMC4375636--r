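#' Detector configuration
#'
#' @param threshold transition-probability cutoff; adjacent pairs whose model
#'   probability falls below it are rare (default 0.01, the worked operating
#'   point; see [calibrateThreshold()] for a data-driven alternative).
#' @param marginPx width of the exclusion band at the white-matter border, in
#'   pixels (default 2). Boundary pixels closer than this to an out-of-mask
#'   pixel are treated as segmentation artefacts.
#' @param minBoundaryPx minimum surviving boundary component size (default 3).
#' @param growthFraction region-growing acceptance fraction (default 0.5):
#'   candidate intensity must lie within this fraction of the region's
#'   standard deviation from its mean. Exactly 0 disables growth entirely.
#' @param maxRegionPx cap on grown-region size; \code{NA} (default) resolves
#'   to 10\% of the white-matter mask area at run time.
#' @return a [DetectionConfig-class].
#' @export
detectionConfig <- function(threshold = 0.01, marginPx = 2,
                            minBoundaryPx = 3L, growthFraction = 0.5,
                            maxRegionPx = NA_real_) {
  new("DetectionConfig", threshold = threshold, marginPx = marginPx,
      minBoundaryPx = as.integer(minBoundaryPx),
      growthFraction = growthFraction,
      maxRegionPx = as.numeric(maxRegionPx))
}

#' Mark rare-transition boundary pixels
#'
#' Every unordered 8-connected in-mask pixel pair is evaluated once: the pair
#' is a rare transition iff the model probability of its state drop,
#' \eqn{q\alpha^{|s_a - s_b|}}, falls below the configured threshold. Both
#' members of a rare pair become boundary pixels; the strictly brighter one
#' (higher state) becomes a seed for region growing, since injury is
#' hyperintense on T1. The darker-to-brighter direction is the mirrored event
#' with identical probability, so the relation is symmetric in the pair.
#'
#' @param states a [StateImage-class].
#' @param model a [TransitionModel-class]; its \eqn{N} must match the state
#'   image's.
#' @param config a [DetectionConfig-class].
#' @return a [BoundarySet-class].
#' @export
markBoundaries <- function(states, model, config = detectionConfig()) {
  stopifnot(is(states, "StateImage"), is(model, "TransitionModel"),
            is(config, "DetectionConfig"))
  sm <- states@states
  if (model@n != states@space@nStates - 1L)
    stop("configuration error: model has N = ", model@n,
         " but the state image has ", states@space@nStates, " states")
  mask <- sm >= 0L
  if (!any(mask)) stop("empty white-matter mask")
  pairs <- adjacentPairs(mask)
  empty <- matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("row", "col")))
  if (!nrow(pairs))
    return(new("BoundarySet", pixels = empty, seeds = empty,
               dim = dim(sm)))
  s1 <- sm[pairs[, 1L]]; s2 <- sm[pairs[, 2L]]
  prob <- model@q * model@alpha^abs(s1 - s2)
  rare <- prob < config@threshold
  if (!any(rare))
    return(new("BoundarySet", pixels = empty, seeds = empty,
               dim = dim(sm)))
  p1 <- pairs[rare, 1L]; p2 <- pairs[rare, 2L]
  s1 <- s1[rare]; s2 <- s2[rare]
  pixIdx <- unique(c(p1, p2))
  seedIdx <- unique(c(p1[s1 > s2], p2[s2 > s1]))
  toRC <- function(i) {
    rc <- arrayInd(i, dim(sm))
    colnames(rc) <- c("row", "col")
    sortPixels(rc)
  }
  new("BoundarySet", pixels = toRC(pixIdx),
      seeds = if (length(seedIdx)) toRC(seedIdx) else empty,
      dim = dim(sm))
}

#' Remove false boundaries at the white-matter margin
#'
#' Two independently switchable filters, applied in order: (1) boundary
#' pixels whose Euclidean distance to the nearest out-of-mask pixel is at
#' most \code{marginPx} are dropped (gray-matter contamination at an
#' imperfect white-matter segmentation produces exactly such margin-hugging
#' boundaries); (2) surviving 8-connected boundary components smaller than
#' \code{minBoundaryPx} pixels are dropped. Seeds are filtered consistently:
#' a seed survives iff its pixel survives.
#'
#' @param boundaries a [BoundarySet-class].
#' @param mask logical white-matter mask the boundaries were computed on.
#' @param config a [DetectionConfig-class].
#' @return a filtered [BoundarySet-class]; possibly empty.
#' @export
removeMarginFalseBoundaries <- function(boundaries, mask,
                                        config = detectionConfig()) {
  stopifnot(is(boundaries, "BoundarySet"), is.matrix(mask))
  px <- boundaries@pixels
  if (!nrow(px)) return(boundaries)
  mask <- mask > 0
  keep <- rep(TRUE, nrow(px))
  if (config@marginPx > 0) {
    d <- distanceToBackground(mask)
    keep <- d[px] > config@marginPx
  }
  px <- px[keep, , drop = FALSE]
  if (nrow(px) && config@minBoundaryPx > 1L) {
    bm <- matrix(FALSE, nrow(mask), ncol(mask))
    bm[px] <- TRUE
    lab <- labelComponents(bm, 8L)
    sizes <- tabulate(lab[lab > 0L])
    px <- px[sizes[lab[px]] >= config@minBoundaryPx, , drop = FALSE]
  }
  sd0 <- boundaries@seeds
  if (nrow(sd0) && nrow(px)) {
    keyP <- paste(px[, 1L], px[, 2L])
    sd0 <- sd0[paste(sd0[, 1L], sd0[, 2L]) %in% keyP, , drop = FALSE]
  } else {
    sd0 <- sd0[integer(), , drop = FALSE]
  }
  new("BoundarySet", pixels = px, seeds = sd0, dim = boundaries@dim)
}

# 8-neighbour (row, col) offsets, row-major order
.neigh8 <- cbind(row = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                 col = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Grow injury regions from boundary seeds
#'
#' Seeded region growing over the stretched intensities. Seeds are processed
#' in row-major order (seeds already absorbed by an earlier region are
#' skipped). A region repeatedly sweeps its 8-connected in-mask frontier in
#' row-major order; a candidate joins when its intensity deviates from the
#' current region mean by less than \code{growthFraction} times the region's
#' sample standard deviation. Region statistics are updated after every
#' accepted pixel, and sweeps repeat until a full pass admits nothing or the
#' size cap is reached (a capped region is reported via the result's
#' \code{capped} attribute).
#'
#' While the region holds fewer than 4 pixels or its standard deviation is
#' below 1e-6 the statistical criterion is undefined; a candidate is then
#' accepted iff its quantized state equals the seed's state (the
#' zero-tolerance reading of the criterion). With \code{growthFraction = 0}
#' nothing is ever admitted and the result is the seeds alone.
#'
#' Regions that touch are merged; components are labelled with
#' 8-connectivity.
#'
#' @param image numeric matrix of stretched intensities (as produced by
#'   [stretchIntensities()]; NA outside the mask is fine).
#' @param states the [StateImage-class] for the same slice (drives the
#'   degenerate-statistics rule).
#' @param boundaries a [BoundarySet-class] whose seeds lie in the mask.
#' @param mask logical white-matter mask.
#' @param config a [DetectionConfig-class].
#' @return a [LesionMask-class] with attribute \code{capped} (TRUE if any
#'   region hit \code{maxRegionPx}).
#' @export
growRegions <- function(image, states, boundaries, mask,
                        config = detectionConfig()) {
  stopifnot(is.matrix(image), is(states, "StateImage"),
            is(boundaries, "BoundarySet"), is.matrix(mask))
  mask <- mask > 0
  sm <- states@states
  nr <- nrow(mask); nc <- ncol(mask)
  seeds <- sortPixels(boundaries@seeds)
  out <- matrix(FALSE, nr, nc)
  capped <- FALSE
  if (!nrow(seeds)) {
    lm <- newLesionMask(out)
    attr(lm, "capped") <- FALSE
    return(lm)
  }
  if (any(!mask[seeds])) stop("seeds outside the white-matter mask")
  maxPx <- if (is.na(config@maxRegionPx)) ceiling(0.1 * sum(mask))
           else config@maxRegionPx
  frac <- config@growthFraction
  for (si in seq_len(nrow(seeds))) {
    sr <- seeds[si, 1L]; sc <- seeds[si, 2L]
    if (out[sr, sc]) next  # absorbed by an earlier region
    region <- matrix(FALSE, nr, nc)
    region[sr, sc] <- TRUE
    seedState <- sm[sr, sc]
    s1 <- image[sr, sc]; s2 <- image[sr, sc]^2; sz <- 1L
    if (frac > 0) {
      repeat {
        # frontier: in-mask 8-neighbours of the region, not yet members
        front <- matrix(FALSE, nr, nc)
        ridx <- which(region)
        rc <- arrayInd(ridx, dim(region))
        for (k in seq_len(8L)) {
          r2 <- rc[, 1L] + .neigh8[k, 1L]
          c2 <- rc[, 2L] + .neigh8[k, 2L]
          ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
          front[cbind(r2[ok], c2[ok])] <- TRUE
        }
        cand <- which(front & mask & !region & !out)
        if (!length(cand)) break
        rcC <- arrayInd(cand, dim(region))
        cand <- cand[order(rcC[, 1L], rcC[, 2L])]
        changed <- FALSE
        for (p in cand) {
          mu <- s1 / sz
          sdv <- if (sz > 1L) sqrt(max((s2 - s1^2 / sz) / (sz - 1L), 0))
                 else 0
          acc <- if (sz < 4L || sdv < 1e-6) sm[p] == seedState
                 else abs(image[p] - mu) / sdv < frac
          if (isTRUE(acc)) {
            region[p] <- TRUE
            s1 <- s1 + image[p]; s2 <- s2 + image[p]^2; sz <- sz + 1L
            changed <- TRUE
            if (sz >= maxPx) { capped <- TRUE; break }
          }
        }
        if (!changed || sz >= maxPx) break
      }
    }
    out <- out | region
  }
  if (capped)
    warning("region growing hit the maxRegionPx cap (", maxPx, " px)")
  lm <- newLesionMask(out)
  attr(lm, "capped") <- capped
  lm
}

#' Detect white matter injury in a slice
#'
#' The full pipeline: percentile stretch and quantization, model fitting
#' (estimate \eqn{q} from the slice or use a fixed value, then solve for
#' \eqn{\alpha}), rare-transition boundary marking, margin/small-component
#' filtering, and seeded region growing.
#'
#' @param image 2D numeric matrix, the raw T1 slice.
#' @param mask logical matrix, the white-matter delineation (an input; this
#'   package does not segment white matter).
#' @param q either \code{"estimate"} (default: estimate from the quantized
#'   slice) or a fixed probability in \eqn{(0, 1)}.
#' @param config a [DetectionConfig-class].
#' @param nStates number of intensity states (default 7).
#' @param clipPercentiles stretch percentiles (default \code{c(1, 99)}).
#' @return list of class \code{"wmiDetection"} with elements
#'   \code{lesions} (a [LesionMask-class]), \code{boundaries} (the filtered
#'   [BoundarySet-class]), \code{states} (the [StateImage-class]) and
#'   \code{report} (q used and its source, alpha, threshold, counts at each
#'   stage, and the full resolved configuration).
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' det <- detectWMI(ph$image, ph$wmMask)
#' det$report$nComponents
#' @export
detectWMI <- function(image, mask, q = "estimate",
                      config = detectionConfig(), nStates = 7L,
                      clipPercentiles = c(1, 99)) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("detectWMI failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  mask <- mask > 0
  st <- stage("stretch", stretchIntensities(image, mask, clipPercentiles))
  states <- stage("quantize",
                  stretchAndQuantize(image, mask, nStates, clipPercentiles))
  qEstimated <- identical(q, "estimate")
  qClamped <- FALSE
  if (qEstimated) {
    qv <- stage("estimate_q", suppressWarnings(estimateQ(states)))
    qClamped <- isTRUE(attr(qv, "clamped"))
    qv <- as.numeric(qv)
  } else {
    qv <- as.numeric(q)
  }
  model <- stage("solve_alpha", transitionModel(qv, nStates - 1L))
  bRaw <- stage("mark_boundaries", markBoundaries(states, model, config))
  b <- stage("filter_boundaries",
             removeMarginFalseBoundaries(bRaw, mask, config))
  lesions <- stage("grow_regions",
                   suppressWarnings(
                     growRegions(st$stretched, states, b, mask, config)))
  report <- list(
    q = qv, qSource = if (qEstimated) "estimated" else "fixed",
    qClamped = qClamped,
    alpha = model@alpha,
    threshold = config@threshold,
    nStates = as.integer(nStates),
    clipPercentiles = as.numeric(clipPercentiles),
    stretchRange = as.numeric(states@sourceStats),
    maskAreaPx = sum(mask),
    nBoundaryPixelsRaw = nrow(bRaw@pixels),
    nBoundaryPixels = nrow(b@pixels),
    nSeeds = nrow(b@seeds),
    nComponents = nrow(lesions@perComponent),
    lesionAreaPx = sum(lesions@mask),
    capped = isTRUE(attr(lesions, "capped")),
    config = list(threshold = config@threshold, marginPx = config@marginPx,
                  minBoundaryPx = config@minBoundaryPx,
                  growthFraction = config@growthFraction,
                  maxRegionPx = config@maxRegionPx))
  structure(list(lesions = lesions, boundaries = b, states = states,
                 report = report),
            class = "wmiDetection")
}

#' @export
print.wmiDetection <- function(x, ...) {
  r <- x$report
  cat("WMI detection: q =", format(r$q, digits = 4),
      paste0("(", r$qSource, ")"),
      "| alpha =", format(r$alpha, digits = 4),
      "| threshold =", r$threshold, "\n")
  cat("  ", r$nSeeds, "seed(s) ->", r$nComponents, "component(s),",
      r$lesionAreaPx, "px total\n")
  invisible(x)
}
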