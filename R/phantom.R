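#' Specify a synthetic slice phantom
#'
#' Describes a 2D phantom emulating a pre-processed neonatal T1 slice: a
#' compact irregular white-matter region (a perturbed ellipse), a smoothly
#' varying background intensity (linear gradient), additive Gaussian noise,
#' and small bright punctate lesions of known location and area. An optional
#' bright rim at the mask border emulates gray-matter contamination from an
#' imperfect white-matter segmentation.
#'
#' Defaults describe the package's reference study conditions: a 128 x 128
#' slice, a white-matter blob of roughly 4000 px, 16\% peak-to-peak smooth
#' intensity variation, low residual noise (sd 0.002, i.e. the image after
#' the enhancement/median-filter front end that precedes detection), and
#' markedly hyperintense punctate lesions (contrast 100 noise sd, about 0.2
#' in absolute intensity against a 0.5 white-matter base).
#'
#' @param shape length-2 integer, (rows, cols); default \code{c(128, 128)}.
#' @param wmAxes length-2 numeric, ellipse semi-axes in pixels (row, col);
#'   default \code{c(40, 32)}.
#' @param wmPerturb amplitude of the low-frequency radial boundary
#'   perturbation, as a fraction of the radius (default 0.08).
#' @param background length-3 numeric \code{c(base, gradient, noiseSd)}:
#'   base white-matter intensity, peak-to-peak amplitude of the linear
#'   gradient across the frame, and Gaussian noise standard deviation.
#' @param lesions list of lesion descriptors as built by [lesionSpec()];
#'   empty list for a lesion-free phantom.
#' @param rim \code{NULL}, or \code{list(width =, intensity =)} for a bright
#'   band of that pixel width and added intensity just inside the mask
#'   border.
#' @param seed integer RNG seed; the phantom is deterministic given the spec.
#' @return a list of class \code{"phantomSpec"}.
#' @seealso [generatePhantom()], [generatePhantomSuite()]
#' @export
phantomSpec <- function(shape = c(128L, 128L), wmAxes = c(40, 32),
                        wmPerturb = 0.08,
                        background = c(base = 0.5, gradient = 0.08,
                                       noiseSd = 0.002),
                        lesions = list(), rim = NULL, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 16),
            length(wmAxes) == 2L, all(wmAxes > 0),
            wmPerturb >= 0, length(background) == 3L,
            background[[3L]] >= 0, is.list(lesions))
  for (l in lesions) {
    stopifnot(is.list(l), all(c("center", "radius", "contrast") %in%
                              names(l)))
    if (l$radius < 1) stop("lesion radius must be >= 1")
    if (l$contrast <= 0) stop("lesion contrast must be positive")
  }
  if (!is.null(rim))
    stopifnot(is.list(rim), rim$width >= 1, rim$intensity > 0)
  structure(list(shape = as.integer(shape), wmAxes = as.numeric(wmAxes),
                 wmPerturb = wmPerturb,
                 background = stats::setNames(as.numeric(background),
                                              c("base", "gradient",
                                                "noiseSd")),
                 lesions = lesions, rim = rim, seed = as.integer(seed)),
            class = "phantomSpec")
}

#' Describe one punctate lesion
#'
#' @param center length-2 numeric, (row, col) center in pixels.
#' @param radius lesion radius in pixels (>= 1).
#' @param contrast lesion brightness above the local background, as a
#'   multiple of the phantom's noise sd (default 100).
#' @param shape \code{"disc"} (default) or \code{"blob"}: a blob is a disc
#'   warped by a low-frequency radial perturbation, mimicking irregular
#'   punctate injury. The warp derives deterministically from the lesion's
#'   center and radius, so ground truth never depends on the noise seed.
#' @return a lesion descriptor list.
#' @export
lesionSpec <- function(center, radius, contrast = 100, shape = "disc") {
  stopifnot(length(center) == 2L, radius >= 1, contrast > 0,
            shape %in% c("disc", "blob"))
  list(center = as.numeric(center), radius = as.numeric(radius),
       contrast = as.numeric(contrast), shape = shape)
}

# Rasterize one lesion into a logical matrix.
rasterizeLesion <- function(lesion, dim) {
  rr <- matrix(seq_len(dim[1L]), dim[1L], dim[2L])
  cc <- matrix(seq_len(dim[2L]), dim[1L], dim[2L], byrow = TRUE)
  dr <- rr - lesion$center[1L]
  dc <- cc - lesion$center[2L]
  if (identical(lesion$shape, "blob")) {
    # deterministic low-frequency warp keyed on center/radius, independent
    # of the phantom's noise stream
    key <- as.integer((lesion$center[1L] * 7919 + lesion$center[2L] * 104729 +
                       lesion$radius * 131) %% .Machine$integer.max)
    coef <- withLocalSeed(key, stats::runif(4L, -1, 1))
    theta <- atan2(dr, dc)
    rad <- lesion$radius * (1 + 0.25 * (coef[1L] * cos(2 * theta) +
                                        coef[2L] * sin(2 * theta) +
                                        coef[3L] * cos(3 * theta) +
                                        coef[4L] * sin(3 * theta)))
    sqrt(dr^2 + dc^2) <= pmax(rad, 1)
  } else {
    dr^2 + dc^2 <= lesion$radius^2
  }
}

#' Generate a synthetic slice phantom
#'
#' Deterministic for a fixed spec (including its seed). Lesions are bright,
#' as punctate white matter injury is on early T1-weighted imaging; the
#' truth mask and manifest depend only on lesion geometry, never on the
#' noise realization.
#'
#' @param spec a [phantomSpec()].
#' @return list with \code{image} (numeric matrix), \code{wmMask} and
#'   \code{truthMask} (logical matrices), \code{manifest} (data.frame with
#'   one row per lesion: center, radius, contrast, shape, rasterized area)
#'   and \code{spec}.
#' @examples
#' ph <- generatePhantom(phantomSpec(
#'   lesions = list(lesionSpec(c(64, 64), 3)), seed = 42))
#' sum(ph$truthMask)  # 29 px for a radius-3 disc
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  withLocalSeed(spec$seed, {
    nr <- spec$shape[1L]; nc <- spec$shape[2L]
    r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    # white-matter blob: ellipse with low-frequency radial perturbation
    coef <- stats::runif(4L, -1, 1)
    theta <- atan2(rr - r0, cc - c0)
    rho <- sqrt(((rr - r0) / spec$wmAxes[1L])^2 +
                ((cc - c0) / spec$wmAxes[2L])^2)
    pert <- spec$wmPerturb * (coef[1L] * cos(2 * theta) +
                              coef[2L] * sin(2 * theta) +
                              coef[3L] * cos(3 * theta) +
                              coef[4L] * sin(3 * theta))
    wmMask <- rho <= 1 + pert
    # background: base + linear gradient along a random direction + noise
    bg <- spec$background
    phi <- stats::runif(1L, 0, 2 * pi)
    t <- ((cc - c0) * cos(phi) + (rr - r0) * sin(phi)) / max(nr, nc)
    image <- bg[["base"]] + bg[["gradient"]] * t +
      stats::rnorm(nr * nc, 0, bg[["noiseSd"]])
    dim(image) <- c(nr, nc)
    # lesions
    truth <- matrix(FALSE, nr, nc)
    rows <- vector("list", length(spec$lesions))
    for (i in seq_along(spec$lesions)) {
      l <- spec$lesions[[i]]
      lm <- rasterizeLesion(l, spec$shape)
      if (any(lm & !wmMask))
        stop("lesion ", i, " at (", l$center[1L], ", ", l$center[2L],
             ") extends outside the white-matter mask")
      image[lm] <- image[lm] + l$contrast * bg[["noiseSd"]]
      truth <- truth | lm
      rows[[i]] <- data.frame(lesion = i, centerRow = l$center[1L],
                              centerCol = l$center[2L], radius = l$radius,
                              contrast = l$contrast, shape = l$shape,
                              areaPx = sum(lm))
    }
    manifest <- if (length(rows)) do.call(rbind, rows)
                else data.frame(lesion = integer(), centerRow = numeric(),
                                centerCol = numeric(), radius = numeric(),
                                contrast = numeric(), shape = character(),
                                areaPx = integer())
    # optional bright rim just inside the mask border (gray-matter
    # contamination scenario); never part of the ground truth
    if (!is.null(spec$rim)) {
      d <- distanceToBackground(wmMask)
      rimPx <- wmMask & d <= spec$rim$width
      image[rimPx] <- image[rimPx] + spec$rim$intensity
    }
    list(image = image, wmMask = wmMask, truthMask = truth,
         manifest = manifest, spec = spec)
  })
}

#' Generate a reproducible suite of phantoms
#'
#' Batch generator for statistical checks: a fixed fraction of the images
#' carry lesions (the first \code{round(lesionPrevalence * nImages)} of the
#' suite), the rest are lesion-free. Lesioned images receive 2-4 lesions
#' with radii 3-5 px and contrasts drawn uniformly from 90-120 noise sd,
#' placed uniformly inside the white-matter mask eroded by radius + 4 px so
#' that no lesion touches the margin exclusion band; clusters arise
#' naturally when draws land close together. Per-image seeds derive from
#' \code{seed}, so the suite is byte-identical across runs.
#'
#' @param nImages number of phantoms.
#' @param lesionPrevalence fraction of images with lesions, in \eqn{[0, 1]}.
#' @param seed integer master seed.
#' @param ... further arguments passed to [phantomSpec()] (e.g. \code{rim}).
#' @return list of phantom tuples as returned by [generatePhantom()].
#' @export
generatePhantomSuite <- function(nImages, lesionPrevalence, seed, ...) {
  stopifnot(nImages >= 1, lesionPrevalence >= 0, lesionPrevalence <= 1)
  nLesioned <- round(lesionPrevalence * nImages)
  lapply(seq_len(nImages), function(i) {
    subSeed <- as.integer((as.double(seed) * 7919 + i * 104729) %%
                          2147483647)
    if (i <= nLesioned) {
      # realize the mask first so lesion centers can be sampled inside it
      probe <- generatePhantom(phantomSpec(seed = subSeed, ...))
      lesions <- withLocalSeed(subSeed + 1L, {
        k <- sample(2:4, 1L)
        maxR <- 5
        d <- distanceToBackground(probe$wmMask)
        ok <- which(d > maxR + 4)
        centers <- arrayInd(sample(ok, k), dim(probe$wmMask))
        lapply(seq_len(k), function(j)
          lesionSpec(center = centers[j, ], radius = sample(3:5, 1L),
                     contrast = stats::runif(1L, 90, 120),
                     shape = sample(c("disc", "blob"), 1L)))
      })
      generatePhantom(phantomSpec(seed = subSeed, lesions = lesions, ...))
    } else {
      generatePhantom(phantomSpec(seed = subSeed, ...))
    }
  })
}
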