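# Readers and writers. Conventions, stated once to avoid dialect drift:
# coordinates are 0-based (row, col) in reports, row-major; masks are 0/255
# in PNG and 0/1 in NIfTI; all images are plain R matrices [row, col].

readRaster <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unreadable file: unsupported raster format '.", ext, "' for ",
         path))
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    flat <- matrix(img, ncol = ch)
    if (ch >= 3L && any(abs(flat[, 1L] - flat[, 2L]) > 1e-9))
      stop("grayscale required: ", path, " has differing color channels")
    img <- img[, , 1L]
  }
  img
}

isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a slice and its white-matter mask
#'
#' Accepts NIfTI volumes (\code{.nii}/\code{.nii.gz}; a 2D slice is
#' extracted along the chosen axis and the pixel spacing comes from the
#' header) or 8/16-bit PNG/TIFF slice images (spacing must then be supplied).
#' The mask (and optional ground-truth mask) must share the image geometry.
#'
#' @param path image file.
#' @param maskPath white-matter mask file (same format family).
#' @param truthPath optional ground-truth lesion mask file.
#' @param sliceIndex 1-based slice position, required for 3D NIfTI input.
#' @param sliceAxis axis along which to slice a NIfTI volume (1, 2 or 3;
#'   default 3).
#' @param spacing length-2 numeric (row mm, col mm); required for PNG/TIFF,
#'   overrides the header for NIfTI.
#' @return list of class \code{"slicePair"}: \code{image} (numeric matrix),
#'   \code{wmMask} and (possibly NULL) \code{truthMask} (logical matrices),
#'   \code{spacing}, \code{provenance} (source paths and slice index).
#' @export
readSlice <- function(path, maskPath, truthPath = NULL, sliceIndex = NULL,
                      sliceAxis = 3L, spacing = NULL) {
  readOne <- function(p) {
    if (!file.exists(p)) stop("unreadable file: ", p, " does not exist")
    if (isNifti(p)) {
      vol <- RNifti::readNifti(p)
      pd <- RNifti::pixdim(vol)
      arr <- as.array(vol)
      if (length(dim(arr)) == 3L) {
        if (is.null(sliceIndex))
          stop("sliceIndex is required for 3D NIfTI input")
        arr <- switch(as.character(sliceAxis),
                      "1" = arr[sliceIndex, , ],
                      "2" = arr[, sliceIndex, ],
                      "3" = arr[, , sliceIndex],
                      stop("sliceAxis must be 1, 2 or 3"))
      } else if (length(dim(arr)) != 2L) {
        stop("unreadable file: ", p, " is not a 2D/3D NIfTI image")
      }
      inPlane <- setdiff(1:3, as.integer(sliceAxis))[1:2]
      list(data = matrix(as.numeric(arr), nrow(arr), ncol(arr)),
           spacing = pd[inPlane])
    } else {
      list(data = readRaster(p), spacing = NULL)
    }
  }
  im <- readOne(path)
  mk <- readOne(maskPath)
  if (!identical(dim(im$data), dim(mk$data)))
    stop("mask geometry mismatch: image is ",
         paste(dim(im$data), collapse = "x"), ", mask is ",
         paste(dim(mk$data), collapse = "x"))
  tr <- NULL
  if (!is.null(truthPath)) {
    tr <- readOne(truthPath)
    if (!identical(dim(im$data), dim(tr$data)))
      stop("mask geometry mismatch: truth mask does not match the image")
  }
  sp <- if (!is.null(spacing)) as.numeric(spacing) else im$spacing
  if (is.null(sp))
    stop("missing spacing: PNG/TIFF carries no pixel size; supply ",
         "spacing = c(row_mm, col_mm)")
  if (length(sp) != 2L || any(!is.finite(sp)) || any(sp <= 0))
    stop("spacing must be two positive numbers (mm)")
  structure(list(image = im$data, wmMask = mk$data > 0.5,
                 truthMask = if (is.null(tr)) NULL else tr$data > 0.5,
                 spacing = sp,
                 provenance = list(image = path, mask = maskPath,
                                   truth = truthPath,
                                   sliceIndex = sliceIndex)),
            class = "slicePair")
}

#' Write a binary mask
#'
#' PNG output encodes the mask as 0/255 8-bit grayscale; NIfTI output as
#' 0/1 integers. Writing then reading any mask reproduces it exactly.
#'
#' @param mask a [LesionMask-class] or logical matrix.
#' @param path destination; format chosen by extension (\code{.png},
#'   \code{.nii}, \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- if (is(mask, "LesionMask")) mask@mask else mask > 0
  if (isNifti(path)) {
    RNifti::writeNifti(RNifti::asNifti(matrix(as.integer(m), nrow(m),
                                              ncol(m))), path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  } else {
    stop("unsupported mask format for ", path, " (use .png or .nii[.gz])")
  }
  invisible(path)
}

#' Read a binary mask written by [writeMask()]
#'
#' @param path mask file (PNG or NIfTI).
#' @return logical matrix.
#' @export
readMask <- function(path) {
  if (isNifti(path)) {
    arr <- as.array(RNifti::readNifti(path))
    matrix(as.numeric(arr), nrow(arr), ncol(arr)) > 0.5
  } else {
    readRaster(path) > 0.5
  }
}

#' Write detection outputs
#'
#' Writes the lesion mask plus a JSON run report embedding the full resolved
#' configuration (the reproducibility contract: identical inputs and config
#' give bit-identical files; no timestamps are recorded). Component areas in
#' the report sum to the mask area.
#'
#' @param detection a \code{"wmiDetection"} result from [detectWMI()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"wmi"}).
#' @param maskFormat \code{"png"} (default) or \code{"nii"}.
#' @param pixelSpacing optional (row mm, col mm); when given, per-component
#'   areas are also reported in cm^2.
#' @return named character vector of the files written, invisibly.
#' @export
writeDetectionOutputs <- function(detection, dir, prefix = "wmi",
                                  maskFormat = c("png", "nii"),
                                  pixelSpacing = NULL) {
  stopifnot(inherits(detection, "wmiDetection"))
  maskFormat <- match.arg(maskFormat)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maskPath <- file.path(dir, paste0(prefix, "_mask.",
                                    if (maskFormat == "png") "png"
                                    else "nii.gz"))
  writeMask(detection$lesions, maskPath)
  comp <- detection$lesions@perComponent
  compOut <- lapply(seq_len(nrow(comp)), function(i) {
    row <- list(label = comp$label[i], areaPx = comp$areaPx[i],
                # 0-based (row, col) coordinates in reports
                centroidRow = comp$centroidRow[i] - 1,
                centroidCol = comp$centroidCol[i] - 1)
    if (!is.null(pixelSpacing))
      row$areaCm2 <- comp$areaPx[i] * pixelSpacing[1L] *
        pixelSpacing[2L] / 100
    row
  })
  report <- c(detection$report, list(components = compOut))
  reportPath <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(mask = maskPath, report = reportPath))
}

#' Write an evaluation report
#'
#' CSV tables (accuracy-distance histogram, per-case Bland-Altman points,
#' binned difference table) plus a JSON summary.
#'
#' @param histogram data.frame from [accuracyDistanceHistogram()], or NULL.
#' @param ba a [BlandAltmanSummary-class], or NULL.
#' @param dir output directory.
#' @param prefix file-name prefix (default \code{"eval"}).
#' @param binWidth bin width for [binnedDifferenceTable()] (default 0.1).
#' @return named character vector of files written, invisibly.
#' @export
writeEvaluationOutputs <- function(histogram = NULL, ba = NULL, dir,
                                   prefix = "eval", binWidth = 0.1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  summary <- list()
  if (!is.null(histogram)) {
    p <- file.path(dir, paste0(prefix, "_distance_histogram.csv"))
    utils::write.csv(histogram, p, row.names = FALSE)
    files["histogram"] <- p
    summary$detectedPixels <- sum(histogram$count)
    summary$withinTruth <- sum(histogram$count[histogram$distance == 0])
  }
  if (!is.null(ba)) {
    stopifnot(is(ba, "BlandAltmanSummary"))
    p <- file.path(dir, paste0(prefix, "_bland_altman.csv"))
    utils::write.csv(ba@perCase, p, row.names = FALSE)
    files["blandAltman"] <- p
    p2 <- file.path(dir, paste0(prefix, "_binned_differences.csv"))
    utils::write.csv(binnedDifferenceTable(ba, binWidth), p2,
                     row.names = FALSE)
    files["binned"] <- p2
    summary$bias <- ba@bias
    summary$loaLow <- ba@loaLow
    summary$loaHigh <- ba@loaHigh
    summary$nCases <- nrow(ba@perCase)
  }
  p <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["summary"] <- p
  invisible(files)
}
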