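# Shared pixel-grid helpers. Images are plain R matrices indexed [row, col];
# linear indices are column-major as usual in R.

# Unordered unique 8-connected in-mask pixel pairs, as a 2-column matrix of
# linear indices. Each pair appears exactly once (offsets cover E, S, SE, SW).
adjacentPairs <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(integer(), 0L, 2L))
  rc <- arrayInd(idx, dim(mask))
  out <- vector("list", 4L)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (k in seq_along(offs)) {
    r2 <- rc[, 1L] + offs[[k]][1L]
    c2 <- rc[, 2L] + offs[[k]][2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (any(ok)) {
      j <- (c2[ok] - 1L) * nr + r2[ok]
      keep <- mask[j]
      out[[k]] <- cbind(idx[ok][keep], j[keep], deparse.level = 0L)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(), 0L, 2L) else res
}

#' Label connected components of a binary mask
#'
#' 8-connected (or 4-connected) component labelling via the pixel adjacency
#' graph. Labels are positive integers assigned in order of each component's
#' first pixel in column-major order; background is 0.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default, diagonals count) or 4.
#' @return integer matrix of labels, same dimensions as \code{mask}.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(mask))
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (o in offs) {
    r2 <- rc[, 1L] + o[1L]
    c2 <- rc[, 2L] + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (any(ok)) {
      j <- (c2[ok] - 1L) * nr + r2[ok]
      keep <- mask[j]
      if (any(keep))
        edges[[length(edges) + 1L]] <- cbind(vid[idx[ok][keep]], vid[j[keep]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))))
  memb <- igraph::components(g)$membership
  # relabel so component ids follow first occurrence in column-major order
  relab <- integer(max(memb))
  nxt <- 0L
  for (m in memb) if (!relab[m]) { nxt <- nxt + 1L; relab[m] <- nxt }
  lab[idx] <- relab[memb]
  lab
}

# Euclidean distance from each in-mask pixel to the nearest out-of-mask
# pixel; out-of-mask pixels get 0. With pad = TRUE (the white-matter margin
# semantics) the image frame counts as out-of-mask, so a mask touching the
# frame still has a margin there; with pad = FALSE distances ignore the
# frame and are Inf when the mask covers the whole image.
distanceToBackground <- function(mask, pad = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(as.integer(mask > 0), nr, nc)
  if (pad) {
    mp <- matrix(0L, nr + 2L, nc + 2L)
    mp[2:(nr + 1L), 2:(nc + 1L)] <- m
    d <- EBImage::distmap(mp, metric = "euclidean")
    matrix(as.numeric(d[2:(nr + 1L), 2:(nc + 1L)]), nr, nc)
  } else {
    matrix(as.numeric(EBImage::distmap(m, metric = "euclidean")), nr, nc)
  }
}

# Per-component area and centroid summary from a label matrix.
componentSummary <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), areaPx = integer(),
                      centroidRow = numeric(), centroidCol = numeric()))
  rc <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  area <- tapply(lab, lab, length)
  crow <- tapply(rc[, 1L], lab, mean)
  ccol <- tapply(rc[, 2L], lab, mean)
  lv <- as.integer(names(area))
  data.frame(label = lv, areaPx = as.integer(area),
             centroidRow = as.numeric(crow), centroidCol = as.numeric(ccol),
             row.names = NULL)
}

# Build a LesionMask from a logical matrix.
newLesionMask <- function(mask) {
  labels <- labelComponents(mask, 8L)
  new("LesionMask", mask = mask, labels = labels,
      perComponent = componentSummary(labels))
}

# Sort (row, col) coordinate rows into row-major order; dedupe.
sortPixels <- function(px) {
  if (!nrow(px)) return(px)
  px <- px[!duplicated(px), , drop = FALSE]
  px[order(px[, 1L], px[, 2L]), , drop = FALSE]
}

# Run a block with a locally-seeded RNG, restoring global state afterwards.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
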