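# Independent oracles: deliberately naive double-loop implementations used
# to cross-check the vectorized package code, plus small fixture builders.

# All unordered 8-connected in-mask pixel pairs by exhaustive enumeration.
oraclePairs <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !mask[r2, c2]) next
      a <- c(r, c); b <- c(r2, c2)
      key <- if (a[1] < b[1] || (a[1] == b[1] && a[2] < b[2]))
        paste(a[1], a[2], b[1], b[2]) else paste(b[1], b[2], a[1], a[2])
      out[[key]] <- key
    }
  }
  names(out)
}

# Fraction of equal-state pairs, by exhaustive enumeration.
oracleEstimateQ <- function(states, mask) {
  keys <- oraclePairs(mask)
  eq <- vapply(keys, function(k) {
    v <- as.integer(strsplit(k, " ")[[1]])
    states[v[1], v[2]] == states[v[3], v[4]]
  }, logical(1))
  mean(eq)
}

# Rare-transition boundary pixels and seeds, by exhaustive enumeration.
oracleBoundaries <- function(states, q, alpha, threshold) {
  mask <- states >= 0L
  keys <- oraclePairs(mask)
  pix <- character(); seeds <- character()
  for (k in keys) {
    v <- as.integer(strsplit(k, " ")[[1]])
    s1 <- states[v[1], v[2]]; s2 <- states[v[3], v[4]]
    if (q * alpha^abs(s1 - s2) < threshold) {
      pix <- c(pix, paste(v[1], v[2]), paste(v[3], v[4]))
      if (s1 > s2) seeds <- c(seeds, paste(v[1], v[2]))
      if (s2 > s1) seeds <- c(seeds, paste(v[3], v[4]))
    }
  }
  list(pixels = sort(unique(pix)), seeds = sort(unique(seeds)))
}

# Grid-scan + hand-rolled bisection root of the transition polynomial,
# independent of solveAlpha's implementation.
oracleAlpha <- function(q, n, gridStep = 1e-5) {
  f <- function(a) q * a^(n + 1) - a + (1 - q)
  grid <- seq(gridStep, 1 - gridStep, by = gridStep)
  fv <- f(grid)
  sw <- which(fv[-1] * fv[-length(fv)] < 0)
  if (!length(sw)) return(NULL)
  lo <- grid[sw[1]]; hi <- grid[sw[1] + 1]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Count sign changes of the polynomial over a fine grid of (0, 1).
oracleSignChanges <- function(q, n, gridStep = 1e-5) {
  f <- function(a) q * a^(n + 1) - a + (1 - q)
  grid <- seq(gridStep, 1 - gridStep, by = gridStep)
  fv <- f(grid)
  sum(fv[-1] * fv[-length(fv)] < 0)
}

# Wrap a raw integer state matrix as a StateImage.
makeStateImage <- function(states, nStates) {
  new("StateImage", states = states, space = stateSpace(nStates),
      sourceStats = c(0, 1))
}

# Canonical key form of a (row, col) coordinate matrix, for set comparison.
pixelKeys <- function(px) sort(paste(px[, 1], px[, 2]))

# Random state matrix with full mask.
randomStates <- function(nr, nc, nStates)
  matrix(sample(0:(nStates - 1L), nr * nc, replace = TRUE), nr, nc)
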