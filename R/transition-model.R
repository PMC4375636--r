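#' Solve for the geometric decay rate of the transition model
#'
#' The drop-size probabilities \eqn{q\alpha^k}, \eqn{k = 0, \dots, n}, must
#' sum to one, which by the geometric-series sum reduces to the polynomial
#' \deqn{q\alpha^{n+1} - \alpha + (1 - q) = 0.}
#' \eqn{\alpha = 1} is always a root but violates normalization; most of the
#' remaining roots are complex, and for feasible \eqn{(q, n)} exactly one real
#' root lies strictly inside \eqn{(0, 1)}. That root is located by a
#' sign-change scan followed by bracketed bisection, which is guaranteed to
#' converge on a bracketed monotone segment; no polynomial companion-matrix
#' machinery is needed.
#'
#' A pair \eqn{(q, n)} is infeasible when no root lies in the open interval
#' (this happens iff \eqn{q \le 1/(n+1)}, where the geometric tail cannot be
#' fat enough to absorb the remaining mass); the function then fails loudly
#' rather than returning the boundary root 1.
#'
#' @param q probability of staying in the same state, in \eqn{(0, 1)}.
#' @param n highest state index (the polynomial has degree \eqn{n + 1}).
#' @param tol absolute tolerance on the root (default 1e-12).
#' @return the root \eqn{\alpha \in (0, 1)}.
#' @examples
#' solveAlpha(0.4, 3)   # 0.69141...
#' solveAlpha(0.8, 3)   # 0.20131...
#' @export
solveAlpha <- function(q, n, tol = 1e-12) {
  stopifnot(is.numeric(q), length(q) == 1L, is.numeric(n), length(n) == 1L)
  if (!(q > 0 && q < 1)) stop("q must be strictly inside (0, 1), got ", q)
  n <- as.integer(n)
  if (n < 1L) stop("n must be a positive integer, got ", n)
  f <- function(a) q * a^(n + 1) - a + (1 - q)
  eps <- 1e-12
  # sign-change scan over the open interval; f(0+) = 1 - q > 0 always
  grid <- seq(eps, 1 - eps, length.out = 4096L)
  fv <- f(grid)
  sw <- which(fv[-1L] * fv[-length(fv)] <= 0 & fv[-length(fv)] != 0)
  if (!length(sw)) {
    # root may coincide with a grid point
    hit <- which(fv == 0)
    if (length(hit)) return(grid[hit[1L]])
    stop("infeasible (q, n) pair: no root of the transition polynomial in ",
         "(0, 1) for q = ", q, ", n = ", n)
  }
  lo <- grid[sw[1L]]; hi <- grid[sw[1L] + 1L]
  root <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  if (root <= eps || root >= 1 - eps)
    stop("infeasible (q, n) pair: only boundary roots for q = ", q,
         ", n = ", n)
  root
}

#' Conditional drop-size probabilities of the transition model
#'
#' Returns \eqn{(q\alpha^0, q\alpha^1, \dots, q\alpha^n)}: element
#' \eqn{k + 1} is the conditional probability that the darker member of an
#' adjacent pixel pair sits exactly \eqn{k} states below the brighter one.
#' The vector sums to 1 by construction of \eqn{\alpha}.
#'
#' @inheritParams solveAlpha
#' @return numeric vector of length \code{n + 1}.
#' @examples
#' round(transitionProbabilities(0.8, 3), 3)  # 0.800 0.161 0.032 0.007
#' @export
transitionProbabilities <- function(q, n) {
  alpha <- solveAlpha(q, n)
  q * alpha^(0:as.integer(n))
}

#' Construct a TransitionModel
#'
#' Solves for \eqn{\alpha} and packages the geometric drop-size law as a
#' validated [TransitionModel-class] object.
#'
#' @inheritParams solveAlpha
#' @return a [TransitionModel-class].
#' @examples
#' transitionModel(0.4, 6)
#' @export
transitionModel <- function(q, n) {
  n <- as.integer(n)
  alpha <- solveAlpha(q, n)
  new("TransitionModel", q = as.numeric(q), alpha = alpha, n = n,
      probs = q * alpha^(0:n))
}

#' Estimate the same-state probability q from a quantized slice
#'
#' \eqn{q} is the probability that two adjacent white-matter pixels fall in
#' the same intensity state. It is estimated as the fraction of unordered
#' 8-connected in-mask pixel pairs whose states are equal, matching the
#' adjacency used by the detection step.
#'
#' A degenerate estimate of exactly 0 or 1 is clamped into the open interval
#' by \eqn{\pm 1/(P + 1)} (\eqn{P} = number of pairs) so the \eqn{\alpha}
#' polynomial remains solvable; clamping is reported via a warning and the
#' \code{"clamped"} attribute of the result.
#'
#' @param states a [StateImage-class], or an integer state matrix with
#'   sentinel -1 outside the mask.
#' @param mask optional logical matrix restricting the estimate; defaults to
#'   the in-mask (non-sentinel) pixels of \code{states}.
#' @return the estimate in \eqn{(0, 1)}, with attributes \code{nPairs} and
#'   \code{clamped}.
#' @export
estimateQ <- function(states, mask = NULL) {
  sm <- if (is(states, "StateImage")) states@states else states
  stopifnot(is.matrix(sm))
  if (is.null(mask)) mask <- sm >= 0L
  if (!any(mask)) stop("degenerate mask: no in-mask pixels")
  pairs <- adjacentPairs(mask)
  if (!nrow(pairs)) stop("degenerate mask: no adjacent in-mask pixel pairs")
  qhat <- mean(sm[pairs[, 1L]] == sm[pairs[, 2L]])
  clamped <- FALSE
  P <- nrow(pairs)
  if (qhat <= 0) { qhat <- 1 / (P + 1); clamped <- TRUE }
  if (qhat >= 1) { qhat <- 1 - 1 / (P + 1); clamped <- TRUE }
  if (clamped)
    warning("q estimate was degenerate (0 or 1); clamped to ", qhat)
  structure(qhat, nPairs = P, clamped = clamped)
}

#' Enumerate the significant (rare) state transitions
#'
#' Ordered state pairs \eqn{(s_a, s_b)} with \eqn{a > b} whose conditional
#' transition probability \eqn{q\alpha^{a-b}} falls below the threshold. The
#' set depends only on the drop size \eqn{a - b}, so it is the union over all
#' pairs whose drop is at least the minimal significant drop.
#'
#' @param model a [TransitionModel-class].
#' @param threshold probability cutoff in \eqn{(0, 1)} (the worked default in
#'   the detector is 0.01).
#' @return data.frame with columns \code{from}, \code{to}, \code{drop},
#'   \code{prob}; zero rows when no transition is rare.
#' @examples
#' significantTransitions(transitionModel(0.8, 3), 0.01)  # only s3 -> s0
#' @export
significantTransitions <- function(model, threshold) {
  stopifnot(is(model, "TransitionModel"))
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be in (0, 1)")
  n <- model@n
  drops <- which(model@probs < threshold) - 1L  # drop sizes below threshold
  drops <- drops[drops >= 1L]
  if (!length(drops))
    return(data.frame(from = integer(), to = integer(), drop = integer(),
                      prob = numeric()))
  out <- do.call(rbind, lapply(drops, function(d) {
    a <- seq.int(d, n)
    data.frame(from = a, to = a - d, drop = d,
               prob = model@probs[d + 1L])
  }))
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the rarity threshold from the slice itself
#'
#' Statistical alternative to a fixed cutoff: the threshold is chosen as the
#' empirical \code{f}-quantile of the model probabilities observed across all
#' adjacent in-mask pixel pairs, so that roughly a fraction \code{f} of pairs
#' is flagged as rare.
#'
#' @param states a [StateImage-class].
#' @param model a [TransitionModel-class] for the same state count.
#' @param f target flagged fraction (default 0.001).
#' @return a probability usable as \code{threshold} in [detectionConfig()].
#' @export
calibrateThreshold <- function(states, model, f = 0.001) {
  stopifnot(is(states, "StateImage"), is(model, "TransitionModel"))
  sm <- states@states
  pairs <- adjacentPairs(sm >= 0L)
  if (!nrow(pairs)) stop("degenerate mask: no adjacent in-mask pixel pairs")
  drop <- abs(sm[pairs[, 1L]] - sm[pairs[, 2L]])
  probs <- model@q * model@alpha^drop
  as.numeric(stats::quantile(probs, f, type = 1L))
}
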