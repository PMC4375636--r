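# The stochastic core: alpha root solving, the geometric drop-size law,
# q estimation, and significance classification.

test_that("solveAlpha reproduces the worked decay rates", {
  expect_equal(round(solveAlpha(0.4, 3), 5), 0.69141)
  expect_equal(round(solveAlpha(0.8, 3), 5), 0.20131)
  expect_equal(round(solveAlpha(0.4, 6), 5), 0.61301)
  # frozen high-precision values (computed with the grid+bisection oracle)
  expect_equal(solveAlpha(0.4, 3), 0.6914140, tolerance = 1e-6)
  expect_equal(solveAlpha(0.8, 3), 0.2013140, tolerance = 1e-6)
  expect_equal(solveAlpha(0.4, 6), 0.6130120, tolerance = 1e-6)
})

test_that("solveAlpha matches the closed form for n = 1 and rejects alpha = 1", {
  # for n = 1 the polynomial factors as q(a - 1)(a - (1-q)/q)
  for (q in c(0.55, 0.6, 0.75, 0.9))
    expect_equal(solveAlpha(q, 1), (1 - q) / q, tolerance = 1e-9)
  # q = 0.5, n = 1 collapses both roots onto 1, outside (0, 1)
  expect_error(solveAlpha(0.5, 1), "infeasible")
  expect_error(solveAlpha(0.4, 1), "infeasible")
  expect_error(solveAlpha(0.2, 3), "infeasible")
  expect_error(solveAlpha(0, 3), "strictly inside")
  expect_error(solveAlpha(1, 3), "strictly inside")
})

test_that("the root satisfies its polynomial and the probabilities normalize", {
  for (q in seq(0.35, 0.95, by = 0.1)) for (n in c(2:8)) {
    if (q <= 1 / (n + 1)) next
    a <- solveAlpha(q, n)
    expect_lt(abs(q * a^(n + 1) - a + (1 - q)), 1e-9)
    p <- transitionProbabilities(q, n)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(p[1], q)
    # strictly decreasing geometric law
    expect_true(all(diff(p) < 0))
  }
})

test_that("alpha is strictly decreasing in q for fixed n", {
  for (n in c(2L, 3L, 6L, 10L)) {
    qs <- seq(0.35, 0.95, by = 0.05)
    qs <- qs[qs > 1 / (n + 1)]
    alphas <- vapply(qs, solveAlpha, numeric(1), n = n)
    expect_true(all(diff(alphas) < 0))
  }
})

test_that("transition probabilities agree with the printed worked examples", {
  # printed vectors carry 3 decimals; agreement to one ulp of that precision
  expect_lt(max(abs(round(transitionProbabilities(0.4, 3), 3) -
                    c(0.4, 0.276, 0.192, 0.132))), 0.0011)
  expect_equal(round(transitionProbabilities(0.8, 3), 3),
               c(0.8, 0.161, 0.032, 0.007))
  expect_lt(max(abs(round(transitionProbabilities(0.4, 6), 3) -
                    c(0.4, 0.245, 0.150, 0.092, 0.057, 0.035, 0.021))),
            0.0011)
  # frozen exact values at full precision
  expect_equal(transitionProbabilities(0.4, 3),
               c(0.4, 0.2765656, 0.1912213, 0.1322131), tolerance = 1e-6)
})

test_that("transitionModel builds a valid object with matching slots", {
  m <- transitionModel(0.8, 3)
  expect_s4_class(m, "TransitionModel")
  expect_true(validObject(m))
  expect_equal(stayProb(m), 0.8)
  expect_equal(decayRate(m), solveAlpha(0.8, 3))
  expect_equal(nStates(m), 4L)
  expect_equal(sum(transitionProbs(m)), 1, tolerance = 1e-9)
})

test_that("estimateQ equals the exhaustive pair-count oracle", {
  set.seed(71)
  for (trial in 1:8) {
    nStatesK <- sample(3:7, 1)
    st <- randomStates(sample(5:16, 1), sample(5:16, 1), nStatesK)
    # randomly punch holes in the mask
    mask <- matrix(runif(length(st)) > 0.2, nrow(st), ncol(st))
    st[!mask] <- -1L
    if (sum(mask) < 4) next
    got <- estimateQ(makeStateImage(st, nStatesK))
    want <- oracleEstimateQ(st, mask)
    if (want > 0 && want < 1)
      expect_equal(as.numeric(got), want)
  }
})

test_that("degenerate q estimates are clamped into (0, 1) and reported", {
  st <- matrix(2L, 4, 4)  # constant states: all pairs equal
  expect_warning(q1 <- estimateQ(makeStateImage(st, 5L)), "clamped")
  expect_lt(as.numeric(q1), 1)
  expect_true(attr(q1, "clamped"))
  expect_equal(as.numeric(q1), 1 - 1 / (attr(q1, "nPairs") + 1))
  # a single equal pair
  st2 <- matrix(c(3L, 3L), 2, 1)
  expect_warning(q2 <- estimateQ(makeStateImage(st2, 5L)), "clamped")
  expect_equal(as.numeric(q2), 1 - 1 / 2)
  # empty / degenerate masks signal
  expect_error(estimateQ(matrix(-1L, 3, 3)), "degenerate mask")
  st3 <- matrix(-1L, 3, 3); st3[1, 1] <- 2L; st3[3, 3] <- 4L
  expect_error(estimateQ(st3), "degenerate mask")
})

test_that("a two-state checkerboard yields the enumerated pair fraction", {
  st <- outer(1:4, 1:4, function(r, c) as.integer((r + c) %% 2))
  q <- estimateQ(makeStateImage(st, 2L))
  # 4-neighbour pairs all unequal, diagonal pairs all equal
  expect_equal(as.numeric(q), oracleEstimateQ(st, st >= 0L))
  expect_equal(as.numeric(q), 18 / 42)  # 18 diagonal pairs of 42 total
})

test_that("significantTransitions reflects the minimal significant drop", {
  m2 <- transitionModel(0.8, 3)
  sig <- significantTransitions(m2, 0.01)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$from, 3L)
  expect_equal(sig$to, 0L)
  # threshold below the smallest probability: empty set
  expect_equal(nrow(significantTransitions(m2, min(transitionProbs(m2)) *
                                           0.5)), 0L)
  # direct filter: every listed pair is below threshold, every drop >= the
  # minimal significant drop appears for all feasible (from, to)
  m3 <- transitionModel(0.4, 6)
  thr <- 0.06
  sig3 <- significantTransitions(m3, thr)
  probs <- transitionProbs(m3)
  dmin <- min(which(probs < thr)) - 1L
  want <- sum(vapply(dmin:6, function(d) 7L - d, integer(1)))
  expect_equal(nrow(sig3), want)
  expect_true(all(sig3$prob < thr))
  expect_true(all(sig3$from > sig3$to))
  # a threshold just above q flags every drop including 0-drops of pairs
  sigAll <- significantTransitions(m3, 0.41)
  expect_true(all((sigAll$from - sigAll$to) >= 1L))
})

test_that("calibrateThreshold returns the empirical quantile of pair probs", {
  set.seed(5)
  st <- randomStates(12, 12, 4)
  si <- makeStateImage(st, 4L)
  m <- transitionModel(0.6, 3)
  # oracle: enumerate all pair probabilities, take the type-1 quantile
  keys <- oraclePairs(st >= 0L)
  probs <- vapply(keys, function(k) {
    v <- as.integer(strsplit(k, " ")[[1]])
    stayProb(m) * decayRate(m)^abs(st[v[1], v[2]] - st[v[3], v[4]])
  }, numeric(1))
  for (f in c(0.01, 0.1, 0.5))
    expect_equal(calibrateThreshold(si, m, f),
                 as.numeric(quantile(probs, f, type = 1)))
})
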