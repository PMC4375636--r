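# Boundary marking, margin filtering, region growing and the composed
# detector.

test_that("a uniform-state image yields no boundaries", {
  si <- makeStateImage(matrix(2L, 10, 10), 4L)
  b <- markBoundaries(si, transitionModel(0.8, 3), detectionConfig())
  expect_equal(nrow(boundaryPixels(b)), 0L)
  expect_equal(nrow(boundarySeeds(b)), 0L)
})

test_that("a single significant drop flags both pixels, the brighter as seed", {
  si <- makeStateImage(matrix(c(3L, 0L), 2, 1), 4L)
  b <- markBoundaries(si, transitionModel(0.8, 3), detectionConfig(0.01))
  expect_equal(pixelKeys(boundaryPixels(b)), c("1 1", "2 1"))
  expect_equal(pixelKeys(boundarySeeds(b)), "1 1")  # the state-3 pixel
  # the same drop is below threshold regardless of orientation
  si2 <- makeStateImage(matrix(c(0L, 3L), 2, 1), 4L)
  b2 <- markBoundaries(si2, transitionModel(0.8, 3), detectionConfig(0.01))
  expect_equal(pixelKeys(boundarySeeds(b2)), "2 1")
})

test_that("markBoundaries matches the exhaustive all-pairs oracle", {
  set.seed(31)
  for (trial in 1:20) {
    nS <- sample(4:7, 1)
    st <- randomStates(16, 16, nS)
    # irregular mask in half the trials
    if (trial %% 2 == 0) st[matrix(runif(256) < 0.25, 16, 16)] <- -1L
    q <- runif(1, 0.35, 0.9)
    if (q <= 1 / nS) next
    m <- transitionModel(q, nS - 1L)
    thr <- runif(1, 0.005, 0.2)
    got <- markBoundaries(makeStateImage(st, nS), m, detectionConfig(thr))
    want <- oracleBoundaries(st, stayProb(m), decayRate(m), thr)
    expect_equal(pixelKeys(boundaryPixels(got)), want$pixels)
    expect_equal(pixelKeys(boundarySeeds(got)), want$seeds)
  }
})

test_that("model/state-space mismatch is a configuration error", {
  si <- makeStateImage(matrix(1L, 4, 4), 5L)
  expect_error(markBoundaries(si, transitionModel(0.8, 3)),
               "configuration error")
})

test_that("lowering the threshold never adds boundary pixels", {
  set.seed(32)
  st <- randomStates(16, 16, 7)
  si <- makeStateImage(st, 7L)
  m <- transitionModel(0.6, 6L)
  prev <- NULL
  for (thr in c(0.2, 0.1, 0.05, 0.02, 0.01, 0.003)) {
    px <- pixelKeys(boundaryPixels(markBoundaries(si, m,
                                                  detectionConfig(thr))))
    if (!is.null(prev)) expect_true(all(px %in% prev))
    prev <- px
  }
})

test_that("margin filtering removes border-hugging boundaries", {
  mask <- matrix(TRUE, 12, 12)
  # boundary pixels all on the mask border: removed entirely at margin 2
  border <- which(row(mask) <= 2 | row(mask) >= 11 | col(mask) <= 2 |
                  col(mask) >= 11)
  px <- arrayInd(border, dim(mask)); colnames(px) <- c("row", "col")
  b <- new("BoundarySet", pixels = px, seeds = px[1:3, , drop = FALSE],
           dim = dim(mask))
  out <- removeMarginFalseBoundaries(b, mask, detectionConfig(marginPx = 2))
  expect_equal(nrow(boundaryPixels(out)), 0L)
  expect_equal(nrow(boundarySeeds(out)), 0L)
})

test_that("small boundary components are deleted, larger ones survive", {
  mask <- matrix(TRUE, 20, 20)
  five <- cbind(row = c(10, 10, 10, 11, 11), col = c(8, 9, 10, 8, 9))
  two <- cbind(row = c(15, 16), col = c(15, 16))  # diagonal: 8-connected
  px <- rbind(five, two); storage.mode(px) <- "integer"
  b <- new("BoundarySet", pixels = px, seeds = px, dim = dim(mask))
  out <- removeMarginFalseBoundaries(b, mask,
                                     detectionConfig(marginPx = 2,
                                                     minBoundaryPx = 3))
  expect_equal(pixelKeys(boundaryPixels(out)), pixelKeys(five))
  expect_equal(pixelKeys(boundarySeeds(out)), pixelKeys(five))
  # filters are independently switchable: margin 0 keeps border pixels
  out0 <- removeMarginFalseBoundaries(b, mask,
                                      detectionConfig(marginPx = 0,
                                                      minBoundaryPx = 1))
  expect_equal(nrow(boundaryPixels(out0)), nrow(px))
  # empty in, empty out
  e <- markBoundaries(makeStateImage(matrix(1L, 4, 4), 4L),
                      transitionModel(0.8, 3))
  expect_equal(nrow(boundaryPixels(
    removeMarginFalseBoundaries(e, matrix(TRUE, 4, 4)))), 0L)
})

test_that("growth fraction zero yields the seeds alone", {
  set.seed(33)
  img <- matrix(runif(100), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  si <- stretchAndQuantize(img, mask, nStates = 5)
  seeds <- cbind(row = c(3L, 8L), col = c(3L, 8L))
  b <- new("BoundarySet", pixels = seeds, seeds = seeds, dim = dim(mask))
  lm <- growRegions(img, si, b, mask,
                    detectionConfig(growthFraction = 0))
  expect_equal(sum(lesionMatrix(lm)), 2L)
  expect_true(all(lesionMatrix(lm)[seeds]))
})

test_that("a uniform bright disc is recovered exactly by the degenerate rule", {
  nr <- 31; nc <- 31
  img <- matrix(0.2, nr, nc)
  disc <- (row(img) - 16)^2 + (col(img) - 16)^2 <= 16
  img[disc] <- 1.0
  mask <- matrix(TRUE, nr, nc)
  si <- stretchAndQuantize(img, mask, nStates = 5,
                           clipPercentiles = c(0, 100))
  seeds <- cbind(row = 16L, col = 16L)
  b <- new("BoundarySet", pixels = seeds, seeds = seeds, dim = dim(img))
  lm <- growRegions(stretchIntensities(img, mask,
                                       c(0, 100))$stretched,
                    si, b, mask, detectionConfig(growthFraction = 0.5))
  # sd inside the disc is 0: state-equality acceptance grows the disc and
  # nothing else
  expect_identical(lesionMatrix(lm), disc)
})

test_that("two seeds inside one lesion merge into a single component", {
  img <- matrix(0.2, 21, 21)
  disc <- (row(img) - 11)^2 + (col(img) - 11)^2 <= 9
  img[disc] <- 0.9
  mask <- matrix(TRUE, 21, 21)
  si <- stretchAndQuantize(img, mask, nStates = 5, clipPercentiles = c(0, 100))
  seeds <- cbind(row = c(10L, 12L), col = c(10L, 12L))
  b <- new("BoundarySet", pixels = seeds, seeds = seeds, dim = dim(img))
  lm <- growRegions(stretchIntensities(img, mask, c(0, 100))$stretched,
                    si, b, mask, detectionConfig())
  expect_equal(nrow(componentTable(lm)), 1L)
})

test_that("the region-size cap halts growth and is reported", {
  img <- matrix(0.8, 12, 12)  # everything identical: unlimited growth
  mask <- matrix(TRUE, 12, 12)
  si <- suppressWarnings(stretchAndQuantize(img, mask, nStates = 5))
  seeds <- cbind(row = 6L, col = 6L)
  b <- new("BoundarySet", pixels = seeds, seeds = seeds, dim = dim(img))
  expect_warning(
    lm <- growRegions(matrix(0.5, 12, 12), si, b, mask,
                      detectionConfig(maxRegionPx = 10)),
    "maxRegionPx")
  expect_true(attr(lm, "capped"))
  expect_lte(sum(lesionMatrix(lm)), 11)
})

test_that("detection is deterministic and confined to the mask", {
  ph <- generatePhantom(phantomSpec(
    lesions = list(lesionSpec(c(60, 60), 4), lesionSpec(c(75, 70), 3)),
    seed = 17))
  d1 <- detectWMI(ph$image, ph$wmMask)
  d2 <- detectWMI(ph$image, ph$wmMask)
  expect_identical(lesionMatrix(d1$lesions), lesionMatrix(d2$lesions))
  expect_identical(d1$report, d2$report)
  expect_true(all(ph$wmMask[lesionMatrix(d1$lesions)]))
  expect_gte(d1$report$nComponents, 1L)
  # run report carries the resolved configuration
  expect_equal(d1$report$config$threshold, 0.01)
  expect_equal(d1$report$qSource, "estimated")
})

test_that("stage errors are reported with their stage name", {
  img <- matrix(runif(64), 8, 8)
  expect_error(detectWMI(img, matrix(FALSE, 8, 8)), "stage 'stretch'")
})

test_that("a fixed q bypasses estimation and lands in the report", {
  ph <- generatePhantom(phantomSpec(seed = 23))
  d <- detectWMI(ph$image, ph$wmMask, q = 0.8)
  expect_equal(d$report$q, 0.8)
  expect_equal(d$report$qSource, "fixed")
  expect_equal(d$report$alpha, solveAlpha(0.8, 6))
})
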