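# Distance featurisation, the max-margin classifier and the CV pair.

test_that("distance features equal the brute-force atom-pair minimum", {
  resA <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  resB <- rbind(c(7, 0, 0), c(8, 1, 0.5))
  frame <- data.frame(resno = c(1, 1, 2, 2), rbind(resA, resB))
  names(frame) <- c("resno", "x", "y", "z")
  tr <- distanceFeatures(list(frame, frame), data.frame(i = 1, j = 2))
  expect_equal(dim(distanceMatrix(tr)), c(2L, 1L))
  expect_equal(distanceMatrix(tr)[1, 1], bruteMinDist(resA, resB) / 10)
  # two single-atom residues 0.7 nm apart give a constant column
  f2 <- data.frame(resno = c(1, 2), x = c(0, 7), y = 0, z = 0)
  tr2 <- distanceFeatures(list(f2, f2, f2), data.frame(i = 1, j = 2))
  expect_equal(as.vector(distanceMatrix(tr2)), rep(0.7, 3))
  expect_error(distanceFeatures(list(f2), data.frame()), "empty")
  expect_error(distanceFeatures(list(f2), data.frame(i = 1, j = 9)),
               "missing")
})

test_that("a 1-D separable problem yields the expected coefficient sign", {
  pairs <- data.frame(i = 1, j = 2)
  A <- distanceTrajectory(matrix(0.4 + runif(20, 0, 0.01)), pairs, label = "A")
  B <- distanceTrajectory(matrix(1.0 + runif(20, 0, 0.01)), pairs, label = "B")
  m <- trainStateClassifier(A, B)
  expect_gt(coef(m)[1], 0)   # decision increases from A to B
  expect_equal(m@metadata$trainingAccuracy, 1)
})

test_that("planted informative pairs dominate the coefficient ranking", {
  ts <- sampleTwoStateTrajectory(3000, deltaU = 0, seed = 3)
  lab <- ts$stateLabels
  D <- distanceMatrix(ts$trajectory)
  pairs <- pairTable(ts$trajectory)
  A <- distanceTrajectory(D[lab == 1, ], pairs, label = "left")
  B <- distanceTrajectory(D[lab == 2, ], pairs, label = "right")
  m <- trainStateClassifier(A, B)
  expect_setequal(pairRanking(m)[1:2], ts$informativePairs)
  expect_gte(m@metadata$trainingAccuracy, 0.95)
  # swapping the ensembles negates every coefficient exactly
  m2 <- trainStateClassifier(B, A)
  expect_identical(coef(m), -coef(m2))
})

test_that("feature rescaling does not change the top-k set", {
  ts <- sampleTwoStateTrajectory(1500, deltaU = 0, seed = 5, nNoise = 20)
  lab <- ts$stateLabels
  D <- distanceMatrix(ts$trajectory)
  pairs <- pairTable(ts$trajectory)
  fit <- function(D) {
    A <- distanceTrajectory(D[lab == 1, ], pairs, label = "left")
    B <- distanceTrajectory(D[lab == 2, ], pairs, label = "right")
    trainStateClassifier(A, B)
  }
  m1 <- fit(D)
  D2 <- D
  D2[, 5] <- D2[, 5] * 7   # standardization absorbs the rescaling
  m2 <- fit(D2)
  k <- 5L
  expect_setequal(pairRanking(m1)[1:k], pairRanking(m2)[1:k])
})

test_that("the CV pair partitions top coefficients by sign", {
  pairs <- data.frame(i = c(1, 3, 5), j = c(2, 4, 6))
  m <- new("LinearStateModel",
           coefficients = setNames(c(2, -1, 1), c("1-2", "3-4", "5-6")),
           intercept = 0, scalerCenter = rep(0, 3),
           scalerScale = rep(1, 3), ranking = c(1L, 2L, 3L),
           pairs = pairs, metadata = list())
  cv <- makeCvPair(m, topK = 3)
  expect_equal(cvWeights(cv, 1)$weight, c(2 / 3, 1 / 3))
  expect_equal(cvWeights(cv, 1)$i, c(1, 5))
  expect_equal(cvWeights(cv, 2)$weight, 1)
  expect_equal(cvWeights(cv, 2)$i, 3)
  # single-pair CV (the other sign class is empty, hence the warning)
  expect_warning(cv1 <- makeCvPair(m, topK = 1), "single-CV")
  expect_equal(nrow(cvWeights(cv1, 1)), 1L)
  # all-positive coefficients leave CV_2 empty with a warning
  mp <- new("LinearStateModel",
            coefficients = setNames(c(2, 1, 1), c("1-2", "3-4", "5-6")),
            intercept = 0, scalerCenter = rep(0, 3),
            scalerScale = rep(1, 3), ranking = c(1L, 2L, 3L),
            pairs = pairs, metadata = list())
  expect_warning(cvp <- makeCvPair(mp, topK = 3), "CV_2 is empty")
  expect_equal(nrow(cvWeights(cvp, 2)), 0L)
})

test_that("CV evaluation is the weighted sum and is monotone", {
  pairs <- data.frame(i = c(1, 3, 5), j = c(2, 4, 6))
  D <- rbind(c(0.4, 0.6, 0.8), c(0.5, 0.7, 0.9))
  tr <- distanceTrajectory(D, pairs)
  cv <- new("CollectiveVariablePair",
            cv1 = data.frame(i = c(1, 3), j = c(2, 4),
                             weight = c(0.25, 0.75)),
            cv2 = data.frame(i = 5, j = 6, weight = 1),
            normalization = "test")
  s <- evaluateCv(tr, cv)
  expect_equal(s[, "cv1"], as.vector(D[, 1:2] %*% c(0.25, 0.75)))
  expect_equal(s[, "cv2"], D[, 3])
  # single pair with weight 1 reproduces that distance column exactly
  cvOne <- new("CollectiveVariablePair",
               cv1 = data.frame(i = 1, j = 2, weight = 1),
               cv2 = data.frame(i = integer(0), j = integer(0),
                                weight = numeric(0)),
               normalization = "test")
  expect_equal(evaluateCv(tr, cvOne, which = 1L)[, 1], D[, 1])
  # linearity: doubling all distances doubles the CV
  tr2 <- distanceTrajectory(2 * D, pairs)
  expect_equal(evaluateCv(tr2, cv), 2 * s)
  # monotone: increasing any constituent distance never lowers the CV
  for (p in 1:2) {
    Dp <- D
    Dp[, p] <- Dp[, p] + 0.1
    sp <- evaluateCv(distanceTrajectory(Dp, pairs), cv)
    expect_true(all(sp[, "cv1"] >= s[, "cv1"]))
  }
  # missing pair is an error
  cvBad <- new("CollectiveVariablePair",
               cv1 = data.frame(i = 9, j = 10, weight = 1),
               cv2 = data.frame(i = integer(0), j = integer(0),
                                weight = numeric(0)),
               normalization = "test")
  expect_error(evaluateCv(tr, cvBad, which = 1L), "missing")
})

test_that("CV definitions survive a JSON round trip", {
  cv <- new("CollectiveVariablePair",
            cv1 = data.frame(i = c(1, 3), j = c(2, 4),
                             weight = c(0.25, 0.75)),
            cv2 = data.frame(i = 5, j = 6, weight = 1),
            normalization = "test")
  f <- tempfile(fileext = ".json")
  writeCv(cv, f)
  cv2 <- readCv(f)
  expect_equal(cvWeights(cv2, 1), cvWeights(cv, 1))
  expect_equal(cvWeights(cv2, 2), cvWeights(cv, 2))
})
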