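# Free-energy surfaces, projections, basins, populations, couplings.

rt <- thermalRT()

test_that("histogram free energies follow -RT log p with anchoring", {
  # uniform counts: all bins at zero
  u <- frameFreeEnergy(rep(c(.125, .375, .625, .875), 25),
                       breaks = c(0, .25, .5, .75, 1))
  expect_equal(as.vector(binEnergies(u)), rep(0, 4))
  # 75/25 split: closed-form gap RT log 3
  u2 <- frameFreeEnergy(c(rep(0.25, 75), rep(0.75, 25)),
                        breaks = c(0, 0.5, 1))
  expect_equal(diff(as.vector(binEnergies(u2))), rt * log(3),
               tolerance = 1e-12)
  expect_equal(min(binEnergies(u2)), 0)
  # single visited bin: zero there, masked elsewhere
  u3 <- frameFreeEnergy(rep(0.1, 10), breaks = c(0, 0.2, 0.4, 0.6))
  expect_equal(as.vector(binEnergies(u3)), c(0, NA, NA))
  # frames outside the range: error, or clamped under the flag
  expect_error(frameFreeEnergy(c(0.1, 2), breaks = c(0, 0.5, 1)),
               "outside")
  uc <- frameFreeEnergy(c(0.1, 2), breaks = c(0, 0.5, 1), clamp = TRUE)
  expect_equal(as.vector(binCounts(uc)), c(1, 1))
})

test_that("identity projection reproduces the source surface", {
  set.seed(8)
  x <- c(rnorm(400, 0.5, 0.08), rnorm(100, 0.9, 0.05))
  fes <- frameFreeEnergy(x, breaks = 30)
  back <- projectFes(fes, x, x, breaks = binEdges(fes)[[1]])
  expect_lt(max(abs(binEnergies(fes) - binEnergies(back)), na.rm = TRUE),
            1e-10)
  expect_identical(is.na(binEnergies(fes)), is.na(binEnergies(back)))
})

test_that("projection equals the brute-force reweighting on a toy input", {
  x <- c(0.1, 0.1, 0.3, 0.3, 0.3, 0.5, 0.5, 0.7, 0.9, 0.9)
  y <- c(1.0, 1.2, 1.1, 1.4, 1.4, 1.9, 1.8, 1.9, 1.1, 1.0)
  xe <- seq(0, 1, 0.2)
  ye <- seq(0.9, 2.1, 0.3)
  fes <- frameFreeEnergy(x, breaks = xe)
  prj <- projectFes(fes, x, y, breaks = ye)
  # brute force: per-frame weight = exp(-U_frame/RT)/bin count, then
  # -RT log of the per-Y-bin weight sum, anchored
  ux <- as.vector(binEnergies(fes))
  xb <- findInterval(x, xe, rightmost.closed = TRUE)
  cnt <- tabulate(xb, length(xe) - 1)
  w <- exp(-ux[xb] / rt) / cnt[xb]
  w <- w / sum(w)
  yb <- findInterval(y, ye, rightmost.closed = TRUE)
  wsum <- vapply(seq_len(length(ye) - 1),
                 function(b) sum(w[yb == b]), numeric(1))
  expected <- -rt * log(wsum)
  expected <- expected - min(expected[is.finite(expected)])
  got <- as.vector(binEnergies(prj))
  expect_equal(got[is.finite(expected)], expected[is.finite(expected)],
               tolerance = 1e-12)
  # constant observable: one visited bin at exactly zero
  cst <- projectFes(fes, x, rep(1, 10), breaks = c(0.5, 1.5, 2.5))
  expect_equal(as.vector(binEnergies(cst)), c(0, NA))
})

test_that("total thermodynamic weight is conserved across projections", {
  set.seed(9)
  x <- runif(2000)
  fes <- frameFreeEnergy(x, breaks = 25)
  w <- frameWeights(fes, x)
  expect_equal(sum(w), 1, tolerance = 1e-10)
  # any regrouping of the same weights conserves the total mass
  y <- sin(7 * x)
  yb <- findInterval(y, seq(-1, 1, length.out = 11),
                     rightmost.closed = TRUE)
  expect_equal(sum(tapply(w, yb, sum)), 1, tolerance = 1e-10)
})

test_that("basins: single well, double well, and the 3-bin rule", {
  # discretized parabola: one basin covering every bin
  z <- seq(-1, 1, length.out = 41)
  para <- frameFreeEnergy(rep(z, times = round(1000 * exp(-8 * z^2)) + 1),
                          breaks = 20)
  bp <- detectBasins(para)
  expect_equal(nrow(basinTable(bp)), 1L)
  expect_equal(sum(!is.na(basinLabels(bp))),
               sum(is.finite(binEnergies(para))))
  # symmetric double well: two basins split at the barrier
  set.seed(10)
  x <- c(rnorm(5000, -1, 0.25), rnorm(5000, 1, 0.25))
  dw <- frameFreeEnergy(x, breaks = 30)
  b2 <- detectBasins(dw)
  expect_equal(nrow(basinTable(b2)), 2L)
  pops <- basinPopulations(dw, b2)
  expect_equal(sum(pops), 1)
  expect_equal(pops[1], 0.5, tolerance = 0.05)
  # the two basin minima flank the barrier
  ctr <- binCenters(dw)[[1]]
  expect_lt(ctr[basinTable(b2)$minBin[1]] *
            ctr[basinTable(b2)$minBin[2]], 0)
})

test_that("sub-minimum-size dips are discarded", {
  # construct a surface with a genuine well and a 2-bin dip
  u <- c(5, 3, 1, 0, 1.2, 2.5, 3.6, 3.4, 3.9, 4.8)
  cnt <- round(exp(-u / rt) * 1e6) + 1
  xs <- rep(seq(0.05, 0.95, 0.1), times = cnt)
  fes <- frameFreeEnergy(xs, breaks = seq(0, 1, 0.1))
  expect_equal(order(as.vector(binEnergies(fes)))[1], 4L)
  b <- detectBasins(fes, minBins = 3)
  tab <- basinTable(b)
  # the 2-bin dip at bin 8 is not a basin
  expect_false(any(tab$minBin == 8))
  expect_true(any(tab$minBin == 4))
})

test_that("mirrored wells offset by RT log 2 split populations 2:1", {
  # build counts that realize the analytic profile exactly
  z <- seq(-1.5, 1.5, length.out = 60)
  uTrue <- 8 * (z^2 - 1)^2 + rt * log(2) * (z > 0)
  p <- exp(-uTrue / rt)
  cnt <- round(p / sum(p) * 2e6)
  xs <- rep(z, times = cnt)
  fes <- frameFreeEnergy(xs, breaks = seq(-1.525, 1.525,
                                          length.out = 61))
  b <- detectBasins(fes)
  pops <- sort(basinPopulations(fes, b), decreasing = TRUE)
  expect_equal(pops[1], 2 / 3, tolerance = 0.01)
  expect_equal(pops[2], 1 / 3, tolerance = 0.01)
})

test_that("energetic coupling is the barrier-to-basin gap", {
  mk <- function(u) {
    new("FreeEnergySurface", dimension = 1L,
        edges = list(seq(0, length(u)) / length(u)),
        energy = array(u - min(u)), counts = array(rep(1, length(u))),
        rt = rt)
  }
  # monotonic and flat surfaces couple to 0
  expect_equal(energeticCoupling(mk(1:8)), 0)
  expect_equal(energeticCoupling(mk(rep(2, 8))), 0)
  # double well: minima at 0 and 2, barrier at 5
  expect_equal(energeticCoupling(mk(c(6, 0, 2, 5, 2.5, 2, 4))), 5)
  # single well
  expect_equal(energeticCoupling(mk(c(4, 2, 0, 2, 4))), 0)
})

test_that("2-D surfaces detect basins and positional sub-labels", {
  set.seed(12)
  xy <- rbind(cbind(rnorm(4000, 0.55, 0.04), rnorm(4000, 0.45, 0.04)),
              cbind(rnorm(2000, 1.15, 0.04), rnorm(2000, 0.85, 0.04)))
  fes <- frameFreeEnergy(xy, breaks = list(25L, 25L),
                         range = list(c(0.4, 1.3), c(0.3, 1.0)))
  b <- detectBasins(fes)
  expect_gte(nrow(basinTable(b)), 2L)
  b <- subLabelBasins(fes, b)
  tab <- basinTable(b)
  major <- order(-tab$population)[1:2]
  expect_setequal(tab$subLabel[major], c("A1", "R"))
})

test_that("surfaces survive the TSV round trip", {
  set.seed(13)
  x <- rnorm(500, 0.8, 0.2)
  fes <- frameFreeEnergy(x, breaks = 15, clamp = TRUE)
  f <- tempfile(fileext = ".tsv")
  writeFes(fes, f)
  back <- readFes(f)
  expect_equal(binEnergies(back), binEnergies(fes))
  expect_equal(binEdges(back), binEdges(fes))
  expect_equal(surfaceRT(back), surfaceRT(fes))
})

test_that("marker-helix RMSD classification matches an independent fit", {
  ref <- data.frame(resno = 1:40, x = (1:40) * 1.5,
                    y = rep(c(0, 0.4), 20), z = 0)
  # frames rigidly displaced: active (RMSD 0 after superposition)
  fr1 <- ref
  fr1$x <- fr1$x + 4; fr1$y <- fr1$y - 2
  cls <- classifyBasinState(list(ref, fr1), ref, rmsdResidues = 30:40)
  expect_equal(cls$meanRmsd, 0, tolerance = 1e-8)
  expect_equal(cls$state, "active")
  # helix locally displaced by 5 A after alignment on the rest
  fr2 <- ref
  fr2$z[30:40] <- fr2$z[30:40] + 5
  cls2 <- classifyBasinState(list(fr2), ref, rmsdResidues = 30:40,
                             alignResidues = 1:29)
  expect_equal(cls2$meanRmsd, 5)
  expect_equal(cls2$state, "resting")
  # independent oracle: bio3d superposition on the alignment selection
  P <- as.matrix(fr2[, c("x", "y", "z")])
  Q <- as.matrix(ref[, c("x", "y", "z")])
  xyzP <- as.vector(t(P)); xyzQ <- as.vector(t(Q))
  idx <- bio3d::atom2xyz(1:29)
  fitted <- bio3d::fit.xyz(xyzQ, xyzP, fixed.inds = idx,
                           mobile.inds = idx)
  rmsdOracle <- bio3d::rmsd(xyzQ, fitted,
                            a.inds = bio3d::atom2xyz(30:40),
                            b.inds = bio3d::atom2xyz(30:40))
  expect_equal(cls2$meanRmsd, rmsdOracle, tolerance = 1e-6)
  # a mean RMSD exactly at the cutoff is resting (strict "below")
  fr3 <- ref
  fr3$z[30:40] <- fr3$z[30:40] + 3.0
  cls3 <- classifyBasinState(list(fr3), ref, rmsdResidues = 30:40,
                             alignResidues = 1:29)
  expect_equal(cls3$meanRmsd, 3.0)
  expect_equal(cls3$state, "resting")
  # empty selection errors
  expect_error(classifyBasinState(list(fr3), ref,
                                  rmsdResidues = 200:210),
               "empty")
})
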