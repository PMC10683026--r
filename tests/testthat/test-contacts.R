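# Contact maps, false-positive detection, clustering and pull coordinates.

test_that("contact map equals the brute-force atom-pair minimum", {
  res <- list(
    rbind(c(0, 0, 0), c(1.2, 0.3, 0), c(0.5, 1.0, 0.2)),
    rbind(c(4.0, 0, 0), c(5.1, 0.8, 0.4)),
    rbind(c(0, 9, 0), c(0.5, 10, 0.3), c(1.2, 9.4, 0)))
  f <- writeMultiAtomPdb(res)
  cmap <- contactMap(f, cutoff = 5.5, minSeqSep = 0)
  D <- distanceMatrix(cmap)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(D[i, j], bruteMinDist(res[[i]], res[[j]]),
                 tolerance = 1e-3)
  expect_identical(D, t(D))
})

test_that("contact rules: cutoff and sequence separation", {
  pdb <- makeToyStructure(7, contacts = rbind(c(1, 6)), contactDist = 3)
  cm <- contactMap(pdb, cutoff = 5.5, minSeqSep = 0)
  expect_true(contactMatrix(cm)[1, 6])
  # adjacent residues are never contacts under a separation filter,
  # whatever their distance
  cm5 <- contactMap(pdb, cutoff = 30, minSeqSep = 5)
  expect_false(any(contactMatrix(cm5)[cbind(1:6, 2:7)]))
  expect_true(contactMatrix(cm5)[1, 6])
})

test_that("alignment-to-structure mapping handles identity and offsets", {
  seqq <- "ACDEFGHIKL"
  pdb <- makeToyStructure(10, sequence = seqq)
  msa <- msaFromStrings(c(seqq, "ACDEFGHIKV"), ids = c("q", "other"))
  mp <- mapAlignmentToStructure(msa, "q", pdb)
  expect_equal(mp$resIdx, 1:10)
  # structure missing the 3 N-terminal residues: those columns unmapped
  pdbTrunc <- makeToyStructure(7, sequence = substr(seqq, 4, 10))
  mpT <- mapAlignmentToStructure(msa, "q", pdbTrunc)
  expect_true(all(is.na(mpT$resIdx[1:3])))
  expect_equal(mpT$resIdx[4:10], 1:7)
  # query absent from the MSA
  expect_error(mapAlignmentToStructure(msa, "nope", pdb), "not found")
  # gapped query columns are unmapped
  msaG <- msaFromStrings(c("AC-DEFGHIKL", "ACWDEFGHIKV"),
                         ids = c("q", "other"))
  pdb2 <- makeToyStructure(10, sequence = seqq)
  mpG <- mapAlignmentToStructure(msaG, "q", pdb2)
  expect_true(is.na(mpG$resIdx[3]))
  expect_equal(sum(!is.na(mpG$resIdx)), 10)
})

test_that("false positives are exactly the high-scoring non-contacts", {
  # planted fixture: 12 residues, contacts (1,7), (2,9); scores put
  # (1,7) [contact], (3,11) and (2,10) [non-contacts] on top
  pdb <- makeToyStructure(12, contacts = rbind(c(1, 7), c(2, 9)))
  cmap <- contactMap(pdb, cutoff = 5.5, minSeqSep = 5)
  L <- 12
  s <- matrix(0.01, L, L)
  s[1, 7] <- s[7, 1] <- 0.9
  s[3, 11] <- s[11, 3] <- 0.8
  s[2, 10] <- s[10, 2] <- 0.7
  diag(s) <- 0
  coevo <- new("CoevolutionMap", scores = s, apcApplied = TRUE,
               columnMap = seq_len(L))
  fp <- detectFalsePositives(coevo, cmap, topNPairs = 3)
  tab <- pairTable(fp)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$i, c(3L, 2L))     # sorted by decreasing score
  expect_equal(tab$j, c(11L, 10L))
  expect_true(all(tab$distance > 5.5))
  # none of the detected pairs is ever a structural contact
  expect_false(any(contactMatrix(cmap)[cbind(tab$i, tab$j)]))
})

test_that("mean shift picks the cluster count and K-means assigns", {
  fp <- new("FalsePositivePairs",
            pairs = data.frame(i = 1:15, j = 21:35, resnoI = 1:15,
                               resnoJ = 21:35, column_i = 1:15,
                               column_j = 21:35,
                               score = rep(c(0.1, 0.5, 0.9), each = 5),
                               distance = 10),
            metadata = list())
  cl <- pairTable(clusterFalsePositives(fp, seed = 1))$cluster
  expect_equal(length(unique(cl)), 3L)
  # cluster 1 is the strongest-coupling group; grouping matches scores
  expect_equal(cl, rep(c(3L, 2L, 1L), each = 5))
  # identical scores collapse to a single cluster
  fp1 <- fp
  fp1@pairs$score <- 0.5
  expect_warning(c1 <- clusterFalsePositives(fp1, seed = 1), NA)
  expect_equal(unique(pairTable(c1)$cluster), 1L)
  # determinism and permutation invariance
  clA <- pairTable(clusterFalsePositives(fp, seed = 7))$cluster
  clB <- pairTable(clusterFalsePositives(fp, seed = 7))$cluster
  expect_identical(clA, clB)
  perm <- sample(15)
  fpP <- fp
  fpP@pairs <- fp@pairs[perm, ]
  clP <- pairTable(clusterFalsePositives(fpP, seed = 7))$cluster
  expect_identical(clP, clA[perm])
})

test_that("pull coordinates are score-weighted means with unit weights", {
  fp <- new("FalsePositivePairs",
            pairs = data.frame(i = c(1, 2, 3), j = c(11, 12, 13),
                               resnoI = c(1, 2, 3), resnoJ = c(11, 12, 13),
                               column_i = 1:3, column_j = 11:13,
                               score = c(0.5, 0.5, 0.9), distance = 12,
                               cluster = c(1L, 1L, 2L)),
            metadata = list())
  pcs <- buildPullCoordinates(fp)
  for (cl in pcs@clusters) expect_equal(sum(cl$weight), 1)
  # two equal-score pairs at 0.4 and 0.8 nm -> 0.6 nm; single pair -> itself
  d <- c("1-11" = 0.4, "2-12" = 0.8, "3-13" = 0.55)
  vals <- evaluatePullCoordinates(pcs, d)
  expect_equal(vals, c(0.6, 0.55))
  # duplicate listing of a pair does not change the coordinate
  fpDup <- fp
  fpDup@pairs <- rbind(fp@pairs, fp@pairs[1, ])
  valsDup <- evaluatePullCoordinates(buildPullCoordinates(fpDup), d)
  expect_equal(valsDup, vals)
  # defaults and argument checking
  expect_equal(pcs@forceConstant, 200)
  expect_equal(pcs@target, 0.2)
  expect_error(buildPullCoordinates(fp, forceConstant = -1), "positive")
  expect_error(buildPullCoordinates(fp, target = 0), "positive")
})

test_that("uniform-weight mode reproduces the plain intracluster mean", {
  fp <- new("FalsePositivePairs",
            pairs = data.frame(i = 1:2, j = 11:12, resnoI = 1:2,
                               resnoJ = 11:12, column_i = 1:2,
                               column_j = 11:12, score = c(0.9, 0.1),
                               distance = 12, cluster = 1L),
            metadata = list())
  d <- c("1-11" = 0.4, "2-12" = 0.8)
  weighted <- evaluatePullCoordinates(buildPullCoordinates(fp), d)
  uniform <- evaluatePullCoordinates(
    buildPullCoordinates(fp, uniformWeights = TRUE), d)
  expect_equal(uniform, 0.6)
  expect_equal(weighted, 0.4 * 0.9 + 0.8 * 0.1)
})

test_that("MD config exports the adaptive-bias defaults and round-trips", {
  txt <- exportMdConfig(awh = awhDefaults("apo"))
  kv <- parseMdConfig(txt)
  expect_equal(as.numeric(kv[["awh1-dim1-cover-diameter"]]), 0.4)
  expect_equal(as.numeric(kv[["awh1-energy-cutoff"]]), 120)
  expect_equal(as.numeric(kv[["awh1-growth-factor"]]), 2.0)
  expect_equal(as.numeric(kv[["awh-nstsample"]]), 10)
  expect_equal(as.numeric(kv[["awh-nsamples-update"]]), 10)
  # per-condition rows from the packaged defaults table
  expect_equal(as.numeric(kv[["awh1-dim1-force-constant"]]), 10000)
  expect_equal(as.numeric(kv[["awh1-dim1-diffusion"]]), 0.001)
  bi <- parseMdConfig(exportMdConfig(awh = awhDefaults("BI-167107")))
  expect_equal(as.numeric(bi[["awh1-dim2-diffusion"]]), 0.005)
  # CV ranges
  expect_equal(as.numeric(kv[["awh1-dim1-start"]]), 0.4)
  expect_equal(as.numeric(kv[["awh1-dim1-end"]]), 1.3)
  expect_equal(as.numeric(kv[["awh1-dim2-start"]]), 0.3)
  expect_equal(as.numeric(kv[["awh1-dim2-end"]]), 1.0)
  # byte-identical round trip, also with a pull section
  expect_identical(txt, reexportMdConfig(parseMdConfig(txt)))
  fp <- new("FalsePositivePairs",
            pairs = data.frame(i = 1:2, j = 11:12, resnoI = 1:2,
                               resnoJ = 11:12, column_i = 1:2,
                               column_j = 11:12, score = c(0.9, 0.1),
                               distance = 12, cluster = c(1L, 2L)),
            metadata = list())
  txt2 <- exportMdConfig(buildPullCoordinates(fp), awhDefaults("apo"))
  expect_identical(txt2, reexportMdConfig(parseMdConfig(txt2)))
  expect_error(exportMdConfig(awh = awhDefaults("apo"), dialect = "x"),
               "dialect")
  expect_error(awhDefaults("unknown-ligand"), "condition")
})
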