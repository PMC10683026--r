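# Energetic-coupling networks: paths, centrality, condition PCA.

test_that("path and centrality basics on canonical graphs", {
  # path graph A-B-C
  net <- couplingNetwork(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    coupling = c(2, 1)))
  p <- shortestCouplingPaths(net, "A", c("C", "A"))
  expect_equal(p$C$path, c("A", "B", "C"))
  expect_equal(p$A$cost, 0)
  expect_equal(p$A$path, character(0))
  # middle node carries all traffic
  bw <- couplingBetweenness(net)
  expect_equal(unname(bw["B"]), 1)
  expect_equal(unname(bw[c("A", "C")]), c(0, 0))
  # star graph: hub 1, leaves 0
  st <- couplingNetwork(data.frame(from = "h", to = paste0("l", 1:4),
                                   coupling = 1))
  bs <- couplingBetweenness(st)
  expect_equal(unname(bs["h"]), 1)
  expect_equal(unname(bs[paste0("l", 1:4)]), rep(0, 4))
  # unreachable sink
  iso <- couplingNetwork(data.frame(from = "A", to = "B", coupling = 1),
                         nodes = c("A", "B", "Z"))
  pz <- shortestCouplingPaths(iso, "A", "Z")
  expect_false(pz$Z$reachable)
  expect_equal(pz$Z$cost, Inf)
  expect_equal(unname(couplingBetweenness(iso)["Z"]), 0)
  expect_error(shortestCouplingPaths(net, "A", "nope"), "unknown")
})

test_that("Dijkstra and betweenness match brute-force enumeration", {
  for (seed in 1:100) {
    n <- sample(4:8, 1)
    net <- randomCouplingGraph(n, seed)
    nodes <- networkNodes(net)
    src <- nodes[1]
    snk <- nodes[n]
    got <- shortestCouplingPaths(net, src, snk)[[snk]]
    ref <- bruteShortestPath(net, src, snk)
    expect_equal(got$cost, ref$cost, tolerance = 1e-9)
    expect_equal(got$path, ref$path)
    if (seed <= 25) {   # centrality enumeration is the expensive oracle
      expect_equal(couplingBetweenness(net), bruteBetweenness(net),
                   tolerance = 1e-9)
    }
  }
})

test_that("strengthening an edge never lengthens any shortest path", {
  for (seed in c(3, 11, 27)) {
    net <- randomCouplingGraph(6, seed)
    e <- networkEdges(net)
    base <- shortestCouplingPaths(net, networkNodes(net)[1],
                                  networkNodes(net))
    e2 <- e
    pick <- (seed %% nrow(e)) + 1
    e2$coupling[pick] <- e2$coupling[pick] * 10
    net2 <- couplingNetwork(e2[, c("from", "to", "coupling")],
                            nodes = networkNodes(net))
    after <- shortestCouplingPaths(net2, networkNodes(net)[1],
                                   networkNodes(net))
    for (s in names(base))
      expect_lte(after[[s]]$cost, base[[s]]$cost + 1e-12)
  }
})

test_that("path costs are invariant under node relabelling", {
  net <- randomCouplingGraph(7, 42)
  e <- networkEdges(net)
  perm <- setNames(sample(letters[1:7]), networkNodes(net))
  e2 <- data.frame(from = unname(perm[e$from]), to = unname(perm[e$to]),
                   coupling = e$coupling)
  net2 <- couplingNetwork(e2)
  src <- networkNodes(net)[2]; snk <- networkNodes(net)[6]
  a <- shortestCouplingPaths(net, src, snk)[[snk]]
  b <- shortestCouplingPaths(net2, unname(perm[src]),
                             unname(perm[snk]))[[unname(perm[snk])]]
  expect_equal(a$cost, b$cost)
  expect_equal(unname(perm[a$path]), b$path)
})

test_that("trajectory-derived networks find the two-state pair", {
  # 3 residues -> 3 pairs; only pair (1,2) switches between two distance
  # states coupled to the sampled coordinate
  ts <- sampleTwoStateTrajectory(20000, deltaU = 0, seed = 21,
                                 nInformative = 1, nNoise = 0)
  z <- ts$latent
  D <- cbind(distanceMatrix(ts$trajectory)[, 1],
             0.45 + runif(length(z), 0, 0.02),
             0.50 + runif(length(z), 0, 0.02))
  traj <- distanceTrajectory(D, data.frame(i = c(1, 1, 2),
                                           j = c(2, 3, 3)))
  cvs <- D[, 1]
  fes <- frameFreeEnergy(cvs, breaks = 40)
  net <- buildCouplingNetwork(traj, fes, cvs, breaks = 40)
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$from, e$to), c("1", "2"))
  expect_gt(e$coupling, 0)
  # all-monocentric trajectories give an empty network with a warning
  Dflat <- D[, 2:3]
  tf <- distanceTrajectory(Dflat, data.frame(i = c(1, 2), j = c(3, 3)))
  expect_warning(
    net0 <- buildCouplingNetwork(tf, fes, cvs, breaks = 40),
    "empty")
  expect_equal(nrow(networkEdges(net0)), 0L)
})

test_that("condition PCA separates along a planted direction", {
  base <- data.frame(from = as.character(1:6), to = as.character(7:12),
                     coupling = 5)
  dirv <- seq(0.1, 0.6, 0.1)
  nets <- lapply(c(0.2, 0.5, 1.0, 2.0), function(a) {
    e <- base
    e$coupling <- 5 + a * dirv
    couplingNetwork(e)
  })
  names(nets) <- paste0("cond", 1:4)
  pc <- conditionPca(nets, mode = "pair")
  expect_gt(pc$varianceExplained[1], 0.999)
  expect_true(all(pc$varianceExplained >= 0))
  expect_lte(sum(pc$varianceExplained), 1 + 1e-12)
  # PC1 loading is collinear with the planted direction
  key <- paste(pmin(base$from, base$to), pmax(base$from, base$to),
               sep = "|")
  v <- pc$loadings[match(key, pc$features), 1]
  cosine <- abs(sum(v * dirv)) / sqrt(sum(v^2) * sum(dirv^2))
  expect_gt(cosine, 0.99)
  # identical conditions: zero variance, coincident scores
  same <- conditionPca(list(a = nets[[1]], b = nets[[1]]))
  expect_equal(sum(same$varianceExplained), 0)
  expect_equal(same$scores[1, ], same$scores[2, ])
  expect_error(conditionPca(nets[1]), "two conditions")
})

test_that("networks export as edge lists", {
  net <- couplingNetwork(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    coupling = c(2, 1)))
  f <- tempfile(fileext = ".tsv")
  writeNetwork(net, f)
  back <- read.delim(f)
  expect_equal(back$coupling, c(2, 1))
  expect_equal(back$cost, 1 / (c(2, 1) + 1e-6))
})
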