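## Residue-level energetic-coupling networks: project the free-energy
## surface onto every eligible pair distance, take the basin-to-barrier
## coupling as the edge weight, and analyse the graph by shortest paths
## (strong coupling = cheap edge) and betweenness centrality.

.edgeCost <- function(coupling, transform, epsilon) {
  switch(transform,
         inverse = 1 / (coupling + epsilon),
         max_minus = max(coupling) - coupling + epsilon,
         stop("unknown cost transform '", transform, "'"))
}

.asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net@nodes))
  igraph::E(g)$weight <- net@edges$cost
  igraph::E(g)$coupling <- net@edges$coupling
  g
}

#' Build an energetic-coupling network from a trajectory
#'
#' For every eligible residue pair the free-energy surface is projected
#' onto that pair's distance ([projectFes()]) and the pair's edge weight
#' is the basin-to-barrier coupling of the resulting 1-D profile
#' ([energeticCoupling()]). Pairs whose profile has a single basin get
#' weight 0 and are dropped. To keep the graph from becoming a dense web
#' of noise, only pairs that actually form contacts are eligible: the
#' minimum distance must drop below `contactNm` in at least `minFraction`
#' of frames (both configurable).
#'
#' @param trajectory a [DistanceTrajectory-class] (distances in nm).
#' @param fes the converged [FreeEnergySurface-class] of the run.
#' @param cvSeries the per-frame CV series behind `fes`.
#' @param breaks bins for each pair-distance projection (default 50).
#' @param contactNm,minFraction edge-eligibility rule (defaults 0.6 nm,
#'   0.05).
#' @param minCoupling smallest coupling kept as an edge, kJ/mol
#'   (default 1 RT): profiles whose secondary minima are shallower than
#'   the thermal energy are treated as single-basin noise.
#' @param costTransform "inverse" (default): cost = 1/(coupling + eps);
#'   or "max_minus".
#' @param epsilon regularizer of the cost transform (default 1e-6).
#' @param clamp passed to the projections.
#' @return a [CouplingNetwork-class]; empty (with a warning) when no
#'   pair is eligible or all couplings are zero.
#' @export
buildCouplingNetwork <- function(trajectory, fes, cvSeries, breaks = 50L,
                                 contactNm = 0.6, minFraction = 0.05,
                                 minCoupling = thermalRT(),
                                 costTransform = c("inverse", "max_minus"),
                                 epsilon = 1e-6, clamp = FALSE) {
  stopifnot(is(trajectory, "DistanceTrajectory"),
            is(fes, "FreeEnergySurface"))
  costTransform <- match.arg(costTransform)
  D <- trajectory@distances
  eligible <- colMeans(D < contactNm) >= minFraction
  nodes <- sort(unique(c(trajectory@pairs$i, trajectory@pairs$j)))
  nodes <- as.character(nodes)
  res <- data.frame(from = character(0), to = character(0),
                    coupling = numeric(0))
  for (p in which(eligible)) {
    prof <- projectFes(fes, cvSeries, D[, p], breaks = breaks,
                       clamp = clamp)
    cpl <- energeticCoupling(prof)
    if (cpl >= minCoupling)
      res <- rbind(res, data.frame(
        from = as.character(trajectory@pairs$i[p]),
        to = as.character(trajectory@pairs$j[p]),
        coupling = cpl))
  }
  if (!nrow(res))
    warning("no eligible pair has a multi-basin distance profile; ",
            "the network is empty")
  res$cost <- if (nrow(res)) .edgeCost(res$coupling, costTransform,
                                       epsilon) else numeric(0)
  new("CouplingNetwork", edges = res, nodes = nodes,
      costTransform = costTransform, epsilon = epsilon)
}

#' Assemble a coupling network from an edge table
#'
#' Constructor used when couplings are already computed (e.g. loaded
#' from a file or produced per condition).
#'
#' @param edges data.frame with columns `from`, `to`, `coupling`.
#' @param nodes optional node universe (default: nodes seen in edges).
#' @param costTransform,epsilon see [buildCouplingNetwork()].
#' @return a [CouplingNetwork-class].
#' @export
couplingNetwork <- function(edges, nodes = NULL,
                            costTransform = c("inverse", "max_minus"),
                            epsilon = 1e-6) {
  costTransform <- match.arg(costTransform)
  edges <- as.data.frame(edges)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  edges$cost <- if (nrow(edges)) .edgeCost(edges$coupling, costTransform,
                                           epsilon) else numeric(0)
  new("CouplingNetwork", edges = edges, nodes = as.character(nodes),
      costTransform = costTransform, epsilon = epsilon)
}

#' Most efficient coupling pathways from a source to sinks
#'
#' Dijkstra shortest paths on the edge costs (strong coupling = cheap
#' edge) from one source residue to each sink. Unreachable sinks are
#' reported as such, not raised as errors.
#'
#' @param net a [CouplingNetwork-class].
#' @param source source node label.
#' @param sinks character vector of sink labels.
#' @return list with one entry per sink: `path` (node labels; empty when
#'   source == sink or unreachable), `cost` (`Inf` if unreachable),
#'   `reachable`.
#' @export
shortestCouplingPaths <- function(net, source, sinks) {
  stopifnot(is(net, "CouplingNetwork"))
  miss <- setdiff(c(source, sinks), net@nodes)
  if (length(miss))
    stop("unknown node(s): ", paste(miss, collapse = ", "))
  g <- .asIgraph(net)
  out <- lapply(sinks, function(s) {
    if (identical(s, source))
      return(list(path = character(0), cost = 0, reachable = TRUE))
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = source, to = s, weights = igraph::E(g)$weight,
      output = "both"))
    nodes <- sp$vpath[[1]]
    if (!length(nodes))
      return(list(path = character(0), cost = Inf, reachable = FALSE))
    list(path = igraph::V(g)$name[as.integer(nodes)],
         cost = sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])]),
         reachable = TRUE)
  })
  names(out) <- sinks
  out
}

#' Betweenness centrality of the coupling network
#'
#' Weighted betweenness on the same edge costs as the path analysis,
#' normalized to `[0, 1]`. Isolated nodes score 0.
#'
#' @param net a [CouplingNetwork-class].
#' @return named numeric vector over all nodes.
#' @export
couplingBetweenness <- function(net) {
  stopifnot(is(net, "CouplingNetwork"))
  if (!nrow(net@edges))
    return(stats::setNames(rep(0, length(net@nodes)), net@nodes))
  g <- .asIgraph(net)
  b <- igraph::betweenness(g, weights = igraph::E(g)$weight,
                           normalized = TRUE)
  stats::setNames(as.numeric(b), igraph::V(g)$name)[net@nodes]
}

#' Principal component analysis across simulation conditions
#'
#' Compares conditions (e.g. different bound ligands) by their coupling
#' fingerprints. Each condition's network is reduced to a per-residue
#' vector (row sums of the adjacency matrix, i.e. total coupling per
#' residue; `mode = "pair"` uses the upper-triangle per-pair vector
#' instead), vectors are aligned on the union of residues/pairs with
#' missing entries as 0, and a mean-centered PCA is computed.
#'
#' @param networks named list of [CouplingNetwork-class] objects, one
#'   per condition (at least two).
#' @param mode "residue" (default) or "pair".
#' @return list with `scores` (conditions x PCs), `varianceExplained`,
#'   `loadings` and `features`.
#' @export
conditionPca <- function(networks, mode = c("residue", "pair")) {
  mode <- match.arg(mode)
  if (length(networks) < 2L)
    stop("need at least two conditions for a PCA")
  stopifnot(all(vapply(networks, is, TRUE, "CouplingNetwork")))
  vec <- lapply(networks, function(net) {
    e <- net@edges
    if (mode == "residue") {
      v <- tapply(c(e$coupling, e$coupling), c(e$from, e$to), sum)
      stats::setNames(as.numeric(v), names(v))
    } else {
      a <- pmin(e$from, e$to)
      b <- pmax(e$from, e$to)
      stats::setNames(e$coupling, paste(a, b, sep = "|"))
    }
  })
  feats <- sort(unique(unlist(lapply(vec, names))))
  M <- t(vapply(vec, function(v) {
    out <- stats::setNames(rep(0, length(feats)), feats)
    out[names(v)] <- v
    out
  }, numeric(length(feats))))
  rownames(M) <- names(networks)
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / max(sum(p$sdev^2), .Machine$double.eps)
  list(scores = p$x, varianceExplained = ve, loadings = p$rotation,
       features = feats)
}
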