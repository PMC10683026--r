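# Shared fixtures and independent oracles, all generated in code.

# Write a small aligned FASTA and return the path.
writeFasta <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), f)
  f
}

# Same alignment in minimal Stockholm.
writeStockholm <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  f <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", paste(ids, seqs), "//"), f)
  f
}

# Multi-atom toy PDB written directly as text: residues is a list of
# n x 3 coordinate matrices (heavy atoms, Angstrom).
writeMultiAtomPdb <- function(residues, chain = "A") {
  f <- tempfile(fileext = ".pdb")
  lines <- character(0)
  serial <- 0L
  names_pool <- c("N", "CA", "C", "O", "CB", "CG")
  for (r in seq_along(residues)) {
    xyz <- residues[[r]]
    for (a in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, names_pool[a], "ALA", chain, r,
        xyz[a, 1], xyz[a, 2], xyz[a, 3],
        substr(names_pool[a], 1, 1)))
    }
  }
  writeLines(c(lines, "END"), f)
  f
}

# Brute-force minimum distance between two atom coordinate matrices.
bruteMinDist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# A random connected weighted graph with n nodes (couplings > 0).
randomCouplingGraph <- function(n, seed) {
  set.seed(seed)
  repeat {
    full <- t(combn(n, 2))
    keep <- runif(nrow(full)) < 0.55
    if (!any(keep)) next
    e <- full[keep, , drop = FALSE]
    # require connectivity via simple reachability
    adj <- matrix(FALSE, n, n)
    adj[e] <- TRUE; adj[e[, 2:1, drop = FALSE]] <- TRUE
    reach <- rep(FALSE, n); reach[1] <- TRUE
    for (k in seq_len(n)) reach <- reach | apply(adj[, reach, drop = FALSE], 1, any)
    if (all(reach)) break
  }
  couplingNetwork(data.frame(from = as.character(e[, 1]),
                             to = as.character(e[, 2]),
                             coupling = runif(nrow(e), 0.5, 5)))
}

# Exhaustive shortest path between two nodes over all simple paths.
bruteShortestPath <- function(net, source, sink) {
  e <- networkEdges(net)
  cost <- new.env()
  for (r in seq_len(nrow(e))) {
    assign(paste(e$from[r], e$to[r]), e$cost[r], envir = cost)
    assign(paste(e$to[r], e$from[r]), e$cost[r], envir = cost)
  }
  nodes <- networkNodes(net)
  best <- list(cost = Inf, path = character(0))
  recurse <- function(path, acc) {
    last <- path[length(path)]
    if (last == sink) {
      if (acc < best$cost) best <<- list(cost = acc, path = path)
      return(invisible())
    }
    for (nxt in nodes) {
      key <- paste(last, nxt)
      if (!nxt %in% path && !is.null(cost[[key]]))
        recurse(c(path, nxt), acc + cost[[key]])
    }
  }
  recurse(source, 0)
  best
}

# Brute-force normalized betweenness by enumerating all shortest paths.
bruteBetweenness <- function(net, tol = 1e-9) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  score <- setNames(rep(0, n), nodes)
  e <- networkEdges(net)
  cost <- new.env()
  for (r in seq_len(nrow(e))) {
    assign(paste(e$from[r], e$to[r]), e$cost[r], envir = cost)
    assign(paste(e$to[r], e$from[r]), e$cost[r], envir = cost)
  }
  allPaths <- function(source, sink) {
    out <- list()
    recurse <- function(path, acc) {
      last <- path[length(path)]
      if (last == sink) {
        out[[length(out) + 1L]] <<- list(path = path, cost = acc)
        return(invisible())
      }
      for (nxt in nodes) {
        key <- paste(last, nxt)
        if (!nxt %in% path && !is.null(cost[[key]]))
          recurse(c(path, nxt), acc + cost[[key]])
      }
    }
    recurse(source, 0)
    out
  }
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    ps <- allPaths(nodes[s], nodes[t])
    if (!length(ps)) next
    costs <- vapply(ps, `[[`, numeric(1), "cost")
    mn <- min(costs)
    shortest <- ps[costs <= mn + tol]
    for (p in shortest) {
      inner <- setdiff(p$path, c(nodes[s], nodes[t]))
      for (v in inner)
        score[v] <- score[v] + 1 / length(shortest)
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}
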