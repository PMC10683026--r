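## Convergence diagnostics for multi-walker adaptive-bias sampling: how
## far the realised coordinate distribution is from the (flat) target,
## whether neighbouring-bin transitions are balanced, and how many
## walkers cover each region.

#' Free-energy deviation from the target distribution
#'
#' When an adaptive bias has converged, the sampled coordinate
#' distribution should match the (usually flat) target; any residual
#' deviation translates into a free-energy error
#' `dev_i = -RT log(p_i / target_i)` per visited bin. The histogram
#' counts as equilibrated when the sampled distribution is within 80%
#' of the target; both a strict reading (`min_i p_i/target_i >= 0.8`)
#' and a mean-based one (`mean_i min(p_i/target_i, 1) >= 0.8`) are
#' reported.
#'
#' @param histogram numeric vector of per-bin visit counts, or a
#'   [WalkerHistograms-class] (walkers are pooled).
#' @param target per-bin target probabilities (default uniform); must be
#'   positive everywhere.
#' @param rt thermal energy in kJ/mol.
#' @param expectedTotal optional design total count. By default densities
#'   are normalized by the observed total; when the sampling plan
#'   prescribes a total (as adaptive-bias targets do), normalizing by it
#'   instead measures each bin against the plan, so a bin at half its
#'   expected share deviates by exactly RT log 2.
#' @return list with `deviation` (kJ/mol per bin, `NA` for unvisited
#'   bins), `ratio` (p/target), `equilibrated` (strict flag),
#'   `equilibratedMean`, `minRatio`, `meanRatio`.
#' @examples
#' flatnessDeviation(c(1, 1, 1, 1))$deviation   # exactly flat: all zero
#' @export
flatnessDeviation <- function(histogram, target = NULL, rt = thermalRT(),
                              expectedTotal = NULL) {
  if (is(histogram, "WalkerHistograms")) {
    if (is.null(target)) target <- histogram@target
    histogram <- colSums(histogram@counts)
  }
  stopifnot(is.numeric(histogram), all(histogram >= 0))
  tot <- if (is.null(expectedTotal)) sum(histogram) else expectedTotal
  if (sum(histogram) <= 0 || tot <= 0) stop("histogram has no counts")
  n <- length(histogram)
  if (is.null(target)) target <- rep(1 / n, n)
  if (length(target) != n) stop("target must have one entry per bin")
  if (any(target <= 0)) stop("target distribution has zero/negative bins")
  target <- target / sum(target)
  p <- histogram / tot
  ratio <- p / target
  dev <- rep(NA_real_, n)
  vis <- histogram > 0
  dev[vis] <- -rt * log(ratio[vis])
  capped <- pmin(ratio, 1)
  ## tiny cushion so the inclusive 80% boundary survives rounding
  list(deviation = dev, ratio = ratio,
       equilibrated = min(ratio) >= 0.8 - 1e-12,
       equilibratedMean = mean(capped) >= 0.8 - 1e-12,
       minRatio = min(ratio), meanRatio = mean(capped))
}

#' Transition imbalance between neighbouring bins
#'
#' Counts directed transitions `n_ij` between neighbouring bins along a
#' binned trajectory and reports the imbalance
#' `|n_ij - n_ji| / (n_ij + n_ji)` per traversed edge. Balanced
#' forward/backward traffic (imbalance near 0) indicates local
#' equilibrium; systematically one-way edges flag poorly converged
#' regions. Non-neighbour jumps are counted separately, not as edges.
#'
#' @param binSeries integer vector of per-frame bin indices (1-D grid),
#'   or a 2-column matrix of grid coordinates (4-connected neighbours).
#' @return list with `edges` (data.frame `from`, `to`, `nForward`,
#'   `nBackward`, `imbalance`), `nTransitions` (= frames - 1), `nSelf`
#'   (frame pairs staying in the same bin) and `nNonNeighbour`.
#' @export
transitionImbalance <- function(binSeries) {
  if (is.matrix(binSeries) && ncol(binSeries) == 2L) {
    key <- paste(binSeries[, 1], binSeries[, 2], sep = ",")
    isNb <- function(a, b) sum(abs(binSeries[a, ] - binSeries[b, ])) == 1L
  } else {
    binSeries <- as.integer(binSeries)
    key <- as.character(binSeries)
    isNb <- function(a, b) abs(binSeries[a] - binSeries[b]) == 1L
  }
  n <- length(key)
  stopifnot(n >= 2L)
  from <- key[-n]
  to <- key[-1]
  moved <- from != to
  nbr <- vapply(which(moved), function(t) isNb(t, t + 1L), logical(1))
  f <- from[moved][nbr]
  t2 <- to[moved][nbr]
  ## canonical undirected edge key
  a <- pmin(f, t2)
  b <- pmax(f, t2)
  ekey <- paste(a, b, sep = "|")
  fwd <- tapply(f == a, ekey, sum)
  bwd <- tapply(f != a, ekey, sum)
  uk <- names(fwd)
  parts <- strsplit(uk, "|", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 2L),
    nForward = as.integer(fwd),
    nBackward = as.integer(bwd))
  edges$imbalance <- abs(edges$nForward - edges$nBackward) /
    (edges$nForward + edges$nBackward)
  rownames(edges) <- NULL
  list(edges = edges, nTransitions = n - 1L,
       nSelf = sum(!moved),
       nNonNeighbour = sum(moved) - sum(nbr))
}

#' Walker overlap per bin
#'
#' For each bin, the number of walkers whose own normalized density
#' exceeds 10% of the across-walker mean density at that bin (strict
#' inequality). Full overlap (= number of walkers) everywhere means all
#' walkers sample the shared target consistently. Walkers without any
#' counts are excluded with a warning.
#'
#' @param walkers a [WalkerHistograms-class] or a walkers x bins count
#'   matrix.
#' @param fraction overlap threshold as a fraction of the mean density
#'   (default 0.1).
#' @return integer vector, one count per bin.
#' @export
walkerOverlap <- function(walkers, fraction = 0.1) {
  counts <- if (is(walkers, "WalkerHistograms")) walkers@counts
            else as.matrix(walkers)
  stopifnot(nrow(counts) >= 2L)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " walker(s) with no counts excluded")
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
    if (nrow(counts) < 2L) stop("fewer than 2 non-empty walkers")
  }
  dens <- counts / tot
  meanDens <- colMeans(dens)
  ov <- colSums(sweep(dens, 2, fraction * meanDens, ">"))
  as.integer(ov)
}

#' Full convergence report
#'
#' Bundles [flatnessDeviation()], [transitionImbalance()] (when a binned
#' series is given) and [walkerOverlap()] into one list, the shape the
#' TSV/JSON exporters write.
#'
#' @param walkers a [WalkerHistograms-class].
#' @param binSeries optional binned CV series for the transition check.
#' @param rt thermal energy in kJ/mol.
#' @return list with elements `flatness`, `overlap` and optionally
#'   `transitions`.
#' @export
convergenceReport <- function(walkers, binSeries = NULL,
                              rt = thermalRT()) {
  stopifnot(is(walkers, "WalkerHistograms"))
  rep_ <- list(flatness = flatnessDeviation(walkers, rt = rt),
               overlap = walkerOverlap(walkers))
  if (!is.null(binSeries))
    rep_$transitions <- transitionImbalance(binSeries)
  rep_
}
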