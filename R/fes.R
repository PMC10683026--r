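## Free-energy surfaces from converged biased sampling: histogram
## estimator U = -RT log p, reweighted projections onto arbitrary
## observables, basin detection on the grid, Boltzmann populations and
## the basin-to-barrier energetic coupling.

## Bin edges: either explicit edges (length > 1) or `breaks` equal bins
## over `range` (default: data range).
.makeEdges <- function(x, breaks, range = NULL) {
  if (length(breaks) > 1L) return(as.numeric(breaks))
  if (is.null(range)) range <- base::range(x, finite = TRUE)
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)
  seq(range[1], range[2], length.out = breaks + 1L)
}

.binIndex <- function(x, edges, clamp = FALSE, axis = 1L) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  out <- idx < 1L | idx > length(edges) - 1L
  if (any(out)) {
    if (!clamp)
      stop(sprintf(
        "%d frame(s) outside the bin range on axis %d [%g, %g]; %s",
        sum(out), axis, edges[1], edges[length(edges)],
        "use clamp = TRUE to clip them to the edge bins"))
    idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  }
  idx
}

## Per-frame flat bin index for a 1-D vector or 2-column matrix series.
.frameBins <- function(series, edges, clamp = FALSE) {
  if (is.matrix(series) && ncol(series) == 2L) {
    i1 <- .binIndex(series[, 1], edges[[1]], clamp, 1L)
    i2 <- .binIndex(series[, 2], edges[[2]], clamp, 2L)
    n1 <- length(edges[[1]]) - 1L
    list(flat = (i2 - 1L) * n1 + i1, dim = c(n1, length(edges[[2]]) - 1L))
  } else {
    series <- as.numeric(series)
    list(flat = .binIndex(series, edges[[1]], clamp),
         dim = length(edges[[1]]) - 1L)
  }
}

#' Free-energy surface from a CV time series
#'
#' Histogram estimator of the free energy along one or two collective
#' variables: U(bin) = -RT log(count/total), anchored so the lowest
#' visited bin is zero. Frames are assumed to sample the Boltzmann
#' distribution along the CV (e.g. reweighted output of a converged
#' adaptive-bias run). Never-visited bins are masked, not set to zero.
#'
#' @param cvSeries numeric vector (1-D) or 2-column matrix (2-D) of
#'   per-frame CV values.
#' @param breaks number of bins per axis (default 50) or, per axis, an
#'   explicit vector of bin edges. For 2-D input a list of two such
#'   specifications.
#' @param range optional list (or vector, 1-D) of axis ranges.
#' @param rt thermal energy RT in kJ/mol (default [thermalRT()], the
#'   room-temperature constant).
#' @param clamp if TRUE frames outside the range are clipped into the
#'   edge bins instead of raising an error.
#' @return a [FreeEnergySurface-class].
#' @examples
#' u <- frameFreeEnergy(c(rep(0.25, 75), rep(0.75, 25)),
#'                      breaks = c(0, 0.5, 1))
#' diff(range(binEnergies(u)))  # RT * log 3
#' @export
frameFreeEnergy <- function(cvSeries, breaks = 50L, range = NULL,
                            rt = thermalRT(), clamp = FALSE) {
  twoD <- is.matrix(cvSeries) && ncol(cvSeries) == 2L
  if (!twoD) cvSeries <- as.numeric(cvSeries)
  stopifnot(NROW(cvSeries) >= 1)
  if (twoD) {
    if (!is.list(breaks)) breaks <- list(breaks, breaks)
    if (!is.list(range)) range <- list(range, range)
    edges <- list(.makeEdges(cvSeries[, 1], breaks[[1]], range[[1]]),
                  .makeEdges(cvSeries[, 2], breaks[[2]], range[[2]]))
  } else {
    if (is.list(breaks)) breaks <- breaks[[1]]
    if (is.list(range)) range <- range[[1]]
    edges <- list(.makeEdges(cvSeries, breaks, range))
  }
  fb <- .frameBins(cvSeries, edges, clamp)
  nBins <- prod(fb$dim)
  counts <- tabulate(fb$flat, nbins = nBins)
  u <- rep(NA_real_, nBins)
  visited <- counts > 0L
  u[visited] <- -rt * log(counts[visited] / sum(counts))
  u <- u - min(u, na.rm = TRUE)
  shape <- if (twoD) fb$dim else nBins
  new("FreeEnergySurface", dimension = if (twoD) 2L else 1L,
      edges = edges, energy = array(u, shape),
      counts = array(as.numeric(counts), shape), rt = rt)
}

#' Bin centers of a surface
#'
#' @param fes a [FreeEnergySurface-class].
#' @return list of numeric vectors, one per axis.
#' @export
binCenters <- function(fes) {
  lapply(fes@edges, function(e) (e[-1] + e[-length(e)]) / 2)
}

#' Per-frame free energies and thermodynamic weights
#'
#' `frameEnergies()` looks up each frame's bin energy; `frameWeights()`
#' converts them to normalized per-frame Boltzmann weights, dividing each
#' bin's weight equally among its member frames (so the weights of the
#' frames in bin b sum to exp(-U_b/RT) / Z). These weights are what
#' [projectFes()] aggregates.
#'
#' @param fes a [FreeEnergySurface-class].
#' @param cvSeries the CV series the surface was built from (same axes).
#' @param clamp passed to the bin lookup.
#' @return numeric vector, one value per frame.
#' @export
frameEnergies <- function(fes, cvSeries, clamp = FALSE) {
  fb <- .frameBins(cvSeries, fes@edges, clamp)
  as.vector(fes@energy)[fb$flat]
}

#' @rdname frameEnergies
#' @export
frameWeights <- function(fes, cvSeries, clamp = FALSE) {
  fb <- .frameBins(cvSeries, fes@edges, clamp)
  u <- as.vector(fes@energy)[fb$flat]
  n <- as.vector(fes@counts)[fb$flat]
  w <- exp(-u / fes@rt) / n
  w / sum(w)
}

#' Project a free-energy surface onto another observable
#'
#' Reweights the frames of a converged run onto an arbitrary per-frame
#' observable Y: each frame carries the thermodynamic weight of its
#' source bin (divided equally among the bin's frames), the weights are
#' summed per Y-bin, and the bin energy is -RT log of the summed weight,
#' anchored to zero at the minimum. Projecting onto the source CV itself
#' with identical binning therefore reproduces the source surface
#' exactly; empty Y-bins are masked.
#'
#' @param fes the source [FreeEnergySurface-class].
#' @param cvSeries the per-frame CV series the source surface was built
#'   from.
#' @param observable per-frame observable series (vector or 2-column
#'   matrix).
#' @param breaks,range binning of the observable axis (as in
#'   [frameFreeEnergy()]).
#' @param clamp clip out-of-range frames into the edge bins.
#' @return a [FreeEnergySurface-class] over the observable.
#' @export
projectFes <- function(fes, cvSeries, observable, breaks = 50L,
                       range = NULL, clamp = FALSE) {
  stopifnot(is(fes, "FreeEnergySurface"))
  w <- frameWeights(fes, cvSeries, clamp = clamp)
  twoD <- is.matrix(observable) && ncol(observable) == 2L
  if (!twoD) observable <- as.numeric(observable)
  if (NROW(observable) != length(w))
    stop("observable and CV series must be aligned frame-wise")
  if (twoD) {
    if (!is.list(breaks)) breaks <- list(breaks, breaks)
    if (!is.list(range)) range <- list(range, range)
    edges <- list(.makeEdges(observable[, 1], breaks[[1]], range[[1]]),
                  .makeEdges(observable[, 2], breaks[[2]], range[[2]]))
  } else {
    if (is.list(breaks)) breaks <- breaks[[1]]
    if (is.list(range)) range <- range[[1]]
    edges <- list(.makeEdges(observable, breaks, range))
  }
  fb <- .frameBins(observable, edges, clamp)
  nBins <- prod(fb$dim)
  wsum <- rep(0, nBins)
  agg <- tapply(w, fb$flat, sum)
  wsum[as.integer(names(agg))] <- agg
  counts <- tabulate(fb$flat, nbins = nBins)
  u <- rep(NA_real_, nBins)
  visited <- counts > 0L
  u[visited] <- -fes@rt * log(wsum[visited])
  u <- u - min(u, na.rm = TRUE)
  shape <- if (twoD) fb$dim else nBins
  new("FreeEnergySurface", dimension = if (twoD) 2L else 1L,
      edges = edges, energy = array(u, shape),
      counts = array(as.numeric(counts), shape), rt = fes@rt)
}

## Neighbour offsets on the flattened grid (1-D: +-1; 2-D: 4-connected),
## returned as a list: for flat index k, .gridNeighbours(dim)[[k]].
.gridNeighbours <- function(dm) {
  if (length(dm) == 1L) {
    n <- dm
    lapply(seq_len(n), function(k)
      k + c(-1L, 1L)[c(k > 1L, k < n)])
  } else {
    n1 <- dm[1]; n2 <- dm[2]
    lapply(seq_len(n1 * n2), function(k) {
      i <- (k - 1L) %% n1 + 1L
      j <- (k - 1L) %/% n1 + 1L
      nb <- integer(0)
      if (i > 1L) nb <- c(nb, k - 1L)
      if (i < n1) nb <- c(nb, k + 1L)
      if (j > 1L) nb <- c(nb, k - n1)
      if (j < n2) nb <- c(nb, k + n1)
      nb
    })
  }
}

## Discrete curvature per bin: second difference along each axis summed
## (NA neighbours are skipped; bins at the border count as convex).
.gridCurvature <- function(u, dm) {
  uv <- as.vector(u)
  nb <- .gridNeighbours(dm)
  vapply(seq_along(uv), function(k) {
    if (!is.finite(uv[k])) return(NA_real_)
    vals <- uv[nb[[k]]]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) return(0)
    sum(vals - uv[k])   # sum of (u_nb - u_k): discrete Laplacian
  }, numeric(1))
}

#' Detect basins of a free-energy surface
#'
#' Local minima are found on the visited grid and every visited bin is
#' assigned to a minimum by steepest descent (watershed): bins are
#' processed in order of increasing energy and join the basin of their
#' lowest already-assigned downhill neighbour. Each basin also has an
#' inflection-bounded core: walking outward from its minimum, bins past
#' a sign change of the discrete curvature (second difference, 1-D;
#' Laplacian, 2-D) are outside the core, so the core ends at the
#' inflection point or at the watershed ridge, whichever comes first.
#' Basins whose core has fewer than `minBins` bins are discarded as
#' microstate noise and their bins left unassigned.
#'
#' Basin membership defaults to the full watershed region
#' (`border = "ridge"`), which conserves each basin's Boltzmann mass on
#' noisy histograms; `border = "inflection"` restricts membership to the
#' core instead. On finitely sampled surfaces the discrete curvature is
#' noise-dominated partway up the basin walls, so the inflection border
#' is best reserved for smooth (densely sampled or analytic) profiles.
#'
#' @param fes a [FreeEnergySurface-class].
#' @param minBins minimum core-bin count for a basin (default 3).
#' @param border "ridge" (default) or "inflection"; which boundary
#'   defines basin membership.
#' @return a [BasinSet-class]; populations are filled in via
#'   [basinPopulations()] over the assigned bins.
#' @export
detectBasins <- function(fes, minBins = 3L,
                         border = c("ridge", "inflection")) {
  border <- match.arg(border)
  stopifnot(is(fes, "FreeEnergySurface"))
  u <- as.vector(fes@energy)
  dm <- if (fes@dimension == 1L) length(u) else dim(fes@energy)
  nb <- .gridNeighbours(dm)
  visited <- which(is.finite(u))
  if (!length(visited)) stop("surface has no visited bins")
  ord <- visited[order(u[visited], visited)]
  label <- rep(NA_integer_, length(u))
  minBin <- integer(0)
  for (k in ord) {
    lower <- nb[[k]]
    lower <- lower[is.finite(u[lower]) &
                   (u[lower] < u[k] |
                    (u[lower] == u[k] & !is.na(label[lower])))]
    if (!length(lower)) {
      minBin <- c(minBin, k)
      label[k] <- length(minBin)
    } else {
      best <- lower[which.min(u[lower])]
      label[k] <- label[best]
    }
  }
  ## inflection-bounded core of each basin: the connected convex region
  ## around the minimum, cut at curvature sign changes or the ridge
  curv <- .gridCurvature(fes@energy, dm)
  coreLabel <- rep(NA_integer_, length(u))
  for (b in seq_along(minBin)) {
    keepable <- which(label == b & (curv >= 0 | seq_along(u) == minBin[b]))
    keep <- minBin[b]
    frontier <- keep
    while (length(frontier)) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- setdiff(intersect(nxt, keepable), keep)
      keep <- c(keep, nxt)
      frontier <- nxt
    }
    coreLabel[keep] <- b
  }
  if (border == "inflection") label <- coreLabel
  ## discard basins whose core is too small
  sizes <- table(factor(coreLabel, levels = seq_along(minBin)))
  ok <- which(sizes >= minBins)
  if (!length(ok)) {
    ## degenerate surface: keep the largest watershed basin as the only one
    ok <- which.max(sizes)
  }
  label[!(label %in% ok)] <- NA_integer_
  relabel <- match(label, ok)
  member <- table(factor(label, levels = ok))
  basins <- data.frame(
    id = seq_along(ok),
    minBin = minBin[ok],
    nBins = as.integer(member),
    coreBins = as.integer(sizes[ok]),
    minEnergy = u[minBin[ok]])
  bs <- new("BasinSet",
            labels = array(relabel,
                           if (fes@dimension == 1L) length(u) else dm),
            basins = basins)
  bs@basins$population <- basinPopulations(fes, bs)
  bs
}

#' Boltzmann population fractions of basins
#'
#' p_b = sum over the basin's bins of exp(-U/RT), normalized over all
#' basin-assigned bins (unassigned bins carry no population).
#'
#' @param fes the [FreeEnergySurface-class] the basins were detected on.
#' @param basins a [BasinSet-class].
#' @return numeric vector of fractions, one per basin, summing to 1.
#' @export
basinPopulations <- function(fes, basins) {
  stopifnot(is(fes, "FreeEnergySurface"), is(basins, "BasinSet"))
  u <- as.vector(fes@energy)
  lab <- as.vector(basins@labels)
  w <- exp(-u / fes@rt)
  w[!is.finite(u)] <- 0
  tot <- sum(w[!is.na(lab)])
  vapply(basins@basins$id, function(b)
    sum(w[!is.na(lab) & lab == b]) / tot, numeric(1))
}

#' Positional sub-labels for 2-D basins
#'
#' Heuristic naming of basins of a 2-D surface by the quadrant of their
#' minimum relative to the grid midpoint: upper-right R (resting),
#' upper-left I (intermediate), lower-left A1 and lower-right A2 (the
#' two active-like corners).
#'
#' @param fes the 2-D [FreeEnergySurface-class].
#' @param basins a [BasinSet-class] detected on it.
#' @return the BasinSet with a `subLabel` column added.
#' @export
subLabelBasins <- function(fes, basins) {
  stopifnot(is(fes, "FreeEnergySurface"), fes@dimension == 2L)
  ctr <- binCenters(fes)
  mid <- vapply(ctr, function(v) mean(range(v)), numeric(1))
  dm <- dim(fes@energy)
  lab <- vapply(basins@basins$minBin, function(k) {
    i <- (k - 1L) %% dm[1] + 1L
    j <- (k - 1L) %/% dm[1] + 1L
    x <- ctr[[1]][i]; y <- ctr[[2]][j]
    if (x >= mid[1] && y >= mid[2]) "R"
    else if (x < mid[1] && y >= mid[2]) "I"
    else if (x < mid[1]) "A1" else "A2"
  }, character(1))
  basins@basins$subLabel <- lab
  basins
}

#' Basin-to-barrier energetic coupling of a 1-D profile
#'
#' For a 1-D projected surface with at least two local minima, the
#' coupling is the highest free-energy barrier separating any two local
#' minima minus the lowest basin energy (zero after anchoring). Surfaces
#' with fewer than two minima (monotonic, flat, single-well) have
#' coupling 0.
#'
#' @param fes a 1-D [FreeEnergySurface-class].
#' @return scalar coupling in kJ/mol.
#' @export
energeticCoupling <- function(fes) {
  stopifnot(is(fes, "FreeEnergySurface"), fes@dimension == 1L)
  u <- as.vector(fes@energy)
  fin <- is.finite(u)
  idx <- which(fin)
  if (length(idx) < 3L) return(0)
  ## local minima over the visited profile (plateaus collapse to first bin)
  uv <- u[idx]
  n <- length(uv)
  isMin <- vapply(seq_len(n), function(k) {
    left <- if (k > 1L) uv[k - 1L] else Inf
    right <- if (k < n) uv[k + 1L] else Inf
    (uv[k] < left && uv[k] <= right) || (uv[k] <= left && uv[k] < right)
  }, logical(1))
  ## drop consecutive plateau duplicates
  mins <- which(isMin)
  if (length(mins) > 1L)
    mins <- mins[c(TRUE, diff(mins) > 1L | diff(uv[mins]) != 0)]
  if (length(mins) < 2L) return(0)
  best <- 0
  for (a in seq_len(length(mins) - 1L)) for (b in (a + 1L):length(mins)) {
    seg <- uv[mins[a]:mins[b]]
    best <- max(best, max(seg))
  }
  best - min(uv)
}
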