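## Synthetic-data generators with known ground truth. They emulate the
## real inputs of the pipeline -- deep alignments, a reference structure,
## equilibrium trajectories, per-walker histograms -- so that every
## analysis stage can be validated end to end without external data.
## All generators are pure functions of their seed and specification.

#' Potts model with planted couplings
#'
#' Builds a sparse Potts model: zero fields and, for each planted pair,
#' a diagonal coupling block that rewards identical non-gap states
#' (`w[i,j,a,a] = strength` for the 20 residue states). Gibbs samples
#' from such a model show strong dependence exactly at the planted
#' pairs.
#'
#' @param L number of positions.
#' @param pairs 2-column matrix or data.frame of planted position pairs;
#'   `NULL` for an independent (zero-coupling) model.
#' @param strength coupling strength (default 1.5).
#' @param q alphabet size (default 21, gap last).
#' @return a [PottsModel-class].
#' @export
plantedPottsModel <- function(L, pairs = NULL, strength = 1.5, q = 21L) {
  w <- array(0, c(L, L, q, q))
  if (is.null(pairs) || !NROW(pairs)) {
    return(new("PottsModel", q = as.integer(q), v = matrix(0, L, q),
               w = w,
               trainingLog = list(loss = numeric(0), seed = NA_integer_,
                                  hyperparameters = list(planted = TRUE))))
  }
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L, all(pairs >= 1), all(pairs <= L),
            all(pairs[, 1] != pairs[, 2]))
  if (anyDuplicated(paste(pmin(pairs[, 1], pairs[, 2]),
                          pmax(pairs[, 1], pairs[, 2]))))
    stop("planted pairs must be distinct")
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    for (a in seq_len(q - 1L)) {
      w[i, j, a, a] <- strength
      w[j, i, a, a] <- strength
    }
  }
  new("PottsModel", q = as.integer(q), v = matrix(0, L, q), w = w,
      trainingLog = list(loss = numeric(0), seed = NA_integer_,
                         hyperparameters = list(planted = TRUE)))
}

#' Gibbs-sample an alignment from a Potts model
#'
#' Runs `nSequences` parallel single-site Gibbs chains: every sweep
#' resamples each position from its conditional distribution given the
#' rest of the sequence. Chains start from independent uniform states and
#' are advanced `burnIn` sweeps before emission. Deterministic given the
#' seed.
#'
#' @param model a [PottsModel-class].
#' @param nSequences number of sequences to draw.
#' @param burnIn sweeps before emission (default 100).
#' @param seed RNG seed.
#' @return an [Msa-class].
#' @export
gibbsSampleMsa <- function(model, nSequences, burnIn = 100L, seed = 1L) {
  stopifnot(is(model, "PottsModel"), nSequences >= 1)
  L <- nrow(model@v)
  q <- model@q
  W <- matrix(aperm(model@w, c(3, 1, 4, 2)), L * q, L * q)
  v <- model@v
  .withSeed(seed, {
    S <- matrix(sample.int(q, nSequences * L, replace = TRUE),
                nSequences, L)
    X <- as.matrix(.oneHot(S, q))
    for (sweep_ in seq_len(burnIn)) {
      for (i in seq_len(L)) {
        blk <- (i - 1L) * q + seq_len(q)
        logits <- X %*% W[, blk, drop = FALSE] +
          rep(v[i, ], each = nSequences)
        g <- -log(-log(matrix(stats::runif(nSequences * q),
                              nSequences, q)))
        newState <- max.col(logits + g, ties.method = "first")
        X[cbind(seq_len(nSequences), (i - 1L) * q + S[, i])] <- 0
        S[, i] <- newState
        X[cbind(seq_len(nSequences), (i - 1L) * q + newState)] <- 1
      }
    }
    alph <- if (q == 21L) .AA_ALPHABET
            else c(.AA_ALPHABET[seq_len(q - 1L)], "-")
    new("Msa", seqs = S, ids = sprintf("synth%d", seq_len(nSequences)),
        columnMap = seq_len(L), alphabet = alph)
  })
}

#' Toy structure realizing a contact pattern
#'
#' Embeds L single-atom (C-alpha) residues in 3-D so that requested
#' pairs sit at `contactDist` Angstrom and all other pairs stay beyond
#' `minSeparation`. Coordinates come from a classical-scaling start
#' refined by penalized optimisation (exact spring terms on contacts,
#' one-sided repulsion up to `farDist` on non-contacts). A pattern that
#' provably cannot be embedded -- a contact chain forces two
#' "non-contacting" residues below `minSeparation` (triangle
#' inequality) -- or that the embedding fails to realize is an error.
#' Written files re-parse to the same coordinates at PDB precision.
#'
#' @param L number of residues (>= 2).
#' @param contacts 2-column matrix/data.frame of residue index pairs to
#'   place in contact; may be empty for an all-far structure.
#' @param contactDist target contact distance in Angstrom (default 4).
#' @param farDist preferred non-contact distance (default 20).
#' @param minSeparation minimum tolerated non-contact distance
#'   (default 8; keep it above the contact cutoff you will map with).
#' @param file optional path to write a PDB file to.
#' @param chain chain identifier (default "A").
#' @param sequence optional one-letter amino-acid sequence of length L
#'   (default: poly-alanine); useful when the structure must be
#'   alignable against an MSA query.
#' @return a `bio3d` pdb object (invisibly also written to `file`).
#' @export
makeToyStructure <- function(L, contacts = NULL, contactDist = 4,
                             farDist = 20, minSeparation = 8,
                             file = NULL, chain = "A", sequence = NULL) {
  stopifnot(L >= 2, contactDist > 0, farDist > minSeparation,
            minSeparation > contactDist)
  isContact <- matrix(FALSE, L, L)
  if (!is.null(contacts) && NROW(contacts)) {
    contacts <- as.matrix(contacts)
    stopifnot(all(contacts >= 1), all(contacts <= L))
    isContact[contacts] <- TRUE
    isContact[contacts[, 2:1, drop = FALSE]] <- TRUE
  }
  ## provable infeasibility: hop distance through the contact graph
  ## bounds any pair's distance by hops * contactDist
  hops <- matrix(Inf, L, L)
  diag(hops) <- 0
  hops[isContact] <- 1
  for (k in seq_len(L))
    hops <- pmin(hops, outer(hops[, k], hops[k, ], "+"))
  bad <- !isContact & upper.tri(hops) & hops * contactDist <= minSeparation
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unrealizable pattern: contact chain forces d(%d,%d) <= %g (%s)",
      ij[1], ij[2], hops[ij[1], ij[2]] * contactDist,
      "triangle inequality"))
  }
  ## target matrix for the classical-scaling start
  D <- matrix(farDist, L, L)
  D[isContact] <- contactDist
  diag(D) <- 0
  xyz <- stats::cmdscale(D, k = min(3L, L - 1L))
  if (ncol(xyz) < 3L) xyz <- cbind(xyz, matrix(0, L, 3L - ncol(xyz)))
  up <- which(upper.tri(D), arr.ind = TRUE)
  cnt <- isContact[up]
  objective <- function(par) {
    X <- matrix(par, L, 3)
    d <- sqrt(rowSums((X[up[, 1], , drop = FALSE] -
                       X[up[, 2], , drop = FALSE])^2))
    100 * sum((d[cnt] - contactDist)^2) +
      sum(pmax(0, farDist - d[!cnt])^2)
  }
  feasible <- function(X) {
    realized <- as.matrix(stats::dist(X))
    all(abs(realized[isContact] - contactDist) < 0.5) &&
      all(realized[!isContact & upper.tri(realized)] > minSeparation)
  }
  if (L > 2L) {
    start <- as.vector(xyz)
    ok <- FALSE
    for (attempt in 1:10) {   # deterministic jittered restarts
      par0 <- if (attempt == 1L) start
              else .withSeed(1000L + attempt,
                             start + stats::rnorm(length(start),
                                                  sd = farDist / 8))
      fit <- stats::optim(par0, objective, method = "BFGS",
                          control = list(maxit = 2000))
      X <- matrix(fit$par, L, 3)
      if (feasible(X)) { xyz <- X; ok <- TRUE; break }
    }
    if (!ok)
      stop("unrealizable pattern: 3-D embedding cannot separate the ",
           "requested contacts from the non-contacts")
  }
  resid <- if (is.null(sequence)) rep("ALA", L)
           else bio3d::aa123(strsplit(toupper(sequence), "")[[1]])
  if (length(resid) != L) stop("sequence must have length L")
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    file = tmp,
    xyz = as.vector(t(xyz)),
    type = rep("ATOM", L),
    resno = seq_len(L),
    resid = resid,
    elety = rep("CA", L),
    chain = rep(chain, L),
    o = rep(1, L), b = rep(0, L))
  pdb <- bio3d::read.pdb(tmp)
  if (is.null(file)) unlink(tmp)
  pdb
}

## Tilted double-well potential on one latent coordinate. The right well
## is the exact mirror of the left shifted by deltaU (step applied past
## the barrier top), so the Boltzmann weight ratio between the half-axes
## is exp(-deltaU/rt) exactly.
.doubleWellU <- function(z, barrier, deltaU) {
  barrier * (z^2 - 1)^2 + deltaU * (z > 0)
}

#' Metropolis-sampled two-state distance trajectory
#'
#' Samples a tilted symmetric double-well potential on a latent
#' coordinate by Metropolis Monte Carlo and maps it to pair distances:
#' informative pairs are affine images of the latent coordinate plus
#' bounded positive uniform noise (clipped at 0), noise pairs are
#' state-independent constants plus the same kind of noise. Because the
#' tilt is a step applied beyond the barrier top, the exact Boltzmann
#' population split between the two wells is `1 : exp(-deltaU/rt)`,
#' which is returned alongside the trajectory.
#'
#' @param nFrames number of frames.
#' @param deltaU energy offset of the right well, kJ/mol (default 0:
#'   symmetric wells).
#' @param barrier barrier height at the latent origin, kJ/mol (default
#'   `4 * rt`, high enough for two clearly resolved states while still
#'   allowing frequent Metropolis crossings).
#' @param rt thermal energy, kJ/mol.
#' @param nInformative number of state-coupled pairs (default 2; the
#'   first increases with the latent coordinate, the second decreases).
#' @param nNoise number of uninformative pairs (default 50).
#' @param noiseAmp amplitude of the bounded uniform noise, nm
#'   (default 0.05).
#' @param step Metropolis proposal width (default 1.0, the scale of the
#'   inter-well distance, so the chain decorrelates across the barrier
#'   within tens of steps; a warning suggests a new value when the
#'   acceptance rate leaves (0.05, 0.95)).
#' @param burnIn discarded initial steps (default 1000).
#' @param seed RNG seed.
#' @return list with `trajectory` ([DistanceTrajectory-class]),
#'   `latent`, `stateLabels` (1 = left well, 2 = right well),
#'   `truePopulations` (exact), `informativePairs` (indices into the
#'   pair table), `acceptanceRate`.
#' @export
sampleTwoStateTrajectory <- function(nFrames, deltaU = 0,
                                     barrier = NULL, rt = thermalRT(),
                                     nInformative = 2L, nNoise = 50L,
                                     noiseAmp = 0.05, step = 1.0,
                                     burnIn = 1000L, seed = 1L) {
  stopifnot(nFrames >= 1, nInformative >= 1)
  if (is.null(barrier)) barrier <- 4 * rt
  .withSeed(seed, {
    nTot <- burnIn + nFrames
    z <- numeric(nTot)
    zc <- -1
    uc <- .doubleWellU(zc, barrier, deltaU)
    prop <- stats::rnorm(nTot, sd = step)
    runif_ <- stats::runif(nTot)
    acc <- 0L
    for (t in seq_len(nTot)) {
      zn <- zc + prop[t]
      un <- .doubleWellU(zn, barrier, deltaU)
      if (runif_[t] < exp(-(un - uc) / rt)) {
        zc <- zn; uc <- un; acc <- acc + 1L
      }
      z[t] <- zc
    }
    accRate <- acc / nTot
    if (accRate <= 0.05 || accRate >= 0.95)
      warning(sprintf(
        "Metropolis acceptance rate %.2f outside (0.05, 0.95); %s %.2g",
        accRate, "consider a step size near", step *
          if (accRate <= 0.05) 0.5 else 2))
    z <- z[-seq_len(burnIn)]
    ## affine latent -> distance maps: first informative pair spans
    ## 0.4 nm (left well) to 1.0 nm (right well), matching typical
    ## contact-breaking amplitudes; further pairs alternate sign.
    slope <- 0.3 * (-1)^(seq_len(nInformative) + 1) *
      (1 - 0.2 * (seq_len(nInformative) - 1) / max(1, nInformative - 1))
    icept <- 0.7
    nPairs <- nInformative + nNoise
    D <- matrix(0, nFrames, nPairs)
    for (p in seq_len(nInformative))
      D[, p] <- icept + slope[p] * z
    if (nNoise > 0) {
      const <- stats::runif(nNoise, 0.4, 1.0)
      D[, nInformative + seq_len(nNoise)] <-
        rep(const, each = nFrames)
    }
    D <- D + matrix(stats::runif(nFrames * nPairs, 0, noiseAmp),
                    nFrames, nPairs)
    D[D < 0] <- 0
    ## pair manifest: synthetic residue numbering 1..2*nPairs
    pairs <- data.frame(i = seq_len(nPairs) * 2L - 1L,
                        j = seq_len(nPairs) * 2L)
    pRight <- exp(-deltaU / rt) / (1 + exp(-deltaU / rt))
    list(
      trajectory = new("DistanceTrajectory",
                       times = seq_len(nFrames) - 1,
                       pairs = pairs, distances = D,
                       label = "two-state synthetic"),
      latent = z,
      stateLabels = ifelse(z <= 0, 1L, 2L),
      truePopulations = c(1 - pRight, pRight),
      informativePairs = seq_len(nInformative),
      acceptanceRate = accRate)
  })
}

#' Synthetic per-walker histograms with controllable defects
#'
#' Builds exact (noise-free) per-walker visit histograms on a uniform
#' target: every bin holds `countsPerBin` counts per walker, except
#' planted defects -- bins at half density across all walkers, and dead
#' bins of a specific walker. The closed-form expectations (e.g. a
#' half-density bin deviates by RT log 2 against the design total) make
#' these fixtures exact oracles for the convergence diagnostics.
#'
#' @param nWalkers number of walkers (>= 2).
#' @param nBins number of grid bins.
#' @param countsPerBin design counts per walker and bin (default 100).
#' @param halfDensityBins bins set to half density for all walkers.
#' @param deadWalkerBins optional list(walker =, bins =): zero those
#'   bins for that walker.
#' @return a [WalkerHistograms-class] (uniform target).
#' @export
makeWalkerHistograms <- function(nWalkers = 4L, nBins = 20L,
                                 countsPerBin = 100,
                                 halfDensityBins = integer(0),
                                 deadWalkerBins = NULL) {
  stopifnot(nWalkers >= 2, nBins >= 1, countsPerBin > 0)
  counts <- matrix(countsPerBin, nWalkers, nBins)
  if (length(halfDensityBins))
    counts[, halfDensityBins] <- countsPerBin / 2
  if (!is.null(deadWalkerBins))
    counts[deadWalkerBins$walker, deadWalkerBins$bins] <- 0
  new("WalkerHistograms", counts = counts,
      target = rep(1 / nBins, nBins), gridDim = as.integer(nBins))
}
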