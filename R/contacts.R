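## Structure-side analysis: contact maps, alignment-to-structure mapping,
## detection and clustering of high-scoring non-contacting ("false
## positive") pairs, and the steering coordinates built from them.

## Load a PDB via bio3d unless already parsed; keep protein ATOM records,
## first model, first altloc, optional chain selection, heavy atoms only.
.loadStructureAtoms <- function(structure, chain = NULL) {
  pdb <- if (is.character(structure)) bio3d::read.pdb(structure)
         else structure
  stopifnot(inherits(pdb, "pdb"))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- substr(elem, 1, 1)
  }
  at <- at[!(toupper(trimws(elem)) %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("no heavy protein atoms found in structure")
  at
}

#' Minimum heavy-atom distance contact map of a structure
#'
#' Computes, for every residue pair, the minimum distance between heavy
#' atoms (Angstrom) and flags contacts as pairs with distance at or below
#' `cutoff` and sequence separation `|i - j| >= minSeqSep`. The reference
#' analysis never fixes the contact criterion, so both parameters are
#' mandatory knobs of every downstream step; the defaults (5.5 Angstrom,
#' separation 5) follow common contact-prediction benchmarking practice.
#'
#' @param structure path to a PDB file or a `bio3d` pdb object
#'   (single model; first altloc used).
#' @param cutoff contact distance cutoff in Angstrom (default 5.5).
#' @param minSeqSep minimum residue separation for a contact (default 5).
#' @param chain optional chain identifier(s) to restrict to.
#' @return a [ContactMap-class]. Residues without heavy atoms get `NA`
#'   distances and never count as contacts.
#' @export
contactMap <- function(structure, cutoff = 5.5, minSeqSep = 5,
                       chain = NULL) {
  stopifnot(cutoff > 0, minSeqSep >= 0)
  at <- .loadStructureAtoms(structure, chain)
  key <- paste(at$chain, at$resno)
  resKey <- unique(key)
  if (length(resKey) < 2L) stop("need at least 2 residues with heavy atoms")
  residx <- match(key, resKey)
  L <- length(resKey)
  first <- match(resKey, key)
  residues <- data.frame(
    resno = at$resno[first], chain = at$chain[first],
    resid = at$resid[first], stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  D <- matrix(NA_real_, L, L)
  atomIdx <- split(seq_len(nrow(at)), residx)
  for (i in seq_len(L - 1L)) {
    ai <- xyz[atomIdx[[i]], , drop = FALSE]
    for (j in (i + 1L):L) {
      aj <- xyz[atomIdx[[j]], , drop = FALSE]
      d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * tcrossprod(ai, aj)
      D[i, j] <- D[j, i] <- sqrt(max(0, min(d2)))
    }
  }
  diag(D) <- 0
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  contacts <- !is.na(D) & D <= cutoff & sep >= minSeqSep
  diag(contacts) <- FALSE
  new("ContactMap", residues = residues, distances = D,
      cutoff = cutoff, minSeqSep = minSeqSep, contacts = contacts)
}

#' Map retained alignment columns to structure residues
#'
#' Aligns the ungapped query sequence (a named record of the MSA) to the
#' structure's one-letter sequence by global pairwise alignment and
#' returns an injective map from retained MSA columns to structure
#' residue rows. Columns whose query position is absent from the
#' structure (or is a gap in the query) are flagged unmapped.
#'
#' @param msa an [Msa-class] object.
#' @param queryId identifier of the query record in the MSA.
#' @param structure PDB path or `bio3d` pdb object.
#' @param chain optional chain restriction.
#' @param identityFloor minimum sequence identity over the aligned span
#'   (default 0.9); below this the mapping is refused.
#' @return data.frame with one row per retained MSA column: `column`,
#'   `origColumn`, `resIdx` (row in the contact map's residue table, `NA`
#'   if unmapped), `resno`, `chain`.
#' @export
mapAlignmentToStructure <- function(msa, queryId, structure, chain = NULL,
                                    identityFloor = 0.9) {
  stopifnot(is(msa, "Msa"))
  rowIdx <- match(queryId, msa@ids)
  if (is.na(rowIdx)) stop("query '", queryId, "' not found in the MSA")
  gap <- length(msa@alphabet)
  qstates <- msa@seqs[rowIdx, ]
  qCols <- which(qstates != gap)                 # retained columns w/ residue
  qSeq <- paste(msa@alphabet[qstates[qCols]], collapse = "")

  at <- .loadStructureAtoms(structure, chain)
  key <- paste(at$chain, at$resno)
  first <- match(unique(key), key)
  res3 <- at$resid[first]
  sSeq <- paste(bio3d::aa321(res3), collapse = "")
  sSeq <- gsub("X", "A", sSeq)   # unknown residues: neutral for alignment

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qSeq), Biostrings::AAString(sSeq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pq <- as.character(Biostrings::alignedPattern(aln))
  ps <- as.character(Biostrings::alignedSubject(aln))
  aq <- strsplit(pq, "")[[1]]
  as_ <- strsplit(ps, "")[[1]]
  both <- aq != "-" & as_ != "-"
  ident <- sum(aq[both] == as_[both]) / max(1L, sum(both))
  if (ident < identityFloor)
    stop(sprintf(
      "query/structure identity %.2f below the floor %.2f over the aligned span",
      ident, identityFloor))

  ## query position -> structure residue row
  qPos <- cumsum(aq != "-")
  sPos <- cumsum(as_ != "-")
  q2s <- rep(NA_integer_, nchar(qSeq))
  q2s[qPos[both]] <- sPos[both]

  L <- alignmentLength(msa)
  col2q <- rep(NA_integer_, L)
  col2q[qCols] <- seq_along(qCols)
  resIdx <- ifelse(is.na(col2q), NA_integer_, q2s[col2q])
  data.frame(
    column = seq_len(L),
    origColumn = msa@columnMap,
    resIdx = resIdx,
    resno = at$resno[first][resIdx],
    chain = at$chain[first][resIdx],
    stringsAsFactors = FALSE)
}

#' Detect high-scoring pairs absent from the structure
#'
#' Takes the `topNPairs` highest-scoring coevolving pairs (default `2L`
#' with `L` the map size), restricts to pairs mappable onto the structure
#' with sequence separation at least the contact map's `minSeqSep`, and
#' returns those that are not in structural contact (minimum heavy-atom
#' distance above the cutoff), sorted by decreasing score. These are the
#' candidate contacts of alternative conformational states.
#'
#' @param coevo an APC-corrected [CoevolutionMap-class].
#' @param cmap a [ContactMap-class] of the reference structure.
#' @param mapping optional output of [mapAlignmentToStructure()]; if
#'   `NULL`, map column k is assumed to be contact-map residue k.
#' @param topNPairs how many top-scoring pairs to screen (default 2 * L).
#' @return a [FalsePositivePairs-class]; empty (with a warning) when every
#'   screened pair is in contact.
#' @export
detectFalsePositives <- function(coevo, cmap, mapping = NULL,
                                 topNPairs = NULL) {
  stopifnot(is(coevo, "CoevolutionMap"), is(cmap, "ContactMap"))
  L <- nrow(coevo@scores)
  if (is.null(topNPairs)) topNPairs <- 2L * L
  tc <- topCouplings(coevo)
  if (is.null(mapping)) {
    tc$resI <- ifelse(tc$i <= nrow(cmap@residues), tc$i, NA_integer_)
    tc$resJ <- ifelse(tc$j <= nrow(cmap@residues), tc$j, NA_integer_)
  } else {
    tc$resI <- mapping$resIdx[tc$i]
    tc$resJ <- mapping$resIdx[tc$j]
  }
  tc <- tc[!is.na(tc$resI) & !is.na(tc$resJ), , drop = FALSE]
  tc <- tc[abs(tc$resI - tc$resJ) >= cmap@minSeqSep, , drop = FALSE]
  tc <- utils::head(tc, topNPairs)
  d <- cmap@distances[cbind(tc$resI, tc$resJ)]
  inContact <- cmap@contacts[cbind(tc$resI, tc$resJ)]
  keep <- !is.na(d) & !inContact
  fp <- tc[keep, , drop = FALSE]
  pairs <- data.frame(
    i = fp$resI, j = fp$resJ,
    resnoI = cmap@residues$resno[fp$resI],
    resnoJ = cmap@residues$resno[fp$resJ],
    column_i = fp$origI, column_j = fp$origJ,
    score = fp$score,
    distance = cmap@distances[cbind(fp$resI, fp$resJ)])
  pairs <- pairs[order(-pairs$score, pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  if (!nrow(pairs))
    warning("no false-positive pairs among the top ", topNPairs,
            " couplings")
  new("FalsePositivePairs", pairs = pairs,
      metadata = list(topNPairs = topNPairs, cutoff = cmap@cutoff,
                      minSeqSep = cmap@minSeqSep))
}

## 1-D Gaussian mean-shift mode seeking; returns the number of modes and
## the mode positions. Used to pick k for the K-means step.
.meanShiftModes <- function(x, bandwidth = NULL, tol = 1e-8,
                            maxIter = 500L) {
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd0(x)
    if (!is.finite(bandwidth) || bandwidth <= 0)
      bandwidth <- max(1e-8, diff(range(x)) / 10, na.rm = TRUE)
  }
  y <- x
  for (it in seq_len(maxIter)) {
    k <- exp(-0.5 * (outer(y, x, "-") / bandwidth)^2)
    ynew <- as.vector(k %*% x) / rowSums(k)
    if (max(abs(ynew - y)) < tol) { y <- ynew; break }
    y <- ynew
  }
  modes <- sort(unique(round(y / (bandwidth * 1e-3)))) * bandwidth * 1e-3
  ## merge modes closer than the bandwidth
  merged <- modes[1]
  for (m in modes[-1])
    if (m - merged[length(merged)] > bandwidth) merged <- c(merged, m)
  merged
}

#' Cluster detected pairs by coevolution strength
#'
#' Chooses the number of clusters by mean-shift mode seeking on the 1-D
#' score distribution and assigns pairs with K-means. Clusters are
#' relabelled so cluster 1 has the highest mean score. Deterministic
#' given the seed; shuffling the pair order does not change the
#' partition.
#'
#' @param fp a [FalsePositivePairs-class].
#' @param seed RNG seed for K-means initialisation.
#' @param k optional fixed cluster count overriding mean shift.
#' @param bandwidth optional mean-shift kernel bandwidth (default:
#'   Silverman's rule).
#' @return the input with a `cluster` column added to `pairTable()`.
#' @export
clusterFalsePositives <- function(fp, seed = 1L, k = NULL,
                                  bandwidth = NULL) {
  stopifnot(is(fp, "FalsePositivePairs"), nrow(fp@pairs) >= 1)
  x <- fp@pairs$score
  if (is.null(k)) k <- length(.meanShiftModes(x, bandwidth))
  nUnique <- length(unique(x))
  if (k > nUnique) {
    warning("fewer distinct scores (", nUnique, ") than clusters (", k,
            "); reducing k")
    k <- nUnique
  }
  if (k == 1L || length(x) == 1L) {
    cl <- rep(1L, length(x))
  } else {
    km <- .withSeed(seed,
      stats::kmeans(x, centers = k, nstart = 25L, iter.max = 100L))
    ## relabel clusters by decreasing centre so labels are order-invariant
    relabel <- match(km$cluster, order(-km$centers[, 1]))
    cl <- as.integer(relabel)
  }
  fp@pairs$cluster <- cl
  fp@metadata$clusterSeed <- seed
  fp@metadata$nClusters <- k
  fp
}

#' Build steering (pull) coordinates from pair clusters
#'
#' One coordinate per cluster, defined as the weighted mean of the member
#' pair distances. Weights default to the normalized coupling scores
#' (`uniformWeights = TRUE` gives the plain intracluster mean instead).
#' Duplicate listings of a pair are collapsed before normalization, so
#' the coordinate value is invariant to duplicates. The per-contact force
#' constant and the target distance default to 200 kJ/mol/nm^2 and 0.2 nm.
#'
#' @param fp a clustered [FalsePositivePairs-class].
#' @param forceConstant per-contact force constant, kJ mol^-1 nm^-2.
#' @param target target distance in nm.
#' @param uniformWeights logical; use equal weights instead of scores.
#' @return a [PullCoordinateSet-class].
#' @export
buildPullCoordinates <- function(fp, forceConstant = 200, target = 0.2,
                                 uniformWeights = FALSE) {
  stopifnot(is(fp, "FalsePositivePairs"))
  if (!"cluster" %in% names(fp@pairs))
    stop("pairs must be clustered first (clusterFalsePositives)")
  if (forceConstant <= 0) stop("force constant must be positive")
  if (target <= 0) stop("target distance must be positive")
  clusters <- lapply(split(fp@pairs, fp@pairs$cluster), function(cl) {
    cl <- cl[!duplicated(cl[, c("i", "j")]), , drop = FALSE]
    w <- if (uniformWeights) rep(1, nrow(cl)) else cl$score
    if (any(w <= 0)) {
      warning("non-positive scores in a cluster; using uniform weights")
      w <- rep(1, nrow(cl))
    }
    cl$weight <- w / sum(w)
    rownames(cl) <- NULL
    cl
  })
  new("PullCoordinateSet", clusters = unname(clusters),
      forceConstant = forceConstant, target = target)
}

#' Evaluate pull coordinates on pair distances
#'
#' @param pcs a [PullCoordinateSet-class].
#' @param distances either a named numeric vector (`"i-j"` in contact-map
#'   row indices) or a [DistanceTrajectory-class]; values in nm.
#' @return numeric vector (one value per cluster) or a frames x clusters
#'   matrix for a trajectory.
#' @export
evaluatePullCoordinates <- function(pcs, distances) {
  stopifnot(is(pcs, "PullCoordinateSet"))
  if (is(distances, "DistanceTrajectory")) {
    key <- paste(distances@pairs$i, distances@pairs$j, sep = "-")
    out <- vapply(pcs@clusters, function(cl) {
      idx <- match(paste(cl$i, cl$j, sep = "-"), key)
      if (anyNA(idx)) stop("trajectory is missing pairs of a cluster")
      as.vector(distances@distances[, idx, drop = FALSE] %*% cl$weight)
    }, numeric(nrow(distances@distances)))
    matrix(out, nrow = nrow(distances@distances))
  } else {
    vapply(pcs@clusters, function(cl) {
      idx <- match(paste(cl$i, cl$j, sep = "-"), names(distances))
      if (anyNA(idx)) stop("distance vector is missing pairs of a cluster")
      sum(distances[idx] * cl$weight)
    }, numeric(1))
  }
}
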