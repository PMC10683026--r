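## Collective-variable learning: distance featurisation of conformational
## ensembles, a linear maximum-margin classifier between two ensembles,
## and the positive/negative-coefficient CV pair built from it.

#' Per-frame minimum inter-residue distances
#'
#' Extracts, for each frame and each requested residue pair, the minimum
#' heavy-atom distance in nm. Frames are given as a list of coordinate
#' tables (`data.frame` with columns `resno`, `x`, `y`, `z`, Angstrom)
#' or `bio3d` pdb objects.
#'
#' @param frames list of frames as described above.
#' @param pairs data.frame with columns `i`, `j`: residue numbers.
#' @param times optional frame times (default 0, 1, 2, ...).
#' @param label source label for the trajectory.
#' @return a [DistanceTrajectory-class] (distances in nm).
#' @export
distanceFeatures <- function(frames, pairs, times = NULL,
                             label = "trajectory") {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (!NROW(pairs)) stop("empty pair list")
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("i", "j") %in% names(pairs)))
  if (is.null(times)) times <- seq_along(frames) - 1
  toTable <- function(fr) {
    if (inherits(fr, "pdb")) {
      at <- .loadStructureAtoms(fr)
      data.frame(resno = at$resno, x = at$x, y = at$y, z = at$z)
    } else as.data.frame(fr)
  }
  mats <- lapply(frames, toTable)
  missing <- unique(unlist(lapply(mats, function(tb) {
    setdiff(unique(c(pairs$i, pairs$j)), unique(tb$resno))
  })))
  if (length(missing))
    stop("pairs reference residues missing from frames: ",
         paste(missing, collapse = ", "))
  D <- matrix(0, length(frames), nrow(pairs))
  for (f in seq_along(mats)) {
    tb <- mats[[f]]
    xyzBy <- split(as.matrix(tb[, c("x", "y", "z")]), tb$resno)
    for (p in seq_len(nrow(pairs))) {
      ai <- matrix(xyzBy[[as.character(pairs$i[p])]], ncol = 3)
      aj <- matrix(xyzBy[[as.character(pairs$j[p])]], ncol = 3)
      d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * tcrossprod(ai, aj)
      D[f, p] <- .angToNm(sqrt(max(0, min(d2))))
    }
  }
  new("DistanceTrajectory", times = as.numeric(times), pairs = pairs,
      distances = D, label = label)
}

#' Construct a DistanceTrajectory from a matrix
#'
#' @param distances frames x pairs matrix, nm.
#' @param pairs data.frame with columns `i`, `j`.
#' @param times optional frame times.
#' @param label source label.
#' @return a [DistanceTrajectory-class].
#' @export
distanceTrajectory <- function(distances, pairs, times = NULL,
                               label = "trajectory") {
  distances <- as.matrix(distances)
  if (is.null(times)) times <- seq_len(nrow(distances)) - 1
  new("DistanceTrajectory", times = as.numeric(times),
      pairs = as.data.frame(pairs), distances = distances, label = label)
}

#' Train a linear maximum-margin state classifier
#'
#' Fits a linear-kernel support-vector machine separating two
#' conformational ensembles on their shared pair-distance features.
#' Features are z-scored first (the scaler is stored in the model);
#' coefficients are reported in standardized space and oriented so the
#' decision value increases from ensemble A towards ensemble B. Classes
#' are balanced by inverse-frequency weights when the ensembles differ
#' in size.
#'
#' @param ensembleA,ensembleB [DistanceTrajectory-class] objects over the
#'   same pair list (order may differ).
#' @param regularization SVM cost parameter C (default 1).
#' @param seed recorded in the metadata (the quadratic-programming fit
#'   itself is deterministic).
#' @return a [LinearStateModel-class].
#' @export
trainStateClassifier <- function(ensembleA, ensembleB, regularization = 1,
                                 seed = 1L) {
  stopifnot(is(ensembleA, "DistanceTrajectory"),
            is(ensembleB, "DistanceTrajectory"),
            nrow(ensembleA@distances) >= 2,
            nrow(ensembleB@distances) >= 2)
  keyA <- paste(ensembleA@pairs$i, ensembleA@pairs$j, sep = "-")
  keyB <- paste(ensembleB@pairs$i, ensembleB@pairs$j, sep = "-")
  if (!setequal(keyA, keyB))
    stop("ensembles must share the same pair list")
  ord <- match(keyA, keyB)
  dA <- ensembleA@distances
  dB <- ensembleB@distances[, ord, drop = FALSE]
  ## canonical internal order: the fit must be symmetric in its inputs so
  ## that swapping the ensembles negates the coefficients exactly
  ## (orientation is fixed to the caller's A -> B below)
  hash <- function(d, lbl) paste(lbl, nrow(d),
                                 format(sum(d), digits = 17),
                                 format(sum(d^2), digits = 17))
  swapped <- hash(dB, ensembleB@label) < hash(dA, ensembleA@label)
  X <- if (swapped) rbind(dB, dA) else rbind(dA, dB)
  y <- factor(c(rep("A", nrow(if (swapped) dB else dA)),
                rep("B", nrow(if (swapped) dA else dB))),
              levels = c("A", "B"))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  cw <- length(y) / (2 * table(y))
  fit <- .withSeed(seed, e1071::svm(
    Z, y, kernel = "linear", cost = regularization, scale = FALSE,
    class.weights = c(A = unname(cw["A"]), B = unname(cw["B"]))))
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- as.vector(Z %*% w) + b
  ## orient: decision increases from the caller's A to the caller's B
  isCallerB <- if (swapped) y == "A" else y == "B"
  if (mean(f[isCallerB]) < mean(f[!isCallerB])) { w <- -w; b <- -b; f <- -f }
  acc <- mean((f > 0) == isCallerB)
  pairKey <- sprintf("%s-%s", ensembleA@pairs$i, ensembleA@pairs$j)
  names(w) <- pairKey
  ranking <- order(-abs(w), ensembleA@pairs$i, ensembleA@pairs$j)
  new("LinearStateModel",
      coefficients = w, intercept = b,
      scalerCenter = center, scalerScale = scale,
      ranking = as.integer(ranking), pairs = ensembleA@pairs,
      metadata = list(regularization = regularization, seed = seed,
                      nA = nrow(ensembleA@distances),
                      nB = nrow(ensembleB@distances),
                      trainingAccuracy = acc))
}

#' Split classifier coefficients into a CV pair
#'
#' Takes the `topK` pairs by absolute coefficient (default 20; ties
#' broken by pair order) and partitions them by coefficient sign: CV_1
#' collects the positive, CV_2 the negative coefficients. Within each CV
#' the absolute coefficients are renormalized to sum to 1, so both CVs
#' are positively weighted sums of distances and respond monotonically
#' to every constituent distance.
#'
#' @param model a [LinearStateModel-class].
#' @param topK number of top-ranked pairs to keep (default 20).
#' @return a [CollectiveVariablePair-class]. If one sign class is empty,
#'   the corresponding CV is empty and a warning is raised (single-CV
#'   mode).
#' @export
makeCvPair <- function(model, topK = 20L) {
  stopifnot(is(model, "LinearStateModel"),
            topK >= 1, topK <= length(model@coefficients))
  sel <- model@ranking[seq_len(topK)]
  co <- model@coefficients[sel]
  pr <- model@pairs[sel, c("i", "j"), drop = FALSE]
  mk <- function(mask) {
    w <- abs(co[mask])
    df <- data.frame(i = pr$i[mask], j = pr$j[mask],
                     weight = if (length(w)) w / sum(w) else numeric(0))
    rownames(df) <- NULL
    df
  }
  cv1 <- mk(co > 0)
  cv2 <- mk(co < 0)
  if (!nrow(cv1)) warning("no positive coefficients in the top ", topK,
                          "; CV_1 is empty (single-CV mode)")
  if (!nrow(cv2)) warning("no negative coefficients in the top ", topK,
                          "; CV_2 is empty (single-CV mode)")
  new("CollectiveVariablePair", cv1 = cv1, cv2 = cv2,
      normalization = "abs-coefficient, renormalized to sum 1 per CV")
}

#' Evaluate a CV on a distance trajectory
#'
#' Weighted sum of the constituent pair distances per frame (nm).
#'
#' @param trajectory a [DistanceTrajectory-class].
#' @param cv a [CollectiveVariablePair-class].
#' @param which which CVs to evaluate, subset of `c(1, 2)`.
#' @return numeric matrix frames x length(which), columns named
#'   `cv1`/`cv2`.
#' @export
evaluateCv <- function(trajectory, cv, which = c(1L, 2L)) {
  stopifnot(is(trajectory, "DistanceTrajectory"),
            is(cv, "CollectiveVariablePair"),
            all(which %in% c(1L, 2L)))
  key <- paste(trajectory@pairs$i, trajectory@pairs$j, sep = "-")
  one <- function(def, label) {
    if (!nrow(def))
      return(stats::setNames(
        rep(NA_real_, nrow(trajectory@distances)), NULL))
    idx <- match(paste(def$i, def$j, sep = "-"), key)
    if (anyNA(idx))
      stop("trajectory is missing CV pairs: ",
           paste(paste(def$i, def$j, sep = "-")[is.na(idx)],
                 collapse = ", "))
    as.vector(trajectory@distances[, idx, drop = FALSE] %*% def$weight)
  }
  defs <- list(cv@cv1, cv@cv2)
  out <- vapply(which, function(k) one(defs[[k]], k),
                numeric(nrow(trajectory@distances)))
  colnames(out) <- paste0("cv", which)
  out
}
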