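## Plain-text serialisation of the pipeline's products: TSV tables for
## matrices and trajectories, JSON for manifests and reports.

#' Write coupling scores as a pair table
#'
#' Tab-separated `i`, `j`, `raw_score`, `apc_score` over the upper
#' triangle, in 1-based original alignment columns.
#'
#' @param raw the uncorrected [CoevolutionMap-class].
#' @param corrected the APC-corrected map on the same columns.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeCouplingScores <- function(raw, corrected, file) {
  stopifnot(is(raw, "CoevolutionMap"), is(corrected, "CoevolutionMap"),
            identical(raw@columnMap, corrected@columnMap))
  idx <- which(upper.tri(raw@scores), arr.ind = TRUE)
  df <- data.frame(
    i = raw@columnMap[idx[, 1]], j = raw@columnMap[idx[, 2]],
    raw_score = raw@scores[idx], apc_score = corrected@scores[idx])
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a square score-matrix dump
#'
#' @param map a [CoevolutionMap-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeScoreMatrix <- function(map, file) {
  stopifnot(is(map, "CoevolutionMap"))
  m <- map@scores
  dimnames(m) <- list(map@columnMap, map@columnMap)
  utils::write.table(m, file, sep = "\t", quote = FALSE)
  invisible(file)
}

#' Distance-trajectory I/O
#'
#' The distance matrix goes to a TSV (`time` column plus one column per
#' pair named `i-j`); the pair manifest and label to a JSON sidecar
#' (`<file>.json`).
#'
#' @param traj a [DistanceTrajectory-class].
#' @param file TSV path.
#' @return `writeDistanceTrajectory`: the path, invisibly;
#'   `readDistanceTrajectory`: the trajectory.
#' @export
writeDistanceTrajectory <- function(traj, file) {
  stopifnot(is(traj, "DistanceTrajectory"))
  df <- data.frame(time = traj@times, traj@distances)
  names(df) <- c("time", paste(traj@pairs$i, traj@pairs$j, sep = "-"))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(pairs = traj@pairs, label = traj@label),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeDistanceTrajectory
#' @export
readDistanceTrajectory <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(file, ".json"),
                              simplifyVector = TRUE)
  new("DistanceTrajectory", times = df$time,
      pairs = as.data.frame(meta$pairs),
      distances = as.matrix(df[, -1, drop = FALSE]),
      label = meta$label)
}

#' Collective-variable definition I/O (JSON)
#'
#' @param cv a [CollectiveVariablePair-class].
#' @param file JSON path.
#' @return `writeCv`: the path, invisibly; `readCv`: the CV pair.
#' @export
writeCv <- function(cv, file) {
  stopifnot(is(cv, "CollectiveVariablePair"))
  jsonlite::write_json(
    list(cv1 = cv@cv1, cv2 = cv@cv2, normalization = cv@normalization),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeCv
#' @export
readCv <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  fix <- function(df) {
    if (!NROW(df)) data.frame(i = integer(0), j = integer(0),
                              weight = numeric(0))
    else as.data.frame(df)
  }
  new("CollectiveVariablePair", cv1 = fix(x$cv1), cv2 = fix(x$cv2),
      normalization = x$normalization)
}

#' Free-energy-surface I/O
#'
#' TSV of bin centers, energy and counts plus a JSON sidecar with the
#' edges, dimensionality and RT.
#'
#' @param fes a [FreeEnergySurface-class].
#' @param file TSV path.
#' @return `writeFes`: the path, invisibly; `readFes`: the surface.
#' @export
writeFes <- function(fes, file) {
  stopifnot(is(fes, "FreeEnergySurface"))
  ctr <- binCenters(fes)
  if (fes@dimension == 1L) {
    df <- data.frame(center1 = ctr[[1]],
                     energy = as.vector(fes@energy),
                     counts = as.vector(fes@counts))
  } else {
    grid <- expand.grid(i1 = seq_along(ctr[[1]]), i2 = seq_along(ctr[[2]]))
    df <- data.frame(center1 = ctr[[1]][grid$i1],
                     center2 = ctr[[2]][grid$i2],
                     energy = as.vector(fes@energy),
                     counts = as.vector(fes@counts))
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(dimension = fes@dimension, edges = fes@edges, rt = fes@rt),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeFes
#' @export
readFes <- function(file) {
  df <- utils::read.delim(file)
  meta <- jsonlite::read_json(paste0(file, ".json"),
                              simplifyVector = TRUE)
  if (!is.list(meta$edges)) meta$edges <- list(meta$edges)
  dims <- vapply(meta$edges, function(e) length(e) - 1L, 1L)
  shape <- if (meta$dimension == 1L) dims[1] else dims
  new("FreeEnergySurface", dimension = as.integer(meta$dimension),
      edges = lapply(meta$edges, as.numeric),
      energy = array(df$energy, shape),
      counts = array(df$counts, shape), rt = meta$rt)
}

#' Write false-positive pairs and their cluster manifest
#'
#' TSV of the pair table plus, when clustered, a JSON manifest of the
#' selection metadata and cluster membership.
#'
#' @param fp a [FalsePositivePairs-class].
#' @param file TSV path.
#' @return the path, invisibly.
#' @export
writeFalsePositives <- function(fp, file) {
  stopifnot(is(fp, "FalsePositivePairs"))
  utils::write.table(fp@pairs, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    c(fp@metadata, list(nPairs = nrow(fp@pairs))),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a coupling network as an edge list
#'
#' TSV with `res_i`, `res_j`, `coupling`, `cost`.
#'
#' @param net a [CouplingNetwork-class].
#' @param file TSV path.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(net, file) {
  stopifnot(is(net, "CouplingNetwork"))
  df <- data.frame(res_i = net@edges$from, res_j = net@edges$to,
                   coupling = net@edges$coupling, cost = net@edges$cost)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a basin report (JSON)
#'
#' @param basins a [BasinSet-class].
#' @param file JSON path.
#' @return the path, invisibly.
#' @export
writeBasinReport <- function(basins, file) {
  stopifnot(is(basins, "BasinSet"))
  jsonlite::write_json(list(basins = basins@basins), file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a convergence report (JSON)
#'
#' @param report output of [convergenceReport()].
#' @param file JSON path.
#' @return the path, invisibly.
#' @export
writeConvergenceReport <- function(report, file) {
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' Write per-residue centrality into a structure's B-factor column
#'
#' Visualisation helper: copies the structure and stores each residue's
#' betweenness centrality (scaled to 0-99) in its B-factor field.
#'
#' @param pdb a `bio3d` pdb object.
#' @param centrality named numeric vector (names = residue numbers).
#' @param file output PDB path.
#' @return the path, invisibly.
#' @export
writeCentralityPdb <- function(pdb, centrality, file) {
  stopifnot(inherits(pdb, "pdb"))
  b <- centrality[as.character(pdb$atom$resno)]
  b[is.na(b)] <- 0
  mx <- max(b)
  if (mx > 0) b <- b / mx * 99
  bio3d::write.pdb(pdb, file = file, b = b)
  invisible(file)
}
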