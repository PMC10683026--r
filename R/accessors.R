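## Accessors and show() methods. Slot access from user code is discouraged;
## these are the supported surface.

#' @name accessors
#' @title Accessors for CoevCV classes
#' @description Small family of getters: alignment content and column maps,
#'   Potts parameters, score/distance/contact matrices, pair tables, CV
#'   weights, free-energy grids and network tables.
#' @param x,object an object of the documented class.
#' @param ... unused.
#' @return The slot content documented per method.
NULL

#' @rdname accessors
#' @export
setGeneric("msaMatrix", function(x) standardGeneric("msaMatrix"))
#' @rdname accessors
#' @export
setMethod("msaMatrix", "Msa", function(x) x@seqs)

#' @rdname accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))
#' @rdname accessors
#' @export
setMethod("seqIds", "Msa", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))
#' @rdname accessors
#' @export
setMethod("alignmentLength", "Msa", function(x) ncol(x@seqs))

#' @rdname accessors
#' @export
setGeneric("msaAlphabet", function(x) standardGeneric("msaAlphabet"))
#' @rdname accessors
#' @export
setMethod("msaAlphabet", "Msa", function(x) x@alphabet)

#' @rdname accessors
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))
#' @rdname accessors
#' @export
setMethod("columnMap", "Msa", function(x) x@columnMap)
#' @rdname accessors
#' @export
setMethod("columnMap", "CoevolutionMap", function(x) x@columnMap)

#' @rdname accessors
#' @export
setGeneric("pottsFields", function(x) standardGeneric("pottsFields"))
#' @rdname accessors
#' @export
setMethod("pottsFields", "PottsModel", function(x) x@v)

#' @rdname accessors
#' @export
setGeneric("pottsCouplings", function(x) standardGeneric("pottsCouplings"))
#' @rdname accessors
#' @export
setMethod("pottsCouplings", "PottsModel", function(x) x@w)

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setMethod("trainingLog", "PottsModel", function(x) x@trainingLog)

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setMethod("scoreMatrix", "CoevolutionMap", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("apcApplied", function(x) standardGeneric("apcApplied"))
#' @rdname accessors
#' @export
setMethod("apcApplied", "CoevolutionMap", function(x) x@apcApplied)

#' @rdname accessors
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))
#' @rdname accessors
#' @export
setMethod("distanceMatrix", "ContactMap", function(x) x@distances)
#' @rdname accessors
#' @export
setMethod("distanceMatrix", "DistanceTrajectory", function(x) x@distances)

#' @rdname accessors
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))
#' @rdname accessors
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@contacts)

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))
#' @rdname accessors
#' @export
setMethod("residueTable", "ContactMap", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setMethod("pairTable", "FalsePositivePairs", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("pairTable", "DistanceTrajectory", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("pairTable", "LinearStateModel", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setMethod("frameTimes", "DistanceTrajectory", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("coef", "LinearStateModel", function(object, ...)
  object@coefficients)

#' @rdname accessors
#' @export
setGeneric("pairRanking", function(x) standardGeneric("pairRanking"))
#' @rdname accessors
#' @export
setMethod("pairRanking", "LinearStateModel", function(x) x@ranking)

#' @rdname accessors
#' @param which 1 for CV_1 (positive coefficients), 2 for CV_2 (negative).
#' @export
setGeneric("cvWeights", function(x, which = 1L) standardGeneric("cvWeights"))
#' @rdname accessors
#' @export
setMethod("cvWeights", "CollectiveVariablePair", function(x, which = 1L) {
  stopifnot(which %in% c(1L, 2L))
  if (which == 1L) x@cv1 else x@cv2
})

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setMethod("binEdges", "FreeEnergySurface", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("binEnergies", function(x) standardGeneric("binEnergies"))
#' @rdname accessors
#' @export
setMethod("binEnergies", "FreeEnergySurface", function(x) x@energy)

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setMethod("binCounts", "FreeEnergySurface", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("surfaceRT", function(x) standardGeneric("surfaceRT"))
#' @rdname accessors
#' @export
setMethod("surfaceRT", "FreeEnergySurface", function(x) x@rt)

#' @rdname accessors
#' @export
setGeneric("basinTable", function(x) standardGeneric("basinTable"))
#' @rdname accessors
#' @export
setMethod("basinTable", "BasinSet", function(x) x@basins)

#' @rdname accessors
#' @export
setGeneric("basinLabels", function(x) standardGeneric("basinLabels"))
#' @rdname accessors
#' @export
setMethod("basinLabels", "BasinSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("walkerCounts", function(x) standardGeneric("walkerCounts"))
#' @rdname accessors
#' @export
setMethod("walkerCounts", "WalkerHistograms", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("targetDistribution",
           function(x) standardGeneric("targetDistribution"))
#' @rdname accessors
#' @export
setMethod("targetDistribution", "WalkerHistograms", function(x) x@target)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "CouplingNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "CouplingNetwork", function(x) x@nodes)

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: %d sequences x %d columns (alphabet size %d)\n",
              nrow(object@seqs), ncol(object@seqs), length(object@alphabet)))
  if (length(object@columnMap))
    cat(sprintf("  original columns %d..%d retained\n",
                min(object@columnMap), max(object@columnMap)))
})

setMethod("show", "PottsModel", function(object) {
  cat(sprintf("PottsModel: L = %d, q = %d\n", nrow(object@v), object@q))
  ll <- object@trainingLog$loss
  if (length(ll))
    cat(sprintf("  %d iterations, loss %.4f -> %.4f\n",
                length(ll), ll[1], ll[length(ll)]))
})

setMethod("show", "CoevolutionMap", function(object) {
  cat(sprintf("CoevolutionMap: %d x %d, APC %s\n",
              nrow(object@scores), ncol(object@scores),
              if (object@apcApplied) "applied" else "not applied"))
})

setMethod("show", "ContactMap", function(object) {
  n <- nrow(object@residues)
  cat(sprintf(
    "ContactMap: %d residues, cutoff %.1f A, |i-j| >= %d: %d contacts\n",
    n, object@cutoff, object@minSeqSep,
    sum(object@contacts[upper.tri(object@contacts)], na.rm = TRUE)))
})

setMethod("show", "FalsePositivePairs", function(object) {
  cat(sprintf("FalsePositivePairs: %d non-contacting high-score pairs\n",
              nrow(object@pairs)))
  if (nrow(object@pairs)) {
    cat(sprintf("  score range %.4g .. %.4g\n",
                min(object@pairs$score), max(object@pairs$score)))
    if ("cluster" %in% names(object@pairs))
      cat(sprintf("  clustered into %d clusters\n",
                  length(unique(object@pairs$cluster))))
  }
})

setMethod("show", "PullCoordinateSet", function(object) {
  cat(sprintf(
    "PullCoordinateSet: %d coordinates, k = %g kJ/mol/nm^2, target %g nm\n",
    length(object@clusters), object@forceConstant, object@target))
})

setMethod("show", "DistanceTrajectory", function(object) {
  cat(sprintf("DistanceTrajectory '%s': %d frames x %d pairs (nm)\n",
              object@label, nrow(object@distances), nrow(object@pairs)))
})

setMethod("show", "LinearStateModel", function(object) {
  cat(sprintf("LinearStateModel: %d pairs, |coef| max %.4g\n",
              length(object@coefficients),
              if (length(object@coefficients))
                max(abs(object@coefficients)) else NA_real_))
})

setMethod("show", "CollectiveVariablePair", function(object) {
  cat(sprintf("CollectiveVariablePair: CV_1 %d pairs, CV_2 %d pairs\n",
              nrow(object@cv1), nrow(object@cv2)))
})

setMethod("show", "FreeEnergySurface", function(object) {
  cat(sprintf(
    "FreeEnergySurface: %d-D, %s bins, %d visited, RT = %.4f kJ/mol\n",
    object@dimension,
    paste(vapply(object@edges, function(e) length(e) - 1L, 1L),
          collapse = " x "),
    sum(is.finite(object@energy)), object@rt))
})

setMethod("show", "BasinSet", function(object) {
  cat(sprintf("BasinSet: %d basins\n", nrow(object@basins)))
  if (nrow(object@basins)) print(object@basins, row.names = FALSE)
})

setMethod("show", "WalkerHistograms", function(object) {
  cat(sprintf("WalkerHistograms: %d walkers x %d bins (grid %s)\n",
              nrow(object@counts), ncol(object@counts),
              paste(object@gridDim, collapse = " x ")))
})

setMethod("show", "CouplingNetwork", function(object) {
  cat(sprintf("CouplingNetwork: %d nodes, %d edges (cost = %s)\n",
              length(object@nodes), nrow(object@edges),
              object@costTransform))
})
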