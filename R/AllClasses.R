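## S4 classes for the coevolution -> collective-variable -> free-energy
## pipeline. Validity methods enforce the structural invariants that the
## numerical code relies on; user code should go through the accessors.

#' @import methods
NULL

## Amino-acid alphabet: 20 residues plus the gap symbol as an explicit
## 21st state. The gap MUST stay last: couplingMatrix() reduces over the
## leading 20x20 block only.
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Multiple sequence alignment container
#'
#' Stores an alignment as an integer matrix over the 20 amino acids plus
#' gap (state 21), together with the mapping from retained columns back to
#' the original alignment numbering. Build one with [readMsa()] and trim
#' gappy columns with [filterColumns()].
#'
#' @slot seqs integer matrix, sequences x positions, values in `1:21`.
#' @slot ids character vector of record identifiers.
#' @slot columnMap integer vector; `columnMap[k]` is the original (1-based)
#'   alignment column behind retained column `k`. Strictly increasing.
#' @slot alphabet character vector of state symbols (gap last).
#' @export
setClass("Msa", representation(
  seqs = "matrix", ids = "character",
  columnMap = "integer", alphabet = "character"
))

setValidity("Msa", function(object) {
  msgs <- character()
  q <- length(object@alphabet)
  if (!is.integer(object@seqs[1]) && length(object@seqs))
    msgs <- c(msgs, "seqs must be an integer matrix")
  if (length(object@ids) != nrow(object@seqs))
    msgs <- c(msgs, "one id per sequence required")
  if (length(object@columnMap) != ncol(object@seqs))
    msgs <- c(msgs, "columnMap length must equal the alignment length")
  if (length(object@columnMap) > 1 && any(diff(object@columnMap) <= 0))
    msgs <- c(msgs, "columnMap must be strictly increasing")
  if (length(object@seqs) &&
      (min(object@seqs) < 1L || max(object@seqs) > q))
    msgs <- c(msgs, sprintf("sequence states must lie in 1..%d", q))
  if (length(msgs)) msgs else TRUE
})

#' Per-sequence weights for redundancy correction
#'
#' Numeric vector of weights in (0, 1]; a sequence with no neighbour above
#' the identity threshold carries weight exactly 1. Created by
#' [sequenceWeights()].
#'
#' @slot .Data numeric weights.
#' @slot threshold the identity threshold used.
#' @export
setClass("SequenceWeights", contains = "numeric",
         representation(threshold = "numeric"))

setValidity("SequenceWeights", function(object) {
  if (any(object@.Data <= 0 | object@.Data > 1))
    return("weights must lie in (0, 1]")
  TRUE
})

#' Potts model fitted by pseudo-likelihood
#'
#' Fields `v` (position x state) and couplings `w` (position-pair x state x
#' state) of a Markov random field over aligned sequences, fitted with
#' [fitPotts()]. Couplings satisfy `w[i,j,a,b] == w[j,i,b,a]`.
#'
#' @slot q alphabet size including the gap state.
#' @slot v numeric matrix L x q of per-position fields.
#' @slot w numeric 4-d array L x L x q x q of pairwise couplings.
#' @slot trainingLog list with per-iteration loss, seed and hyperparameters.
#' @export
setClass("PottsModel", representation(
  q = "integer", v = "matrix", w = "array", trainingLog = "list"
))

setValidity("PottsModel", function(object) {
  msgs <- character()
  L <- nrow(object@v)
  q <- object@q
  if (ncol(object@v) != q) msgs <- c(msgs, "v must be L x q")
  if (!identical(dim(object@w), c(L, L, q, q)))
    msgs <- c(msgs, "w must be L x L x q x q")
  else if (max(abs(object@w - aperm(object@w, c(2, 1, 4, 3)))) > 1e-8)
    msgs <- c(msgs, "w must satisfy w[i,j,a,b] == w[j,i,b,a]")
  if (length(msgs)) msgs else TRUE
})

#' Residue-pair coevolution score matrix
#'
#' Symmetric L x L matrix of coupling strengths, optionally after average
#' product correction, with the column map back to the original alignment
#' numbering. Produced by [couplingMatrix()] and [apc()].
#'
#' @slot scores symmetric numeric matrix, zero diagonal.
#' @slot apcApplied logical flag.
#' @slot columnMap integer map retained column -> original alignment column.
#' @export
setClass("CoevolutionMap", representation(
  scores = "matrix", apcApplied = "logical", columnMap = "integer"
))

setValidity("CoevolutionMap", function(object) {
  s <- object@scores
  msgs <- character()
  if (nrow(s) != ncol(s)) msgs <- c(msgs, "scores must be square")
  if (any(!is.finite(s))) msgs <- c(msgs, "scores must be finite")
  if (nrow(s) && max(abs(s - t(s))) > 1e-8)
    msgs <- c(msgs, "scores must be symmetric")
  if (length(object@columnMap) &&
      length(object@columnMap) != nrow(s))
    msgs <- c(msgs, "columnMap must match matrix dimension")
  if (length(msgs)) msgs else TRUE
})

#' Structure-derived residue contact map
#'
#' Minimum heavy-atom inter-residue distances (Angstrom) plus the boolean
#' contact matrix under a distance cutoff and sequence-separation rule.
#'
#' @slot residues data.frame with columns `resno`, `chain`, `resid`
#'   (author numbering carried verbatim).
#' @slot distances symmetric numeric matrix of minimum heavy-atom
#'   distances in Angstrom; `NA` where a residue lacks heavy atoms.
#' @slot cutoff contact cutoff in Angstrom.
#' @slot minSeqSep minimum sequence separation `|i - j|` for a contact.
#' @slot contacts logical matrix; TRUE iff distance <= cutoff and the
#'   separation rule holds.
#' @export
setClass("ContactMap", representation(
  residues = "data.frame", distances = "matrix",
  cutoff = "numeric", minSeqSep = "numeric", contacts = "matrix"
))

setValidity("ContactMap", function(object) {
  d <- object@distances
  msgs <- character()
  if (nrow(d) != nrow(object@residues))
    msgs <- c(msgs, "distance matrix must match residue table")
  if (nrow(d) && max(abs(d - t(d)), na.rm = TRUE) > 1e-8)
    msgs <- c(msgs, "distances must be symmetric")
  if (any(d < 0, na.rm = TRUE)) msgs <- c(msgs, "distances must be >= 0")
  if (object@cutoff <= 0) msgs <- c(msgs, "cutoff must be positive")
  if (length(msgs)) msgs else TRUE
})

#' High-scoring residue pairs absent from the reference structure
#'
#' The coevolving pairs whose minimum heavy-atom distance exceeds the
#' contact criterion ("false positives" of contact prediction), sorted by
#' decreasing coupling score. Optionally carries a cluster assignment.
#'
#' @slot pairs data.frame with columns `i`, `j` (structure row indices),
#'   `resnoI`, `resnoJ` (author numbering), `score`, `distance` (Angstrom)
#'   and, after clustering, `cluster`.
#' @slot metadata list describing the selection rule (top-N, cutoff, ...).
#' @export
setClass("FalsePositivePairs", representation(
  pairs = "data.frame", metadata = "list"
))

#' Steering (pull) coordinate set built from pair clusters
#'
#' One coordinate per coevolution-strength cluster: a weighted mean of the
#' member pair distances, with per-contact force constant and target
#' distance for the MD engine.
#'
#' @slot clusters list of data.frames (`i`, `j`, `resnoI`, `resnoJ`,
#'   `score`, `weight`); weights sum to 1 within each cluster.
#' @slot forceConstant per-contact force constant, kJ mol^-1 nm^-2.
#' @slot target target distance, nm.
#' @export
setClass("PullCoordinateSet", representation(
  clusters = "list", forceConstant = "numeric", target = "numeric"
))

setValidity("PullCoordinateSet", function(object) {
  msgs <- character()
  if (object@forceConstant <= 0) msgs <- c(msgs, "force constant must be > 0")
  if (object@target <= 0) msgs <- c(msgs, "target distance must be > 0")
  for (cl in object@clusters)
    if (abs(sum(cl$weight) - 1) > 1e-8) {
      msgs <- c(msgs, "cluster weights must sum to 1")
      break
    }
  if (length(msgs)) msgs else TRUE
})

#' Per-frame inter-residue distance features
#'
#' Frames x pairs matrix of minimum inter-residue distances in nm, the
#' tracked-pair manifest, and frame times.
#'
#' @slot times numeric frame times (arbitrary units).
#' @slot pairs data.frame with columns `i`, `j` (and optional labels);
#'   free of duplicates.
#' @slot distances numeric matrix frames x pairs, nm, finite and >= 0.
#' @slot label character source label (e.g. which ensemble).
#' @export
setClass("DistanceTrajectory", representation(
  times = "numeric", pairs = "data.frame",
  distances = "matrix", label = "character"
))

setValidity("DistanceTrajectory", function(object) {
  msgs <- character()
  if (ncol(object@distances) != nrow(object@pairs))
    msgs <- c(msgs, "one pair per distance column required")
  if (length(object@times) != nrow(object@distances))
    msgs <- c(msgs, "one time per frame required")
  if (any(!is.finite(object@distances)) || any(object@distances < 0))
    msgs <- c(msgs, "distances must be finite and >= 0")
  key <- paste(object@pairs$i, object@pairs$j)
  if (anyDuplicated(key)) msgs <- c(msgs, "duplicate pairs not allowed")
  if (length(msgs)) msgs else TRUE
})

#' Linear maximum-margin state classifier
#'
#' Coefficients of a linear support-vector separator between two
#' conformational ensembles, in standardized feature space, with the
#' stored scaler and the ranking of pairs by absolute coefficient.
#'
#' @slot coefficients named numeric, one per pair.
#' @slot intercept numeric scalar.
#' @slot scalerCenter,scalerScale the per-feature standardization.
#' @slot ranking integer permutation ordering pairs by |coefficient|
#'   (ties broken by pair label).
#' @slot pairs data.frame pair manifest matching `coefficients`.
#' @slot metadata list (regularization, seed, class sizes, accuracy).
#' @export
setClass("LinearStateModel", representation(
  coefficients = "numeric", intercept = "numeric",
  scalerCenter = "numeric", scalerScale = "numeric",
  ranking = "integer", pairs = "data.frame", metadata = "list"
))

setValidity("LinearStateModel", function(object) {
  msgs <- character()
  p <- length(object@coefficients)
  if (length(object@ranking) != p ||
      !setequal(object@ranking, seq_len(p)))
    msgs <- c(msgs, "ranking must be a permutation of the pairs")
  if (nrow(object@pairs) != p)
    msgs <- c(msgs, "pair manifest must match coefficients")
  if (length(msgs)) msgs else TRUE
})

#' Pair of collective variables from a linear classifier
#'
#' CV_1 collects the positive-coefficient pairs, CV_2 the
#' negative-coefficient pairs (absolute weights); each CV evaluates as a
#' weighted sum of pair distances with weights renormalized to 1.
#'
#' @slot cv1,cv2 data.frames with columns `i`, `j`, `weight` (> 0).
#' @slot normalization character, how weights were normalized.
#' @export
setClass("CollectiveVariablePair", representation(
  cv1 = "data.frame", cv2 = "data.frame", normalization = "character"
))

setValidity("CollectiveVariablePair", function(object) {
  msgs <- character()
  for (cv in list(object@cv1, object@cv2))
    if (nrow(cv) && any(cv$weight <= 0)) {
      msgs <- c(msgs, "CV weights must be strictly positive")
      break
    }
  k1 <- paste(object@cv1$i, object@cv1$j)
  k2 <- paste(object@cv2$i, object@cv2$j)
  if (length(intersect(k1, k2)))
    msgs <- c(msgs, "CV_1 and CV_2 pair sets must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Binned free-energy surface
#'
#' Free energies U = -RT log(p) on a 1-D or 2-D grid, anchored so the
#' lowest visited bin is 0. Never-visited bins are masked (`NA` energy)
#' and carry no population.
#'
#' @slot dimension 1 or 2.
#' @slot edges list of bin-edge vectors, one per axis.
#' @slot energy numeric vector (1-D) or matrix (2-D), kJ/mol; `NA` where
#'   masked.
#' @slot counts frame counts per bin, same shape.
#' @slot rt RT in kJ/mol.
#' @export
setClass("FreeEnergySurface", representation(
  dimension = "integer", edges = "list",
  energy = "array", counts = "array", rt = "numeric"
))

setValidity("FreeEnergySurface", function(object) {
  msgs <- character()
  if (!object@dimension %in% c(1L, 2L))
    msgs <- c(msgs, "dimension must be 1 or 2")
  if (length(object@edges) != object@dimension)
    msgs <- c(msgs, "one edge vector per axis required")
  u <- object@energy
  if (any(is.finite(u)) && abs(min(u, na.rm = TRUE)) > 1e-8)
    msgs <- c(msgs, "energies must be anchored (min over visited bins = 0)")
  if (object@rt <= 0) msgs <- c(msgs, "RT must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Basins of a free-energy surface
#'
#' Disjoint basins grown from local minima, each with at least `minBins`
#' member bins, Boltzmann population fractions (summing to 1 over assigned
#' bins) and optional functional state labels.
#'
#' @slot labels integer array matching the surface grid; `NA` = unassigned.
#' @slot basins data.frame: `id`, `minBin` (flat index of the minimum),
#'   `nBins`, `minEnergy`, `population`, and (after classification)
#'   `state` in {resting, active} and `subLabel`.
#' @export
setClass("BasinSet", representation(
  labels = "array", basins = "data.frame"
))

#' Per-walker visit histograms on a shared grid
#'
#' @slot counts numeric matrix walkers x bins (grids flattened
#'   column-major), non-negative.
#' @slot target target probability per bin (default uniform), sums to 1.
#' @slot gridDim integer vector, the underlying grid shape.
#' @export
setClass("WalkerHistograms", representation(
  counts = "matrix", target = "numeric", gridDim = "integer"
))

setValidity("WalkerHistograms", function(object) {
  msgs <- character()
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (length(object@target) != ncol(object@counts))
    msgs <- c(msgs, "target must have one entry per bin")
  if (abs(sum(object@target) - 1) > 1e-8)
    msgs <- c(msgs, "target must sum to 1")
  if (prod(object@gridDim) != ncol(object@counts))
    msgs <- c(msgs, "gridDim inconsistent with bin count")
  if (length(msgs)) msgs else TRUE
})

#' Residue-level energetic-coupling network
#'
#' Undirected graph whose edge weights are energetic couplings (kJ/mol)
#' from per-pair free-energy projections, with the edge-cost transform
#' used for path analysis.
#'
#' @slot edges data.frame: `from`, `to` (residue labels), `coupling`
#'   (kJ/mol, >= 0), `cost`.
#' @slot nodes character vector of residue labels.
#' @slot costTransform "inverse" (1/(w + eps)) or "max_minus"
#'   (max(w) - w + eps).
#' @slot epsilon numeric regularizer of the cost transform.
#' @export
setClass("CouplingNetwork", representation(
  edges = "data.frame", nodes = "character",
  costTransform = "character", epsilon = "numeric"
))

setValidity("CouplingNetwork", function(object) {
  msgs <- character()
  if (nrow(object@edges)) {
    if (any(object@edges$coupling < 0))
      msgs <- c(msgs, "couplings must be >= 0")
    if (any(object@edges$from == object@edges$to))
      msgs <- c(msgs, "self-edges not allowed")
  }
  if (length(msgs)) msgs else TRUE
})
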