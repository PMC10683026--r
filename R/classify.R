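## Functional labelling of basins by structural similarity to an active
## reference: rigid-body superposition on a shared C-alpha selection, then
## RMSD over a marker helix (TM6 in the GPCR application).

## Coerce a frame to a C-alpha coordinate table (resno, x, y, z; Angstrom).
.caTable <- function(frame) {
  if (inherits(frame, "pdb")) {
    sel <- bio3d::atom.select(frame, elety = "CA", verbose = FALSE)
    at <- frame$atom[sel$atom, , drop = FALSE]
    data.frame(resno = at$resno, x = at$x, y = at$y, z = at$z)
  } else {
    tb <- as.data.frame(frame)
    stopifnot(all(c("resno", "x", "y", "z") %in% names(tb)))
    tb[!duplicated(tb$resno), c("resno", "x", "y", "z")]
  }
}

## Kabsch superposition of P onto Q (n x 3 each, matched rows); returns
## the transformed P.
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P0 %*% t(R), 2, cq, "+")
}

#' Classify frames as active or resting by marker-helix RMSD
#'
#' Each frame is rigidly superposed onto the reference structure using
#' the C-alpha atoms of `alignResidues` (default: all residues shared
#' with the reference), then the C-alpha RMSD over `rmsdResidues`
#' (default 269-298, the TM6 helix in the GPCR application) is computed.
#' A basin whose mean RMSD is strictly below `cutoff` (default 3.0
#' Angstrom) is labelled "active", otherwise "resting".
#'
#' @param frames list of frames: `bio3d` pdb objects or coordinate tables
#'   with columns `resno`, `x`, `y`, `z` (Angstrom; one C-alpha per
#'   residue, or full atoms for pdb input).
#' @param reference the active reference structure (same forms).
#' @param rmsdResidues residue numbers of the marker selection
#'   (default `269:298`).
#' @param alignResidues residue numbers for superposition (default:
#'   all residues shared by frame and reference).
#' @param cutoff classification cutoff in Angstrom (default 3.0,
#'   strict "below" for the active label).
#' @return list with `state` ("active"/"resting"), `meanRmsd`,
#'   `rmsd` (per frame), `cutoff`, `rmsdResidues`, `alignResidues`.
#' @export
classifyBasinState <- function(frames, reference,
                               rmsdResidues = 269:298,
                               alignResidues = NULL, cutoff = 3.0) {
  stopifnot(length(frames) >= 1, cutoff > 0)
  ref <- .caTable(reference)
  rmsd <- vapply(frames, function(fr) {
    tb <- .caTable(fr)
    shared <- intersect(tb$resno, ref$resno)
    alignSel <- if (is.null(alignResidues)) shared
                else intersect(alignResidues, shared)
    rmsdSel <- intersect(rmsdResidues, shared)
    if (length(alignSel) < 3L)
      stop("alignment selection has fewer than 3 shared residues")
    if (!length(rmsdSel))
      stop("RMSD selection is empty after mapping onto the frames")
    P <- as.matrix(tb[match(shared, tb$resno), c("x", "y", "z")])
    Q <- as.matrix(ref[match(shared, ref$resno), c("x", "y", "z")])
    ai <- match(alignSel, shared)
    ## superpose on the alignment selection, apply to all shared atoms
    cp <- colMeans(P[ai, , drop = FALSE])
    cq <- colMeans(Q[ai, , drop = FALSE])
    s <- svd(crossprod(sweep(P[ai, , drop = FALSE], 2, cp),
                       sweep(Q[ai, , drop = FALSE], 2, cq)))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    Pfit <- sweep(sweep(P, 2, cp) %*% t(R), 2, cq, "+")
    ri <- match(rmsdSel, shared)
    sqrt(mean(rowSums((Pfit[ri, , drop = FALSE] -
                       Q[ri, , drop = FALSE])^2)))
  }, numeric(1))
  m <- mean(rmsd)
  list(state = if (m < cutoff) "active" else "resting",
       meanRmsd = m, rmsd = rmsd, cutoff = cutoff,
       rmsdResidues = rmsdResidues, alignResidues = alignResidues)
}

#' Attach functional states to a basin set
#'
#' Runs [classifyBasinState()] per basin on the supplied frame lists and
#' writes the labels into the basin table.
#'
#' @param basins a [BasinSet-class].
#' @param framesByBasin list (one entry per basin id) of frame lists.
#' @param reference,... passed to [classifyBasinState()].
#' @return the BasinSet with `state` and `meanRmsd` columns.
#' @export
assignBasinStates <- function(basins, framesByBasin, reference, ...) {
  stopifnot(is(basins, "BasinSet"),
            length(framesByBasin) == nrow(basins@basins))
  res <- lapply(framesByBasin, classifyBasinState, reference = reference,
                ...)
  basins@basins$state <- vapply(res, `[[`, "", "state")
  basins@basins$meanRmsd <- vapply(res, `[[`, numeric(1), "meanRmsd")
  basins
}
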