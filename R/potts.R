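## Pseudo-likelihood Potts model (direct coupling analysis).
##
## The model assigns each aligned sequence x a probability proportional to
## exp( sum_i v[i, x_i] + sum_{i<j} w[i, j, x_i, x_j] ). Fitting maximises
## the weighted pseudo-likelihood: the product over positions i of the
## conditional probability of x_i given the rest of the sequence, which
## avoids the intractable partition function (only the per-position
## normalizer over q states remains).
##
## Internally sequences are one-hot encoded into a sparse N x (L*q) design
## matrix X and the couplings live in a symmetric (L*q) x (L*q) block
## matrix W with zero diagonal blocks, so all conditional logits are a
## single sparse matrix product X %*% W.

## One-hot encoding of an integer state matrix (N x L, states 1..q).
.oneHot <- function(m, q) {
  n <- nrow(m)
  L <- ncol(m)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), L),
    j = (rep(seq_len(L), each = n) - 1L) * q + as.vector(m),
    x = 1, dims = c(n, L * q))
}

## Zero the L diagonal q x q blocks of an (Lq x Lq) matrix in place.
.zeroDiagBlocks <- function(W, L, q) {
  for (i in seq_len(L)) {
    idx <- (i - 1L) * q + seq_len(q)
    W[idx, idx] <- 0
  }
  W
}

## Loss and gradient of the weighted negative log pseudo-likelihood with
## L2 penalties. v is L x q, W the symmetric coupling matrix.
## Returns list(loss, gradV (L x q), gradW (Lq x Lq, symmetric)).
.plmObjective <- function(v, W, X, states, wts, lambdaV, lambdaW,
                          gradient = TRUE) {
  L <- nrow(v)
  q <- ncol(v)
  n <- nrow(states)
  vflat <- as.vector(t(v))                      # (i-1)*q + a ordering
  logits <- as.matrix(X %*% W)
  logits <- logits + rep(vflat, each = n)
  A <- array(logits, c(n, q, L))
  ## blockwise log-sum-exp over the q states of each position
  M <- A[, 1L, ]
  for (a in 2:q) M <- pmax(M, A[, a, ])
  S <- array(0, c(n, L))
  P <- A
  for (a in seq_len(q)) {
    P[, a, ] <- exp(A[, a, ] - M)
    S <- S + P[, a, ]
  }
  logZ <- M + log(S)                            # n x L
  trueCols <- (rep(seq_len(L), each = n) - 1L) * q + as.vector(states)
  trueLogit <- logits[cbind(rep(seq_len(n), L), trueCols)]
  nll <- rowSums(logZ) - rowSums(matrix(trueLogit, n, L))
  loss <- sum(wts * nll) +
    lambdaV * sum(v^2) + (lambdaW / 2) * sum(W^2)
  if (!is.finite(loss))
    stop("non-finite pseudo-likelihood loss; check parameters ",
         "(max |v| = ", signif(max(abs(v)), 3),
         ", max |w| = ", signif(max(abs(W)), 3), ")")
  if (!gradient) return(list(loss = loss))
  for (a in seq_len(q)) P[, a, ] <- P[, a, ] / S  # softmax
  D <- matrix(P, n, L * q)
  D <- (D - as.matrix(X)) * wts
  gradV <- matrix(colSums(D), q, L)              # q x L, transpose below
  gradV <- t(gradV) + 2 * lambdaV * v
  ## W stores each coupling twice (w[i,j,a,b] at [(i,a),(j,b)] and
  ## [(j,b),(i,a)]); the tied-parameter gradient sums both conditionals
  ## and doubles the penalty term, giving a symmetric gradient matrix
  ## whose [r,c] entry is d(loss)/d(coupling behind entry [r,c]).
  G <- as.matrix(Matrix::crossprod(X, D))
  gradW <- G + t(G)
  gradW <- .zeroDiagBlocks(gradW, L, q)
  gradW <- gradW + 2 * lambdaW * W
  list(loss = loss, gradV = gradV, gradW = gradW)
}

#' Fit a Potts model by pseudo-likelihood maximisation
#'
#' Minimises the weighted negative log pseudo-likelihood of the alignment
#' with the Adam optimizer. Gaps are modelled as an explicit 21st state.
#' A small L2 penalty on fields and couplings keeps the problem well posed
#' (the coupling penalty is scaled with alignment length and alphabet size
#' following common practice for pseudo-likelihood DCA).
#'
#' The default protocol (300 iterations at learning rate 1e-4, parameters
#' initialised from N(0, 1)) mirrors the reference analysis of deep PFAM
#' alignments. For small or synthetic alignments a larger learning rate
#' and a near-zero initialisation converge much further; see the package
#' vignette.
#'
#' @param msa an [Msa-class] object.
#' @param weights [SequenceWeights-class] or numeric vector (default: all 1).
#' @param iterations number of Adam iterations (default 300).
#' @param learningRate Adam step size (default 1e-4).
#' @param seed RNG seed for the random initialisation; recorded in the
#'   training log.
#' @param initSd standard deviation of the normal initialisation
#'   (default 1; 0 gives a deterministic zero start).
#' @param lambdaV,lambdaW L2 penalty weights for fields and couplings.
#'   `lambdaW = NULL` (default) uses `0.01 * (L - 1) * q / 2`.
#' @return a [PottsModel-class]; `trainingLog(model)$loss` holds the loss
#'   per iteration.
#' @examples
#' msa <- msaFromStrings(c("ACDE", "ACDE", "AKDE", "CCDE"))
#' m <- fitPotts(msa, iterations = 20, learningRate = 0.05, initSd = 0)
#' tail(trainingLog(m)$loss, 1) < trainingLog(m)$loss[1]
#' @seealso [couplingMatrix()], [apc()], [gibbsSampleMsa()]
#' @export
fitPotts <- function(msa, weights = NULL, iterations = 300,
                     learningRate = 1e-4, seed = 1L, initSd = 1,
                     lambdaV = 0.01, lambdaW = NULL) {
  stopifnot(is(msa, "Msa"), nrow(msa@seqs) > 0, iterations >= 1)
  states <- msa@seqs
  n <- nrow(states)
  L <- ncol(states)
  q <- length(msa@alphabet)
  if (is.null(weights)) weights <- rep(1, n)
  wts <- as.numeric(weights)
  if (length(wts) != n)
    stop("weights must align with the MSA (", n, " sequences)")
  if (is.null(lambdaW)) lambdaW <- 0.01 * (L - 1) * q / 2
  X <- .oneHot(states, q)

  init <- .withSeed(seed, list(
    v = matrix(stats::rnorm(L * q, sd = initSd), L, q),
    W = matrix(stats::rnorm(L * q * L * q, sd = initSd), L * q, L * q)))
  v <- init$v
  W <- init$W
  W <- (W + t(W)) / 2
  W <- .zeroDiagBlocks(W, L, q)

  ## Adam state
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  mV <- uV <- matrix(0, L, q)
  mW <- uW <- matrix(0, L * q, L * q)
  lossLog <- numeric(iterations)
  for (it in seq_len(iterations)) {
    obj <- .plmObjective(v, W, X, states, wts, lambdaV, lambdaW)
    lossLog[it] <- obj$loss
    mV <- b1 * mV + (1 - b1) * obj$gradV
    uV <- b2 * uV + (1 - b2) * obj$gradV^2
    mW <- b1 * mW + (1 - b1) * obj$gradW
    uW <- b2 * uW + (1 - b2) * obj$gradW^2
    corr1 <- 1 - b1^it
    corr2 <- 1 - b2^it
    v <- v - learningRate * (mV / corr1) / (sqrt(uV / corr2) + eps)
    W <- W - learningRate * (mW / corr1) / (sqrt(uW / corr2) + eps)
    W <- .zeroDiagBlocks(W, L, q)   # diagonal blocks stay exactly zero
  }
  ## (Lq x Lq) -> (a, i, b, j) -> (i, j, a, b)
  wArr <- aperm(array(W, c(q, L, q, L)), c(2, 4, 1, 3))
  new("PottsModel", q = as.integer(q), v = v, w = wArr,
      trainingLog = list(
        loss = lossLog, seed = seed,
        hyperparameters = list(
          iterations = iterations, learningRate = learningRate,
          initSd = initSd, lambdaV = lambdaV, lambdaW = lambdaW,
          adam = c(beta1 = b1, beta2 = b2, epsilon = eps))))
}

#' Reduce pairwise couplings to a residue-pair score matrix
#'
#' Collapses each pair's coupling block over the 20 x 20 non-gap states to
#' a scalar coevolution strength. The default reduction is the Frobenius
#' norm; `"abs_sum"` sums absolute values instead (a plain signed sum is
#' deliberately not offered because opposite-sign couplings would cancel).
#'
#' @param model a fitted [PottsModel-class].
#' @param reduction "frobenius" (default) or "abs_sum".
#' @param columnMap optional integer map back to original alignment
#'   columns (defaults to 1..L).
#' @return a [CoevolutionMap-class] with `apcApplied = FALSE`.
#' @export
couplingMatrix <- function(model, reduction = c("frobenius", "abs_sum"),
                           columnMap = NULL) {
  stopifnot(is(model, "PottsModel"))
  reduction <- match.arg(reduction)
  L <- nrow(model@v)
  ngap <- seq_len(model@q - 1L)       # gap is the last state by convention
  s <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    b <- model@w[i, j, ngap, ngap]
    s[i, j] <- if (reduction == "frobenius") sqrt(sum(b^2)) else sum(abs(b))
  }
  s <- (s + t(s)) / 2                  # numerically exact symmetry
  if (is.null(columnMap)) columnMap <- seq_len(L)
  new("CoevolutionMap", scores = s, apcApplied = FALSE,
      columnMap = as.integer(columnMap))
}

#' Average product correction
#'
#' Removes the multiplicative row/column background from a symmetric score
#' matrix: `S'_ij = S_ij - mean_i * mean_j / mean_all`. For coevolution
#' maps (zero diagonal) the means exclude the diagonal, the standard DCA
#' convention; for raw matrices the diagonal can be included, in which
#' case any rank-one positive matrix is annihilated exactly. An all-zero
#' matrix (zero total) is returned unchanged.
#'
#' @param x a symmetric numeric matrix or a [CoevolutionMap-class].
#' @param excludeDiagonal logical; for matrices, whether row/column means
#'   skip the diagonal (default TRUE, matching coevolution-map usage).
#' @param ... passed between methods.
#' @return same class as the input, corrected; for maps `apcApplied` is
#'   set to TRUE.
#' @examples
#' u <- c(1, 2, 3)
#' max(abs(apc(outer(u, u), excludeDiagonal = FALSE)))  # ~0
#' @export
setGeneric("apc", function(x, ...) standardGeneric("apc"))

#' @rdname apc
#' @export
setMethod("apc", "matrix", function(x, excludeDiagonal = TRUE, ...) {
  stopifnot(nrow(x) == ncol(x))
  if (nrow(x) && max(abs(x - t(x))) > 1e-8)
    stop("apc() requires a symmetric matrix")
  L <- nrow(x)
  if (L < 2L) return(x)
  if (excludeDiagonal) {
    rmean <- (rowSums(x) - diag(x)) / (L - 1)
    gmean <- (sum(x) - sum(diag(x))) / (L * (L - 1))
  } else {
    rmean <- rowMeans(x)
    gmean <- mean(x)
  }
  if (abs(gmean) < .Machine$double.eps) return(x)  # all-zero guard
  out <- x - outer(rmean, rmean) / gmean
  (out + t(out)) / 2
})

#' @rdname apc
#' @export
setMethod("apc", "CoevolutionMap", function(x, ...) {
  s <- apc(x@scores, excludeDiagonal = TRUE)
  diag(s) <- 0
  new("CoevolutionMap", scores = s, apcApplied = TRUE,
      columnMap = x@columnMap)
})

#' Rank residue pairs of a coevolution map
#'
#' @param map a [CoevolutionMap-class].
#' @param n number of top pairs to return (default all).
#' @return data.frame with columns `i`, `j` (retained-column indices),
#'   `origI`, `origJ` (original alignment columns) and `score`, sorted by
#'   decreasing score.
#' @export
topCouplings <- function(map, n = Inf) {
  stopifnot(is(map, "CoevolutionMap"))
  s <- map@scores
  L <- nrow(s)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], score = s[idx])
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  if (length(map@columnMap)) {
    df$origI <- map@columnMap[df$i]
    df$origJ <- map@columnMap[df$j]
  }
  rownames(df) <- NULL
  utils::head(df, n)
}
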