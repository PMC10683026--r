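## Alignment input and preprocessing for the coevolution analysis.

## Encode aligned character sequences into the integer state matrix.
## Unknown symbols (B, X, Z, ...) are conservatively mapped to the gap
## state; '.' (and lowercase insert-state letters, once uppercased) are
## treated like their standard equivalents.
.encodeAlignment <- function(seqs, ids) {
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("alignment error: ragged sequence lengths (",
         paste(unique(lens), collapse = ", "), ")")
  L <- lens[1]
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                  ncol = L, byrow = TRUE)
  states <- match(chars, .AA_ALPHABET)
  if (anyNA(states)) {
    bad <- sort(unique(chars[is.na(states)]))
    warning("unknown residue symbol(s) mapped to gap: ",
            paste(bad, collapse = ", "))
    states[is.na(states)] <- length(.AA_ALPHABET)
  }
  m <- matrix(as.integer(states), nrow = length(seqs), ncol = L)
  new("Msa", seqs = m, ids = ids, columnMap = seq_len(L),
      alphabet = .AA_ALPHABET)
}

## Minimal Stockholm reader: no pre-installed R package parses the format,
## so sequence lines (possibly wrapped over blocks) are accumulated by name.
.readStockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//")]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no sequences found in Stockholm file: ", path)
  parts <- regmatches(lines, regexpr("\\s+", lines), invert = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  agg <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                paste, "", collapse = "")
  list(ids = unique(ids), seqs = unname(agg[unique(ids)]))
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file into an [Msa-class] object over
#' the 20 amino acids plus gap. Symbols outside that alphabet are mapped to
#' the gap state with a warning; ragged lengths are an error. The original
#' column numbering is preserved in the column map so that downstream
#' coupling scores can always be reported in the input alignment's
#' coordinates.
#'
#' @param path path to the alignment file.
#' @param format "fasta" (default) or "stockholm".
#' @return an [Msa-class] object.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-D", ">b", "ACWD"), fa)
#' msa <- readMsa(fa)
#' alignmentLength(msa)
#' @seealso [filterColumns()], [sequenceWeights()], [fitPotts()]
#' @export
readMsa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    aa <- Biostrings::readBStringSet(path)
    if (!length(aa)) stop("no sequences found in FASTA file: ", path)
    .encodeAlignment(as.character(aa), names(aa))
  } else {
    st <- .readStockholm(path)
    .encodeAlignment(st$seqs, st$ids)
  }
}

#' Construct an Msa from character vectors
#'
#' Programmatic constructor used by the synthetic generators and tests.
#'
#' @param seqs character vector of aligned sequences (equal lengths).
#' @param ids optional record identifiers.
#' @return an [Msa-class] object.
#' @export
msaFromStrings <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  .encodeAlignment(seqs, ids)
}

#' Drop alignment columns with too many gaps
#'
#' Removes columns whose gap fraction exceeds `maxGapFraction` (default
#' 0.2, i.e. columns with more than 20% gaps are filtered). The column map
#' records the surviving columns' original indices.
#'
#' @param msa an [Msa-class] object.
#' @param maxGapFraction columns with gap fraction strictly above this are
#'   removed; in `[0, 1]`.
#' @return the filtered [Msa-class].
#' @export
filterColumns <- function(msa, maxGapFraction = 0.2) {
  stopifnot(is(msa, "Msa"),
            maxGapFraction >= 0, maxGapFraction <= 1)
  gap <- length(msa@alphabet)
  frac <- colMeans(msa@seqs == gap)
  keep <- frac <= maxGapFraction
  if (!any(keep))
    stop("no columns left after filtering at max gap fraction ",
         maxGapFraction)
  new("Msa", seqs = msa@seqs[, keep, drop = FALSE], ids = msa@ids,
      columnMap = msa@columnMap[keep], alphabet = msa@alphabet)
}

#' Redundancy-correcting sequence weights
#'
#' Each sequence n receives weight 1 / N, where N is the number of
#' sequences (including n itself) whose identity with n exceeds the
#' threshold. Identity is the fraction of matching columns over the full
#' alignment length; "over 90% identity" is implemented as a strict
#' inequality, so a sequence without any close neighbour has weight
#' exactly 1.
#'
#' @param msa an [Msa-class] object.
#' @param identityThreshold identity threshold in (0, 1); default 0.9.
#' @return a [SequenceWeights-class] numeric vector.
#' @export
sequenceWeights <- function(msa, identityThreshold = 0.9) {
  stopifnot(is(msa, "Msa"),
            identityThreshold > 0, identityThreshold < 1)
  m <- msa@seqs
  n <- nrow(m)
  L <- ncol(m)
  ## pairwise identity via per-state indicator cross-products:
  ## matches(n, m) = sum_s 1[x_n = s] . 1[x_m = s]
  matches <- matrix(0, n, n)
  for (s in seq_along(msa@alphabet)) {
    ind <- (m == s) * 1
    matches <- matches + tcrossprod(ind)
  }
  neigh <- rowSums(matches / L > identityThreshold)  # diagonal counts self
  new("SequenceWeights", 1 / neigh, threshold = identityThreshold)
}
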