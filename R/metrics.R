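# Alignment quality against the reference: Accuracy = I/R, Confidence =
# I/A, where I counts residue-index pairs shared by the reference and the
# algorithmic alignment, R and A the pairs of each. Comparisons are
# residue-residue pairs only; gap columns never count.

#' Score an algorithmic alignment against the reference
#'
#' `I` is the number of exact residue-index pairs present in both
#' alignments, `R` and `A` the reference and algorithmic pair counts;
#' Accuracy = I/R, Confidence = I/A. An empty algorithmic alignment (a
#' local search that found nothing) has Confidence 0 by convention and is
#' retained in averages — complete mismatches are informative.
#'
#' @param reference,algorithmic [PairAlignment-class] objects over the same
#'   two sequences.
#' @return One-row data.frame with columns `I`, `R`, `A`, `accuracy`,
#'   `confidence`.
#' @examples
#' ref <- new("PairAlignment", i = c(1L, 2L, 3L, 4L), j = c(1L, 2L, 3L, 5L),
#'            len1 = 4L, len2 = 5L)
#' alg <- new("PairAlignment", i = c(1L, 3L, 4L), j = c(1L, 3L, 4L),
#'            len1 = 4L, len2 = 5L)
#' scoreAlignment(ref, alg)   # I = 2, accuracy 0.5, confidence 2/3
#' @export
scoreAlignment <- function(reference, algorithmic) {
  stopifnot(is(reference, "PairAlignment"), is(algorithmic, "PairAlignment"))
  if (reference@len1 != algorithmic@len1 ||
      reference@len2 != algorithmic@len2)
    stop("alignments refer to sequences of different lengths")
  R <- length(reference@i)
  A <- length(algorithmic@i)
  # pair sets as single keys; lengths bound the key space
  key_ref <- (reference@i - 1) * as.numeric(reference@len2 + 1L) + reference@j
  key_alg <- (algorithmic@i - 1) * as.numeric(reference@len2 + 1L) +
    algorithmic@j
  I <- sum(key_alg %in% key_ref)
  data.frame(I = I, R = R, A = A,
             accuracy = if (R > 0) I / R else 0,
             confidence = if (A > 0) I / A else 0)
}

#' Average quality over a set of scored pairs
#'
#' Unweighted per-pair (macro) means of Accuracy and Confidence, the
#' aggregation used for every grid cell.
#'
#' @param scores data.frame with `accuracy` and `confidence` columns, one
#'   row per pair (rbind of [scoreAlignment()] outputs).
#' @return Named numeric `(accuracy, confidence)`.
#' @export
meanQuality <- function(scores) {
  if (NROW(scores) == 0)
    stop("'scores' must contain at least one pair")
  c(accuracy = mean(scores$accuracy), confidence = mean(scores$confidence))
}

#' Identity fraction of an alignment
#'
#' Fraction of aligned residue pairs whose residues are identical; 0 for an
#' empty alignment.
#'
#' @param a A [PairAlignment-class].
#' @param s1,s2 The aligned sequences.
#' @return Fraction in [0, 1].
#' @export
identityFraction <- function(a, s1, s2) {
  stopifnot(is(a, "PairAlignment"))
  if (length(a@i) == 0) return(0)
  v1 <- .aa_to_int(s1)
  v2 <- .aa_to_int(s2)
  mean(v1[a@i] == v2[a@j])
}

#' Indel fraction of an alignment
#'
#' Gap positions over total alignment columns, taking the full (global)
#' span of both sequences: `gaps = (len1 - pairs) + (len2 - pairs)` and the
#' fraction is `gaps / (pairs + gaps)`.
#'
#' @param a A [PairAlignment-class].
#' @param s1,s2 The aligned sequences (used for their lengths).
#' @return Fraction in [0, 1).
#' @export
indelFraction <- function(a, s1, s2) {
  stopifnot(is(a, "PairAlignment"))
  np <- length(a@i)
  gaps <- (a@len1 - np) + (a@len2 - np)
  if (np + gaps == 0) return(0)
  gaps / (np + gaps)
}
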