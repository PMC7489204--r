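# User-facing wrappers around the compiled Gotoh dynamic programming.
# Conventions, fixed package-wide:
#  * a gap of length L costs gop + (L-1)*gep (opening a gap costs gop for
#    its first residue);
#  * terminal gaps are penalized in global mode unless freeEndGaps = TRUE;
#  * traceback tie-break prefers residue pair > gap in s2 > gap in s1,
#    applied from the alignment end, so outputs are bit-reproducible;
#  * scores are real-valued (gap extensions like 0.1 rule out integers).

.check_gap <- function(gop, gep) {
  if (!is.finite(gop) || !is.finite(gep) || gop <= 0 || gep <= 0)
    stop("'gop' and 'gep' must be positive penalty magnitudes")
}

.align_one <- function(s1, s2, m, gop, gep, local, freeEndGaps = FALSE) {
  v1 <- .aa_to_int(s1)
  v2 <- .aa_to_int(s2)
  res <- .gotoh_align_cpp(v1, v2, scores(m), gop, gep, local, freeEndGaps)
  aln <- new("PairAlignment",
             i = as.integer(res$i), j = as.integer(res$j),
             len1 = length(v1), len2 = length(v2))
  new("AlignmentResult", alignment = aln, score = res$score,
      mode = if (local) "local" else "global")
}

#' Optimal global (Needleman-Wunsch) alignment with affine gap penalty
#'
#' Maximizes the summed substitution scores minus `gop + (L-1)*gep` per
#' gap of length `L` over all end-to-end alignments. Terminal gaps are
#' penalized unless `freeEndGaps = TRUE`.
#'
#' @param s1,s2 Amino-acid sequences (single strings over the 20-letter
#'   alphabet).
#' @param m A [SubstitutionMatrix-class].
#' @param gop,gep Gap-opening and gap-extension penalties (positive
#'   magnitudes; they are subtracted).
#' @param freeEndGaps If TRUE, leading and trailing gaps are free.
#' @return An [AlignmentResult-class].
#' @examples
#' m <- scoreMatrix("BLOSUM62")
#' globalAlign("HEAGAWGHEE", "PAWHEAE", m, gop = 8, gep = 8)
#' @export
globalAlign <- function(s1, s2, m, gop, gep, freeEndGaps = FALSE) {
  stopifnot(is(m, "SubstitutionMatrix"))
  .check_gap(gop, gep)
  .align_one(s1, s2, m, gop, gep, local = FALSE, freeEndGaps = freeEndGaps)
}

#' Optimal local (Smith-Waterman) alignment with affine gap penalty
#'
#' Returns the maximal-scoring contiguous sub-alignment; if no residue
#' pairing scores positively the empty alignment (score 0) is returned.
#'
#' @inheritParams globalAlign
#' @return An [AlignmentResult-class].
#' @examples
#' m <- scoreMatrix("BLOSUM62")
#' localAlign("HEAGAWGHEE", "PAWHEAE", m, gop = 12, gep = 0.5)
#' @export
localAlign <- function(s1, s2, m, gop, gep) {
  stopifnot(is(m, "SubstitutionMatrix"))
  .check_gap(gop, gep)
  .align_one(s1, s2, m, gop, gep, local = TRUE)
}

#' Re-score an alignment under a matrix and gap penalty
#'
#' Computes, independently of the dynamic programming, the score of a
#' [PairAlignment-class]: summed substitution scores of the aligned pairs
#' minus `gop + (L-1)*gep` for every maximal run of unaligned residues,
#' terminal runs included in (penalized) global mode and excluded in local
#' mode. Used as a consistency oracle for the DP score.
#'
#' @param aln A [PairAlignment-class].
#' @param s1,s2 The aligned sequences.
#' @param m A [SubstitutionMatrix-class].
#' @param gop,gep Gap penalties (positive magnitudes).
#' @param mode `"global"` or `"local"`.
#' @param freeEndGaps If TRUE (global), terminal gaps are not charged.
#' @return Numeric score.
#' @export
rescoreAlignment <- function(aln, s1, s2, m, gop, gep,
                             mode = c("global", "local"),
                             freeEndGaps = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(aln, "PairAlignment"))
  v1 <- .aa_to_int(s1)
  v2 <- .aa_to_int(s2)
  stopifnot(aln@len1 == length(v1), aln@len2 == length(v2))
  i <- aln@i; j <- aln@j
  sc <- scores(m)
  total <- sum(sc[cbind(v1[i], v2[j])])
  gap_cost <- function(L) if (L > 0) gop + (L - 1) * gep else 0
  if (length(i) == 0) {
    if (mode == "local") return(0)
    if (freeEndGaps) return(0)
    return(-gap_cost(length(v1)) - gap_cost(length(v2)))
  }
  # internal gap runs between consecutive aligned pairs
  if (length(i) > 1) {
    di <- diff(i) - 1L
    dj <- diff(j) - 1L
    total <- total - sum(vapply(di, gap_cost, numeric(1))) -
                     sum(vapply(dj, gap_cost, numeric(1)))
  }
  if (mode == "global" && !freeEndGaps) {
    total <- total - gap_cost(i[1L] - 1L) - gap_cost(j[1L] - 1L) -
      gap_cost(length(v1) - i[length(i)]) -
      gap_cost(length(v2) - j[length(j)])
  }
  total
}
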