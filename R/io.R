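# Sequence and alignment input/output: FASTA through Biostrings, aligned
# FASTA (gap character '-') and TSV index-pair dumps, and ingestion of
# reference multiple alignments (aligned FASTA or MSF) from which all
# induced pairwise reference alignments can be extracted.

#' Write the sequence pairs of a test set as FASTA
#'
#' Records are named `pair<k>_s1` / `pair<k>_s2` in pair order.
#'
#' @param ts A [TestSet-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writePairsFasta <- function(ts, file) {
  stopifnot(is(ts, "TestSet"))
  seqs <- unlist(lapply(seq_along(ts@pairs), function(k) {
    pr <- ts@pairs[[k]]
    stats::setNames(c(pr@s1, pr@s2),
                    paste0("pair", k, c("_s1", "_s2")))
  }))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), file)
  invisible(file)
}

#' Read sequence pairs from FASTA
#'
#' Consecutive records form pairs (1st with 2nd, 3rd with 4th, ...).
#'
#' @param file FASTA path.
#' @return List of `list(s1, s2, name1, name2)`.
#' @export
readPairsFasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  if (length(x) %% 2 != 0)
    stop("pair FASTA must contain an even number of records")
  lapply(seq_len(length(x) / 2), function(k) {
    list(s1 = as.character(x[[2 * k - 1]]), s2 = as.character(x[[2 * k]]),
         name1 = names(x)[2 * k - 1], name2 = names(x)[2 * k])
  })
}

#' Render a pairwise alignment as two gapped strings
#'
#' Builds the aligned rows (gap character `-`) over the full span of both
#' sequences. Where both sequences have unaligned residues between two
#' aligned columns, the residues of the first sequence are laid out before
#' those of the second.
#'
#' @param aln A [PairAlignment-class].
#' @param s1,s2 The aligned sequences.
#' @return Character vector of the two gapped rows.
#' @export
alignmentToStrings <- function(aln, s1, s2) {
  stopifnot(is(aln, "PairAlignment"))
  c1 <- strsplit(s1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1L]]
  stopifnot(length(c1) == aln@len1, length(c2) == aln@len2)
  i_prev <- 0L; j_prev <- 0L
  r1 <- character(); r2 <- character()
  emit <- function(ii, jj) {
    # unaligned residues first from s1 (over gaps), then from s2
    if (ii - i_prev > 1L) {
      idx <- (i_prev + 1L):(ii - 1L)
      r1 <<- c(r1, c1[idx]); r2 <<- c(r2, rep("-", length(idx)))
    }
    if (jj - j_prev > 1L) {
      idx <- (j_prev + 1L):(jj - 1L)
      r1 <<- c(r1, rep("-", length(idx))); r2 <<- c(r2, c2[idx])
    }
  }
  ip <- aln@i; jp <- aln@j
  for (k in seq_along(ip)) {
    emit(ip[k], jp[k])
    r1 <- c(r1, c1[ip[k]]); r2 <- c(r2, c2[jp[k]])
    i_prev <- ip[k]; j_prev <- jp[k]
  }
  emit(aln@len1 + 1L, aln@len2 + 1L)
  c(paste(r1, collapse = ""), paste(r2, collapse = ""))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A [PairAlignment-class].
#' @param s1,s2 The aligned sequences.
#' @param file Output path.
#' @param names Record names.
#' @return `file`, invisibly.
#' @export
writeAlignedFasta <- function(aln, s1, s2, file, names = c("s1", "s2")) {
  rows <- alignmentToStrings(aln, s1, s2)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(rows, names)), file)
  invisible(file)
}

#' Write an alignment as a TSV of 1-based index pairs
#'
#' @param aln A [PairAlignment-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeAlignmentTsv <- function(aln, file) {
  stopifnot(is(aln, "PairAlignment"))
  utils::write.table(data.frame(i = aln@i, j = aln@j), file,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a reference multiple alignment
#'
#' Reads an aligned-FASTA or MSF reference alignment (as distributed by
#' curated alignment benchmarks) into a named character vector of gapped
#' rows. MSF parsing is delegated to \pkg{seqinr}.
#'
#' @param file Path to the alignment.
#' @param format `"fasta"` or `"msf"`.
#' @return Named character vector of equal-length gapped sequences.
#' @export
readReferenceMsa <- function(file, format = c("fasta", "msf")) {
  format <- match.arg(format)
  rows <- if (format == "fasta") {
    x <- Biostrings::readAAStringSet(file)
    stats::setNames(as.character(x), names(x))
  } else {
    if (!requireNamespace("seqinr", quietly = TRUE))
      stop("reading MSF requires the 'seqinr' package")
    aln <- seqinr::read.alignment(file, format = "msf")
    stats::setNames(toupper(unlist(aln$seq)), aln$nam)
  }
  rows <- gsub("[.~]", "-", rows)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows have unequal lengths")
  rows
}

#' Extract induced pairwise reference alignments from a multiple alignment
#'
#' For each selected pair of rows, columns where both rows carry a residue
#' become aligned index pairs; all other columns are gaps. This turns a
#' curated reference multiple alignment into pairwise reference alignments
#' scorable with [scoreAlignment()] — the external-data path of the
#' benchmark.
#'
#' @param msa Named character vector from [readReferenceMsa()].
#' @param pairs Optional two-column matrix of row indices; default all
#'   unordered pairs.
#' @param n Optional number of pairs to sample (after `pairs` resolution).
#' @param seed Seed used when sampling.
#' @return List of `list(name1, name2, s1, s2, reference)` where
#'   `reference` is a [PairAlignment-class] over the ungapped sequences.
#' @export
msaPairAlignments <- function(msa, pairs = NULL, n = NULL, seed = 1) {
  stopifnot(length(msa) >= 2)
  if (is.null(pairs))
    pairs <- t(utils::combn(length(msa), 2))
  if (!is.null(n) && n < nrow(pairs)) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), n), , drop = FALSE]
  }
  chars <- lapply(msa, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    ca <- chars[[a]]; cb <- chars[[b]]
    resa <- ca != "-"; resb <- cb != "-"
    posa <- cumsum(resa); posb <- cumsum(resb)
    both <- resa & resb
    list(name1 = names(msa)[a], name2 = names(msa)[b],
         s1 = paste(ca[resa], collapse = ""),
         s2 = paste(cb[resb], collapse = ""),
         reference = new("PairAlignment",
                         i = as.integer(posa[both]), j = as.integer(posb[both]),
                         len1 = sum(resa), len2 = sum(resb)))
  })
}
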