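#' Bundled substitution matrices
#'
#' `scoreMatrix()` resolves a matrix by name from the bundled registry
#' (canonical NCBI PAM30/120/250 and BLOSUM45/50/62 tables, plus a PAM60
#' generated from the bundled Dayhoff PAM1 model) or loads an arbitrary
#' file. `availableMatrices()` lists the bundled names.
#'
#' @param name Bundled matrix name (see `availableMatrices()`), or a path
#'   to a file in NCBI/EMBOSS square format.
#' @return A [SubstitutionMatrix-class].
#' @examples
#' availableMatrices()
#' scoreMatrix("PAM250")
#' @export
scoreMatrix <- function(name) {
  dir <- system.file("extdata", "matrices", package = "SubMatBench",
                     mustWork = TRUE)
  path <- file.path(dir, paste0(name, ".txt"))
  if (file.exists(path))
    return(readScoreMatrix(path, name = name))
  if (file.exists(name))
    return(readScoreMatrix(name))
  stop("unknown matrix '", name, "'; bundled: ",
       paste(availableMatrices(), collapse = ", "),
       ". Pass a file path for other matrices.")
}

#' @rdname scoreMatrix
#' @export
availableMatrices <- function() {
  dir <- system.file("extdata", "matrices", package = "SubMatBench",
                     mustWork = TRUE)
  sort(sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$")))
}

#' Shift a score matrix so every entry is strictly positive
#'
#' Adds the constant `1 - floor(min(scores))` when the minimum entry is not
#' already positive (an all-positive matrix is returned unchanged). Pairwise
#' score differences — and therefore Pearson correlations with other
#' matrices — are preserved exactly. This is the construction behind
#' all-positive variants such as a positively shifted Gonnet table, which
#' interact distinctively with local alignment.
#'
#' @param m A [SubstitutionMatrix-class].
#' @return A [SubstitutionMatrix-class]; name suffixed `"_p"` if shifted.
#' @examples
#' positiveShift(scoreMatrix("BLOSUM62"))
#' @export
positiveShift <- function(m) {
  stopifnot(is(m, "SubstitutionMatrix"))
  lo <- min(scores(m))
  if (lo > 0) return(m)
  shift <- 1 - floor(lo)
  new("SubstitutionMatrix",
      name = paste0(matrixName(m), "_p"),
      scores = scores(m) + shift,
      metadata = c(m@metadata,
                   paste0("All entries shifted by +", shift)))
}

#' Pearson correlation between two substitution matrices
#'
#' Computed over the 210 unique elements of the symmetric tables (upper
#' triangle including the diagonal), avoiding the double weighting of
#' off-diagonal entries that a full-matrix correlation would introduce.
#'
#' @param m1,m2 [SubstitutionMatrix-class] objects over the same alphabet.
#' @return Pearson r in [-1, 1].
#' @examples
#' matrixCorrelation(scoreMatrix("PAM250"), scoreMatrix("BLOSUM62"))
#' @export
matrixCorrelation <- function(m1, m2) {
  stopifnot(is(m1, "SubstitutionMatrix"), is(m2, "SubstitutionMatrix"))
  ut <- upper.tri(scores(m1), diag = TRUE)
  x <- scores(m1)[ut]
  y <- scores(m2)[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a matrix has zero variance")
  stats::cor(x, y)
}
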