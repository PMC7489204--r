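#' Accessors for package classes
#'
#' Small accessor layer so downstream code never touches slots directly:
#' `scores()` returns the numeric score table of a
#' [SubstitutionMatrix-class], `matrixName()` its name, `probMatrix()` the
#' row-stochastic table of a [PamProbability-class], `alignedPairs()` the
#' two-column index matrix of a [PairAlignment-class], `nAligned()` the
#' number of aligned residue pairs, `gridCells()` and `optimum()` the cell
#' table and the selected optimum of a [GridResult-class].
#'
#' @param x An object of the documented class.
#' @return See details above.
#' @name accessors
#' @aliases scores matrixName probMatrix alignedPairs nAligned gridCells optimum
NULL

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("matrixName", function(x) standardGeneric("matrixName"))
#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))
#' @rdname accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
#' @rdname accessors
#' @export
setGeneric("nAligned", function(x) standardGeneric("nAligned"))
#' @rdname accessors
#' @export
setGeneric("gridCells", function(x) standardGeneric("gridCells"))
#' @rdname accessors
#' @export
setGeneric("optimum", function(x) standardGeneric("optimum"))

#' @rdname accessors
setMethod("scores", "SubstitutionMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("matrixName", "SubstitutionMatrix", function(x) x@name)
#' @rdname accessors
setMethod("matrixName", "GridResult", function(x) x@matrixName)
#' @rdname accessors
setMethod("probMatrix", "PamProbability", function(x) x@prob)
#' @rdname accessors
setMethod("alignedPairs", "PairAlignment",
  function(x) cbind(i = x@i, j = x@j))
#' @rdname accessors
setMethod("alignedPairs", "AlignmentResult",
  function(x) alignedPairs(x@alignment))
#' @rdname accessors
setMethod("nAligned", "PairAlignment", function(x) length(x@i))
#' @rdname accessors
setMethod("nAligned", "AlignmentResult", function(x) nAligned(x@alignment))
#' @rdname accessors
setMethod("gridCells", "GridResult", function(x) x@cells)
#' @rdname accessors
setMethod("optimum", "GridResult", function(x) x@optimum)

#' @exportMethod show
setMethod("show", "SubstitutionMatrix", function(object) {
  s <- object@scores
  cat("SubstitutionMatrix \"", object@name, "\"\n", sep = "")
  cat("  score range [", min(s), ", ", max(s), "], diagonal mean ",
      round(mean(diag(s)), 2), "\n", sep = "")
  if (length(object@metadata))
    cat("  ", object@metadata[1L], "\n", sep = "")
})

setMethod("show", "PamProbability", function(object) {
  cat("PamProbability at distance ", object@distance, " PAM",
      " (expected identity ", round(sum(dayhoffFrequencies() *
        diag(object@prob)), 4), ")\n", sep = "")
})

setMethod("show", "PairAlignment", function(object) {
  cat("PairAlignment: ", length(object@i), " aligned pairs over sequences of ",
      object@len1, " and ", object@len2, " residues\n", sep = "")
})

setMethod("show", "EvolvedPair", function(object) {
  cat("EvolvedPair at ", object@pam, " PAM per branch\n", sep = "")
  cat("  ancestor ", nchar(object@ancestor), " aa; descendants ",
      nchar(object@s1), " and ", nchar(object@s2), " aa; ",
      sum(!is.na(object@map1) & !is.na(object@map2)),
      " jointly conserved positions\n", sep = "")
})

setMethod("show", "TestSet", function(object) {
  cat("TestSet: ", length(object@pairs), " pairs at ", object@pam,
      " PAM (seed ", object@seed, ")\n", sep = "")
})

setMethod("show", "AlignmentResult", function(object) {
  cat(object@mode, " AlignmentResult: score ", object@score, ", ",
      nAligned(object), " aligned pairs\n", sep = "")
})

setMethod("show", "GridResult", function(object) {
  o <- object@optimum
  cat("GridResult: ", object@matrixName, ", ", object@mode, " on ",
      object@testSetId, "\n  ", nrow(object@cells),
      " cells; optimum GOP=", o["gop"], " GEP=", o["gep"],
      " accuracy=", round(o["accuracy"], 4),
      " confidence=", round(o["confidence"], 4), "\n", sep = "")
})

#' Number of pairs in a test set
#' @param x A [TestSet-class].
#' @return Integer count.
#' @export
setMethod("length", "TestSet", function(x) length(x@pairs))

#' Extract one evolved pair from a test set
#' @param x A [TestSet-class].
#' @param i Index.
#' @param j,...,exact Unused.
#' @return An [EvolvedPair-class].
#' @export
setMethod("[[", "TestSet", function(x, i, j, ...) x@pairs[[i]])
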