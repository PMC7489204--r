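#' @import methods
NULL

#' SubstitutionMatrix: a symmetric 20x20 amino-acid score table
#'
#' Scores are real-valued (gap-extension penalties down to 0.1 make integer
#' arithmetic inappropriate downstream) and indexed by the package-wide
#' amino-acid alphabet, see [aminoAlphabet()]. Symmetry is enforced by the
#' validity method within 1e-9.
#'
#' @slot name Single string naming the matrix (e.g. `"PAM250"`).
#' @slot scores 20x20 numeric matrix with dimnames equal to the alphabet.
#' @slot metadata Free-text provenance lines.
#'
#' @seealso [readScoreMatrix()], [scoreMatrix()], [positiveShift()],
#'   [matrixCorrelation()]
#' @export
setClass("SubstitutionMatrix",
  representation(name = "character", scores = "matrix", metadata = "character"),
  prototype(metadata = character())
)

setValidity("SubstitutionMatrix", function(object) {
  s <- object@scores
  alpha <- aminoAlphabet()
  if (!is.numeric(s) || !identical(dim(s), c(20L, 20L)))
    return("'scores' must be a numeric 20x20 matrix")
  if (!identical(rownames(s), alpha) || !identical(colnames(s), alpha))
    return("'scores' must have the package amino-acid alphabet as dimnames")
  if (any(!is.finite(s)))
    return("'scores' must be finite")
  if (max(abs(s - t(s))) > 1e-9)
    return("'scores' must be symmetric within 1e-9")
  if (length(object@name) != 1L || is.na(object@name))
    return("'name' must be a single string")
  TRUE
})

#' PamProbability: a PAM mutation-probability matrix at a given distance
#'
#' Row-stochastic: entry `[a, b]` is the probability that ancestor residue
#' `a` is observed as `b` after `distance` PAM of evolution. Distance 0 is
#' the identity table; distance n is the bundled Dayhoff PAM1 raised to the
#' n-th power.
#'
#' @slot distance Non-negative number of PAM units.
#' @slot prob 20x20 row-stochastic numeric matrix over the alphabet.
#'
#' @seealso [pamProbability()], [expectedIdentity()]
#' @export
setClass("PamProbability",
  representation(distance = "numeric", prob = "matrix")
)

setValidity("PamProbability", function(object) {
  p <- object@prob
  alpha <- aminoAlphabet()
  if (!identical(dim(p), c(20L, 20L)) ||
      !identical(rownames(p), alpha) || !identical(colnames(p), alpha))
    return("'prob' must be 20x20 over the package alphabet")
  if (any(p < 0) || any(p > 1))
    return("'prob' entries must lie in [0, 1]")
  if (max(abs(rowSums(p) - 1)) > 1e-9)
    return("'prob' rows must sum to 1 within 1e-9")
  if (length(object@distance) != 1L || object@distance < 0)
    return("'distance' must be a single non-negative number")
  TRUE
})

#' PairAlignment: an alignment as an ordered set of residue-index pairs
#'
#' Gap columns are implicit: any residue of either sequence that appears in
#' no pair sits in a gap. Indices are 1-based (R convention). Both index
#' vectors must be strictly increasing — alignments never cross.
#'
#' @slot i Integer indices into the first sequence, strictly increasing.
#' @slot j Integer indices into the second sequence, strictly increasing.
#' @slot len1,len2 Lengths of the two aligned sequences.
#'
#' @seealso [referenceAlignment()], [scoreAlignment()], [identityFraction()]
#' @export
setClass("PairAlignment",
  representation(i = "integer", j = "integer", len1 = "integer", len2 = "integer")
)

setValidity("PairAlignment", function(object) {
  i <- object@i; j <- object@j
  if (length(i) != length(j))
    return("'i' and 'j' must have equal length")
  if (length(i)) {
    if (any(diff(i) <= 0) || any(diff(j) <= 0))
      return("aligned indices must be strictly increasing (no crossings)")
    if (i[1L] < 1L || j[1L] < 1L ||
        i[length(i)] > object@len1 || j[length(j)] > object@len2)
      return("aligned indices out of sequence bounds")
  }
  TRUE
})

#' EvolvedPair: two descendants of a common ancestor with position maps
#'
#' `map1`/`map2` give, for each ancestor position, the 1-based position of
#' the derived residue in the descendant, or `NA` if the position was
#' deleted. Descendant residues outside the map image are insertions.
#'
#' @slot ancestor,s1,s2 Amino-acid sequences as single strings.
#' @slot map1,map2 Integer vectors of length `nchar(ancestor)` (NA = deleted).
#' @slot pam PAM distance used for each ancestor-to-descendant branch.
#'
#' @seealso [evolvePair()], [referenceAlignment()]
#' @export
setClass("EvolvedPair",
  representation(ancestor = "character", s1 = "character", s2 = "character",
                 map1 = "integer", map2 = "integer", pam = "numeric")
)

setValidity("EvolvedPair", function(object) {
  L0 <- nchar(object@ancestor)
  for (k in 1:2) {
    map <- slot(object, paste0("map", k))
    len <- nchar(slot(object, paste0("s", k)))
    if (length(map) != L0)
      return("position map length must equal ancestor length")
    ok <- map[!is.na(map)]
    if (length(ok) && (any(diff(ok) <= 0) || ok[1L] < 1L || ok[length(ok)] > len))
      return("position map must be strictly increasing and in bounds")
  }
  TRUE
})

#' TestSet: a reproducible collection of evolved sequence pairs
#'
#' @slot pam PAM distance of each ancestor-to-descendant branch.
#' @slot seed Master seed the set was generated from.
#' @slot pairs List of [EvolvedPair-class] objects.
#'
#' @seealso [generateTestSet()], [testSetStats()], [evaluateGrid()]
#' @export
setClass("TestSet",
  representation(pam = "numeric", seed = "integer", pairs = "list")
)

setValidity("TestSet", function(object) {
  if (!all(vapply(object@pairs, is, logical(1), class2 = "EvolvedPair")))
    return("'pairs' must be a list of EvolvedPair objects")
  TRUE
})

#' AlignmentResult: an optimal alignment with its dynamic-programming score
#'
#' @slot alignment The [PairAlignment-class] of matched residue indices.
#' @slot score DP optimum under the matrix and gap penalty used.
#' @slot mode `"local"` (Smith-Waterman) or `"global"` (Needleman-Wunsch).
#'
#' @seealso [globalAlign()], [localAlign()], [rescoreAlignment()]
#' @export
setClass("AlignmentResult",
  representation(alignment = "PairAlignment", score = "numeric", mode = "character")
)

setValidity("AlignmentResult", function(object) {
  if (!object@mode %in% c("local", "global"))
    return("'mode' must be \"local\" or \"global\"")
  if (object@mode == "local" && object@score < 0)
    return("local alignment score cannot be negative")
  TRUE
})

#' GridResult: mean alignment quality over a gap-penalty grid
#'
#' @slot matrixName Name of the substitution matrix evaluated.
#' @slot mode `"local"` or `"global"`.
#' @slot testSetId Identifier of the test set (e.g. `"PAM120/n=1000"`).
#' @slot cells data.frame with columns `gop`, `gep`, `accuracy`, `confidence`.
#' @slot optimum Named numeric `(gop, gep, accuracy, confidence)` maximizing
#'   `min(accuracy, confidence)` over the cells.
#'
#' @seealso [evaluateGrid()], [selectOptimum()], [rankMatrices()]
#' @export
setClass("GridResult",
  representation(matrixName = "character", mode = "character",
                 testSetId = "character", cells = "data.frame",
                 optimum = "numeric")
)

setValidity("GridResult", function(object) {
  need <- c("gop", "gep", "accuracy", "confidence")
  if (!all(need %in% names(object@cells)))
    return("'cells' must have columns gop, gep, accuracy, confidence")
  if (!all(need %in% names(object@optimum)))
    return("'optimum' must be named (gop, gep, accuracy, confidence)")
  TRUE
})
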