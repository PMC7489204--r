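# Grid evaluation and matrix ranking: align every pair of a test set at
# every (GOP, GEP) cell, macro-average Accuracy/Confidence per cell, pick
# the cell maximizing min(Accuracy, Confidence), and rank matrices by the
# mean of the two optimal values.

#' Gap-penalty grid
#'
#' The default grid is GOP 3..30 in steps of 1 crossed with
#' GEP in {0.1, 0.2, 0.5, 1, 2, 3, 4, 8} — the classical search region for
#' affine-gap protein alignment. Fully configurable.
#'
#' @param gop Vector of gap-opening penalties (positive).
#' @param gep Vector of gap-extension penalties (positive).
#' @return A `PenaltyGrid` (list with `gop` and `gep`).
#' @examples
#' penaltyGrid(gop = c(9, 12), gep = c(0.5, 1))
#' @export
penaltyGrid <- function(gop = 3:30, gep = c(0.1, 0.2, 0.5, 1, 2, 3, 4, 8)) {
  if (!length(gop) || !length(gep) || any(gop <= 0) || any(gep <= 0))
    stop("'gop' and 'gep' must be non-empty and positive")
  structure(list(gop = as.numeric(gop), gep = as.numeric(gep)),
            class = "PenaltyGrid")
}

#' @export
print.PenaltyGrid <- function(x, ...) {
  cat("PenaltyGrid:", length(x$gop), "GOP x", length(x$gep), "GEP values\n")
  invisible(x)
}

.test_set_id <- function(ts) {
  sprintf("PAM%g/n=%d/seed=%d", ts@pam, length(ts), ts@seed)
}

#' Evaluate mean alignment quality over a penalty grid
#'
#' Aligns every pair of the test set at every grid cell and macro-averages
#' Accuracy and Confidence against the reference alignments. Cells are
#' independent: a sub-grid reproduces the corresponding cells of the full
#' grid exactly, and results do not depend on evaluation order.
#'
#' @param ts A [TestSet-class].
#' @param m A [SubstitutionMatrix-class].
#' @param mode `"local"` or `"global"`.
#' @param grid A [penaltyGrid()].
#' @param freeEndGaps Passed to the global aligner.
#' @return A [GridResult-class].
#' @examples
#' ts <- generateTestSet(30, n = 3, length = 80, seed = 1)
#' evaluateGrid(ts, scoreMatrix("PAM250"), "global",
#'              penaltyGrid(gop = 9, gep = 1))
#' @export
evaluateGrid <- function(ts, m, mode = c("local", "global"),
                         grid = penaltyGrid(), freeEndGaps = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(ts, "TestSet"), is(m, "SubstitutionMatrix"),
            inherits(grid, "PenaltyGrid"))
  local <- mode == "local"
  sc <- scores(m)
  prep <- lapply(ts@pairs, function(pr) {
    ref <- referenceAlignment(pr)
    list(v1 = .aa_to_int(pr@s1), v2 = .aa_to_int(pr@s2),
         key = (ref@i - 1) * as.numeric(ref@len2 + 1L) + ref@j,
         R = length(ref@i))
  })
  cells <- expand.grid(gep = grid$gep, gop = grid$gop)[, c("gop", "gep")]
  acc <- conf <- numeric(nrow(cells))
  for (cidx in seq_len(nrow(cells))) {
    gop <- cells$gop[cidx]; gep <- cells$gep[cidx]
    a <- cf <- numeric(length(prep))
    for (k in seq_along(prep)) {
      pp <- prep[[k]]
      r <- .gotoh_align_cpp(pp$v1, pp$v2, sc, gop, gep, local, freeEndGaps)
      A <- length(r$i)
      key_alg <- (r$i - 1) * as.numeric(length(pp$v2) + 1L) + r$j
      I <- sum(key_alg %in% pp$key)
      a[k] <- if (pp$R > 0) I / pp$R else 0
      cf[k] <- if (A > 0) I / A else 0
    }
    acc[cidx] <- mean(a); conf[cidx] <- mean(cf)
  }
  cells$accuracy <- acc
  cells$confidence <- conf
  new("GridResult", matrixName = matrixName(m), mode = mode,
      testSetId = .test_set_id(ts), cells = cells,
      optimum = selectOptimum(cells))
}

#' Select the optimal penalty cell
#'
#' The optimum maximizes `min(accuracy, confidence)` over the cells; ties
#' are broken toward the smaller GOP, then the smaller GEP.
#'
#' @param x A [GridResult-class] or a data.frame of cells with columns
#'   `gop`, `gep`, `accuracy`, `confidence`.
#' @return Named numeric `(gop, gep, accuracy, confidence)`.
#' @export
selectOptimum <- function(x) {
  cells <- if (is(x, "GridResult")) gridCells(x) else x
  stopifnot(NROW(cells) > 0)
  crit <- pmin(cells$accuracy, cells$confidence)
  ord <- order(-crit, cells$gop, cells$gep)
  best <- cells[ord[1L], ]
  c(gop = best$gop, gep = best$gep,
    accuracy = best$accuracy, confidence = best$confidence)
}

#' Rank matrices by optimal alignment quality
#'
#' Orders matrices by the mean of the optimal Accuracy and Confidence
#' (descending). All results must come from the same test set and mode.
#'
#' @param results List of [GridResult-class] objects.
#' @return data.frame with columns `matrix`, `gop`, `gep`, `accuracy`,
#'   `confidence`, `mean`, sorted descending by `mean`.
#' @export
rankMatrices <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, is, logical(1), class2 = "GridResult")))
  ids <- vapply(results, function(r) r@testSetId, character(1))
  modes <- vapply(results, function(r) r@mode, character(1))
  if (length(unique(ids)) != 1L || length(unique(modes)) != 1L)
    stop("all results must share one test set and one alignment mode")
  rows <- lapply(results, function(r) {
    o <- optimum(r)
    data.frame(matrix = matrixName(r), gop = o[["gop"]], gep = o[["gep"]],
               accuracy = o[["accuracy"]], confidence = o[["confidence"]],
               mean = (o[["accuracy"]] + o[["confidence"]]) / 2)
  })
  df <- do.call(rbind, rows)
  df[order(-df$mean, df$matrix), , drop = FALSE]
}

#' Ratio of global to local optimal alignment quality
#'
#' For one matrix on one test set, the optimal global quality divided by
#' the optimal local quality, per metric. A zero local value yields `Inf`
#' as an unbounded marker.
#'
#' @param local,global_ [GridResult-class] objects for the same matrix and
#'   test set in local and global mode.
#' @return Named numeric `(accuracy, confidence)` ratios.
#' @export
localGlobalRatio <- function(local, global_) {
  stopifnot(is(local, "GridResult"), is(global_, "GridResult"),
            local@mode == "local", global_@mode == "global")
  if (matrixName(local) != matrixName(global_) ||
      local@testSetId != global_@testSetId)
    stop("results must share the matrix and the test set")
  ol <- optimum(local); og <- optimum(global_)
  c(accuracy = if (ol[["accuracy"]] > 0)
      og[["accuracy"]] / ol[["accuracy"]] else Inf,
    confidence = if (ol[["confidence"]] > 0)
      og[["confidence"]] / ol[["confidence"]] else Inf)
}

#' All-pairs Pearson correlation of substitution matrices
#'
#' Symmetric table of [matrixCorrelation()] values with unit diagonal.
#'
#' @param matrices List of [SubstitutionMatrix-class] objects.
#' @return Numeric matrix with matrix names as dimnames.
#' @examples
#' correlationReport(list(scoreMatrix("PAM250"), scoreMatrix("BLOSUM62")))
#' @export
correlationReport <- function(matrices) {
  stopifnot(length(matrices) >= 2,
            all(vapply(matrices, is, logical(1), class2 = "SubstitutionMatrix")))
  nm <- vapply(matrices, matrixName, character(1))
  n <- length(matrices)
  out <- diag(n)
  dimnames(out) <- list(nm, nm)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    out[a, b] <- out[b, a] <- matrixCorrelation(matrices[[a]], matrices[[b]])
  }
  out
}
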