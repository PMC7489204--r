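# Grid evaluation, optimum selection, ranking, ratios and correlations.

test_that("a one-cell grid on a one-pair set reduces to scoreAlignment", {
  ts <- generateTestSet(60, n = 1, length = 100, seed = 3)
  m <- scoreMatrix("PAM250")
  gr <- evaluateGrid(ts, m, "global", penaltyGrid(gop = 11, gep = 1))
  pr <- ts[[1]]
  direct <- scoreAlignment(referenceAlignment(pr),
                           globalAlign(pr@s1, pr@s2, m, 11, 1)@alignment)
  cells <- gridCells(gr)
  expect_equal(cells$accuracy, direct$accuracy)
  expect_equal(cells$confidence, direct$confidence)
})

test_that("grid cells are independent of the surrounding grid", {
  ts <- generateTestSet(60, n = 5, length = 100, seed = 4)
  m <- scoreMatrix("BLOSUM62")
  big <- gridCells(evaluateGrid(ts, m, "local",
                                penaltyGrid(gop = c(5, 10, 15),
                                            gep = c(0.5, 1, 2))))
  small <- gridCells(evaluateGrid(ts, m, "local",
                                  penaltyGrid(gop = 10, gep = 1)))
  row <- big[big$gop == 10 & big$gep == 1, ]
  expect_equal(row$accuracy, small$accuracy)
  expect_equal(row$confidence, small$confidence)
})

test_that("optimum selection maximizes the worse of the two metrics", {
  one <- data.frame(gop = 5, gep = 1, accuracy = 0.8, confidence = 0.7)
  expect_equal(selectOptimum(one)[["gop"]], 5)
  two <- data.frame(gop = c(5, 9), gep = c(1, 1),
                    accuracy = c(0.9, 0.7), confidence = c(0.4, 0.6))
  expect_equal(selectOptimum(two)[["gop"]], 9)   # min 0.6 beats min 0.4
  # synthetic 5x5 surface against a brute-force scan
  set.seed(42)
  grid <- expand.grid(gop = 1:5, gep = 1:5)
  grid$accuracy <- runif(25)
  grid$confidence <- runif(25)
  opt <- selectOptimum(grid)
  brute <- -Inf
  for (r in seq_len(25)) {
    v <- min(grid$accuracy[r], grid$confidence[r])
    if (v > brute) { brute <- v; row <- grid[r, ] }
  }
  expect_equal(opt[["accuracy"]], row$accuracy)
  expect_equal(opt[["gop"]], row$gop)
  # ties break toward the smaller gop, then gep
  tied <- data.frame(gop = c(9, 3, 3), gep = c(1, 2, 0.5),
                     accuracy = 0.8, confidence = 0.9)
  expect_equal(selectOptimum(tied)[["gop"]], 3)
  expect_equal(selectOptimum(tied)[["gep"]], 0.5)
})

test_that("ranking orders by mean optimal quality and ignores input order", {
  ts <- cached_set(120, 300)
  g250 <- evaluateGrid(ts, scoreMatrix("PAM250"), "local",
                       penaltyGrid(gop = 12, gep = 0.5))
  g30 <- evaluateGrid(ts, scoreMatrix("PAM30"), "local",
                      penaltyGrid(gop = 3, gep = 1))
  rk <- rankMatrices(list(g30, g250))
  expect_identical(rk$matrix[1], "PAM250")
  expect_equal(rk$mean,
               (rk$accuracy + rk$confidence) / 2)
  rk2 <- rankMatrices(list(g250, g30))
  expect_equal(rk, rk2, ignore_attr = TRUE)
  expect_equal(rankMatrices(list(g250))$matrix, "PAM250")
  other <- evaluateGrid(cached_set(30, 300), scoreMatrix("PAM30"), "local",
                        penaltyGrid(gop = 3, gep = 1))
  expect_error(rankMatrices(list(g250, other)), "share")
})

# same numbers rebadged as a global result, for the identity-ratio check
gl2glob <- function(gr)
  new("GridResult", matrixName = matrixName(gr), mode = "global",
      testSetId = gr@testSetId, cells = gridCells(gr),
      optimum = optimum(gr))

test_that("global/local ratios divide the optimum values per metric", {
  ts <- cached_set(120, 300)
  m <- scoreMatrix("PAM30")
  gl <- evaluateGrid(ts, m, "local", penaltyGrid(gop = 3, gep = 1))
  gg <- evaluateGrid(ts, m, "global", penaltyGrid(gop = 30, gep = 4))
  r <- localGlobalRatio(gl, gg)
  ol <- optimum(gl); og <- optimum(gg)
  expect_equal(r[["accuracy"]], og[["accuracy"]] / ol[["accuracy"]])
  expect_equal(r[["confidence"]], og[["confidence"]] / ol[["confidence"]])
  expect_equal(localGlobalRatio(gl, gl2glob(gl)), c(accuracy = 1,
                                                    confidence = 1))
  expect_error(localGlobalRatio(gg, gl), "local")
})

test_that("correlation report is symmetric with unit diagonal", {
  mats <- lapply(c("PAM30", "PAM250", "BLOSUM62"), scoreMatrix)
  cr <- correlationReport(mats)
  expect_equal(diag(cr), c(PAM30 = 1, PAM250 = 1, BLOSUM62 = 1))
  expect_equal(cr, t(cr))
  expect_equal(cr["PAM30", "PAM250"],
               matrixCorrelation(mats[[1]], mats[[2]]))
  expect_error(correlationReport(mats[1]), "length")
})

test_that("distant-homology matrices dominate on a distant test set", {
  ts <- cached_set(120, 300)
  q250 <- cell_quality(ts, "PAM250", "local", 12, 0.5)
  q30 <- cell_quality(ts, "PAM30", "local", 3, 1)
  expect_gt(min(q250$accuracy, q250$confidence) -
            min(q30$accuracy, q30$confidence), 0.4)
})

test_that("all PAM matrices perform near-perfectly on a close test set", {
  ts <- cached_set(30, 300)
  printed <- list(
    local = list(PAM30 = c(19, 0.2), PAM60 = c(16, 0.2),
                 PAM120 = c(10, 0.1), PAM250 = c(8, 0.1)),
    global = list(PAM30 = c(18, 2), PAM60 = c(17, 1),
                  PAM120 = c(13, 1), PAM250 = c(9, 1)))
  for (mode in names(printed)) {
    for (mn in names(printed[[mode]])) {
      gp <- printed[[mode]][[mn]]
      q <- cell_quality(ts, mn, mode, gp[1], gp[2])
      expect_gt(q$accuracy, 0.96)
    }
  }
})
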