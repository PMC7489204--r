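# Matrix loading, the PAM probability model, and matrix comparisons.

test_that("bundled matrices load, are symmetric, and round-trip the writer", {
  b62 <- scoreMatrix("BLOSUM62")
  expect_identical(scores(b62)["W", "W"], 11)
  expect_identical(scores(b62)["A", "A"], 4)
  for (nm in availableMatrices()) {
    m <- scoreMatrix(nm)
    expect_true(validObject(m))
    expect_equal(scores(m), t(scores(m)))
    f <- tempfile(fileext = ".txt")
    writeScoreMatrix(m, f)
    m2 <- readScoreMatrix(f, name = nm)
    expect_identical(scores(m2), scores(m))
  }
})

test_that("matrix reader rejects malformed and asymmetric input", {
  alpha <- aminoAlphabet()
  lines <- c(paste(alpha[1:2], collapse = " "), "A 1 0", "R 0 1")
  expect_error(readScoreMatrix(paste(lines, collapse = "\n")), "C")
  # asymmetric beyond tolerance
  m <- scores(scoreMatrix("BLOSUM62"))
  m["A", "C"] <- m["A", "C"] + 1
  rows <- c(paste(" ", paste(alpha, collapse = " ")),
            vapply(alpha, function(a)
              paste(a, paste(m[a, ], collapse = " ")), character(1)))
  expect_error(readScoreMatrix(paste(rows, collapse = "\n")), "asymmetry")
})

test_that("pamProbability is the bundled PAM1 raised to the distance", {
  expect_equal(probMatrix(pamProbability(0)),
               diag(20) + 0 * probMatrix(pamProbability(0)),
               ignore_attr = FALSE)
  p1 <- probMatrix(pamProbability(1))
  expect_equal(rowSums(p1), setNames(rep(1, 20), aminoAlphabet()))
  # brute-force double-loop product oracle for distance 2
  p2 <- probMatrix(pamProbability(2))
  manual <- matrix(0, 20, 20, dimnames = dimnames(p1))
  for (a in 1:20) for (b in 1:20)
    manual[a, b] <- sum(p1[a, ] * p1[, b])
  expect_equal(p2, manual, tolerance = 1e-12)
  expect_error(pamProbability(-1), "non-negative")
  expect_error(pamProbability(2.5), "integer")
})

test_that("PAM powering satisfies the semigroup property", {
  for (pair in list(c(3, 5), c(10, 20), c(60, 60))) {
    lhs <- probMatrix(pamProbability(sum(pair)))
    rhs <- probMatrix(pamProbability(pair[1])) %*%
           probMatrix(pamProbability(pair[2]))
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("expected identity decreases with distance and matches Monte Carlo", {
  expect_equal(expectedIdentity(0), 1)
  ids <- vapply(c(0, 10, 30, 60, 120, 250, 500), expectedIdentity, numeric(1))
  expect_true(all(diff(ids) < 0))
  expect_equal(expectedIdentity(30), 0.75, tolerance = 0.01)
  # the curve is floored by the random-identity baseline
  expect_gt(expectedIdentity(2000), randomIdentity())
  expect_lt(expectedIdentity(2000) - randomIdentity(), 1e-3)
  # Monte-Carlo oracle: 1e6 positions through ten PAM1 cycles
  set.seed(42)
  f <- dayhoffFrequencies()
  start <- sample.int(20, 1e6, replace = TRUE, prob = f)
  p10 <- probMatrix(pamProbability(10))
  end <- start
  for (a in 1:20) {
    idx <- which(start == a)
    end[idx] <- sample.int(20, length(idx), replace = TRUE, prob = p10[a, ])
  }
  est <- mean(start == end)
  se <- sqrt(est * (1 - est) / 1e6)
  expect_lt(abs(est - expectedIdentity(10)), 3 * se)
})

test_that("pamFromIdentity inverts the identity curve", {
  expect_equal(as.numeric(pamFromIdentity(1)), 0)
  for (d in c(10, 50, 122, 200, 300))
    expect_equal(as.numeric(pamFromIdentity(expectedIdentity(d))), d,
                 tolerance = 0.5)
  expect_equal(as.numeric(pamFromIdentity(0.3756)), 122, tolerance = 5)
  cens <- pamFromIdentity(0.05)
  expect_true(attr(cens, "censored"))
  expect_match(formatPam(cens), "^> ")
  expect_false(attr(pamFromIdentity(0.5), "censored"))
  expect_error(pamFromIdentity(0), "0, 1")
  expect_error(pamFromIdentity(1.2), "0, 1")
})

test_that("random identity matches closed forms", {
  expect_equal(randomIdentity(rep(1 / 20, 20)), 0.05)
  expect_equal(randomIdentity(dayhoffFrequencies()), 0.0601,
               tolerance = 0.0005 / 0.0601)
  expect_equal(randomIdentity(1), 1)   # degenerate one-letter composition
  expect_error(randomIdentity(c(0.5, 0.4)), "sum to 1")
})

test_that("positive shift preserves structure", {
  b62 <- scoreMatrix("BLOSUM62")
  p <- positiveShift(b62)
  expect_identical(min(scores(p)), 1)
  expect_identical(matrixName(p), "BLOSUM62_p")
  expect_equal(scores(p) - scores(b62),
               matrix(1 - floor(min(scores(b62))), 20, 20,
                      dimnames = dimnames(scores(b62))))
  expect_identical(positiveShift(p), p)          # already positive
  expect_equal(matrixCorrelation(b62, p), 1)     # affine invariance
})

test_that("matrix correlation agrees with the explicit-sum Pearson formula", {
  m1 <- scoreMatrix("PAM250")
  m2 <- scoreMatrix("BLOSUM62")
  expect_equal(matrixCorrelation(m1, m1), 1)
  ut <- upper.tri(scores(m1), diag = TRUE)
  x <- scores(m1)[ut]; y <- scores(m2)[ut]
  n <- length(x)
  expect_identical(n, 210L)
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(matrixCorrelation(m1, m2), r_hand)
  flat <- new("SubstitutionMatrix", name = "flat",
              scores = matrix(1, 20, 20,
                              dimnames = list(aminoAlphabet(),
                                              aminoAlphabet())))
  expect_error(matrixCorrelation(m1, flat), "zero variance")
})

test_that("generated PAM log-odds track the published tables", {
  gen <- pamLogOdds(250, scale = "halfbit")
  pub <- scoreMatrix("PAM250")
  # rounding differs entry-wise but the tables are nearly collinear
  expect_gt(matrixCorrelation(gen, pub), 0.97)
  expect_true(validObject(gen))
})
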