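# The divergent-evolution simulator: ancestors, indels, substitutions,
# position maps, and test-set statistics.

test_that("ancestor generation follows the background composition", {
  set.seed(42)
  expect_equal(nchar(generateAncestor(1)), 1L)
  seqs <- replicate(2000, generateAncestor(200))
  counts <- table(factor(unlist(strsplit(seqs, "")), levels = aminoAlphabet()))
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = dayhoffFrequencies()))
  expect_gt(gof$p.value, 1e-4)
  set.seed(7); a <- generateAncestor(100)
  set.seed(7); b <- generateAncestor(100)
  expect_identical(a, b)
})

test_that("indel probability follows the saturating law", {
  expect_equal(indelProbability(0), 0.0005)
  expect_equal(indelProbability(30), 0.0224 - 0.0219 * exp(-0.3504))
  pam <- c(0, 10, 30, 60, 120, 500)
  expect_true(all(diff(indelProbability(pam)) > 0))
  expect_lt(abs(indelProbability(1e4) - 0.0224), 1e-6)
  expect_error(indelProbability(-5), "non-negative")
})

test_that("indel lengths follow the truncated Zipf law", {
  expect_true(all(sampleIndelLength(100, maxLen = 1) == 1L))
  set.seed(42)
  draws <- sampleIndelLength(2e5, exponent = 1.7, maxLen = 50)
  expect_true(all(draws >= 1 & draws <= 50))
  pmf <- (1:50)^(-1.7); pmf <- pmf / sum(pmf)
  gof <- suppressWarnings(
    stats::chisq.test(tabulate(draws, 50), p = pmf))
  expect_gt(gof$p.value, 0.001)
  set.seed(1); hi <- mean(sampleIndelLength(2e4, exponent = 2.5))
  set.seed(1); lo <- mean(sampleIndelLength(2e4, exponent = 1.2))
  expect_lt(hi, lo)
  expect_error(sampleIndelLength(1, exponent = 1), "exponent")
  expect_error(sampleIndelLength(1, maxLen = 0), "maxLen")
})

test_that("zero-distance descendants are unchanged when no indel fires", {
  # P(indel) = 5e-4 at pam 0; seed chosen by convention, verified event-free
  set.seed(42)
  anc <- generateAncestor(100)
  d <- mutateDescendant(anc, pam = 0)
  expect_identical(d$seq, anc)
  expect_identical(d$map, seq_len(100))
})

test_that("one substitution cycle reproduces the PAM1 row marginals", {
  set.seed(42)
  anc <- paste(rep("A", 2e5), collapse = "")
  d <- mutateDescendant(anc, pam = 1)   # indel prob ~5e-4: a few indels fine
  keep <- !is.na(d$map)
  out <- match(strsplit(d$seq, "")[[1]][d$map[keep]], aminoAlphabet())
  p1_row <- probMatrix(pamProbability(1))["A", ]
  counts <- tabulate(out, 20)
  # structural zeros of the PAM1 row can never be observed
  expect_true(all(counts[p1_row == 0] == 0))
  pos <- p1_row > 0
  gof <- suppressWarnings(
    stats::chisq.test(counts[pos], p = p1_row[pos] / sum(p1_row[pos])))
  expect_gt(gof$p.value, 1e-4)
})

test_that("compressed and explicit substitution cycles agree in law", {
  set.seed(42)
  anc <- generateAncestor(2000)
  idc <- function(cycles) {
    d <- mutateDescendant(anc, pam = 30, cycles = cycles)
    keep <- !is.na(d$map)
    a <- strsplit(anc, "")[[1]][keep]
    b <- strsplit(d$seq, "")[[1]][d$map[keep]]
    mean(a == b)
  }
  set.seed(101); id_comp <- mean(replicate(5, idc("compressed")))
  set.seed(101); id_expl <- mean(replicate(5, idc("explicit")))
  se <- sqrt(0.75 * 0.25 / (5 * 2000))
  expect_lt(abs(id_comp - id_expl), 4 * se)
  expect_lt(abs(id_comp - expectedIdentity(30)), 4 * se)
})

test_that("descendant length conservation holds", {
  set.seed(42)
  for (pam in c(5, 30, 120)) {
    anc <- generateAncestor(150)
    d <- mutateDescendant(anc, pam)
    surv <- sum(!is.na(d$map))
    inserted <- nchar(d$seq) - surv
    expect_gte(inserted, 0)
    expect_identical(nchar(d$seq), surv + inserted)
    # mapped positions strictly increasing and inside the descendant
    ok <- d$map[!is.na(d$map)]
    if (length(ok) > 1) expect_true(all(diff(ok) > 0))
    expect_true(all(ok >= 1 & ok <= nchar(d$seq)))
    # map image has no duplicates: insertions are exactly its complement
    expect_identical(anyDuplicated(ok), 0L)
    expect_identical(length(setdiff(seq_len(nchar(d$seq)), ok)), inserted)
  }
})

test_that("evolvePair is deterministic and its branches are independent", {
  p1 <- evolvePair(60, length = 120, seed = 11)
  p2 <- evolvePair(60, length = 120, seed = 11)
  expect_identical(p1@s1, p2@s1)
  expect_identical(p1@s2, p2@s2)
  expect_identical(p1@map1, p2@map1)
  ts <- cached_set(60, 300)
  st <- testSetStats(ts)
  r <- stats::cor(st$pairs$id01, st$pairs$id02)
  expect_lt(abs(r), 0.15)
})

test_that("reference alignment composes the two position maps", {
  # no-event pair: identity alignment over the full length
  set.seed(42)
  pr0 <- evolvePair(0, length = 60, seed = 5)
  ref0 <- referenceAlignment(pr0)
  expect_identical(alignedPairs(ref0),
                   cbind(i = 1:60, j = 1:60))
  # hand-composed toy: ancestor AAAA, deletion at position 3 in branch 1
  # and at position 4 in branch 2
  toy <- new("EvolvedPair", ancestor = "AAAA", s1 = "AAA", s2 = "AAA",
             map1 = c(1L, 2L, NA, 3L), map2 = c(1L, 2L, 3L, NA),
             pam = 0)
  expect_identical(alignedPairs(referenceAlignment(toy)),
                   cbind(i = c(1L, 2L), j = c(1L, 2L)))
  # cardinality bound
  for (pam in c(30, 120)) {
    pr <- evolvePair(pam, length = 100, seed = pam)
    expect_lte(nAligned(referenceAlignment(pr)),
               min(nchar(pr@s1), nchar(pr@s2)))
  }
})

test_that("test sets are reproducible with derived per-pair seeds", {
  ts <- generateTestSet(30, n = 3, length = 80, seed = 9)
  # pair k uses seed (master + 1000003*k) mod (2^31 - 1)
  pr1 <- evolvePair(30, length = 80, seed = (9 + 1000003 * 1) %% 2147483647)
  expect_identical(ts[[1]]@s1, pr1@s1)
  expect_identical(ts[[1]]@s2, pr1@s2)
  ts2 <- generateTestSet(30, n = 3, length = 80, seed = 9)
  expect_identical(ts[[3]]@s2, ts2[[3]]@s2)
  expect_identical(length(ts), 3L)
})

test_that("divergent and sequential statistics are internally consistent", {
  st30 <- testSetStats(cached_set(30, 300))
  st60 <- testSetStats(cached_set(60, 300))
  st120 <- testSetStats(cached_set(120, 300))
  # two branches of `pam` compose to one branch of 2*pam
  n <- 300
  se <- function(x) stats::sd(x) / sqrt(length(x))
  comb <- sqrt(se(st30$pairs$id12)^2 +
               se(c(st60$pairs$id01, st60$pairs$id02))^2)
  expect_lt(abs(st30$divergentId - st60$sequentialId), 3 * comb)
  # visible substitutions saturate with distance
  expect_gt(st120$divergentId, randomIdentity())
  expect_lt(st120$divergentId, st120$sequentialId)
})
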