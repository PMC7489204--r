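# Divergent-evolution simulator. A test pair is built by drawing a random
# ancestor from the Dayhoff composition and evolving two descendants
# independently: first an indel stage (one Bernoulli event check per
# ancestor position, insertion-before vs deletion-from chosen equiprobably,
# Zipf-distributed lengths), then a substitution stage in which every
# surviving ancestral position passes through `pam` cycles of the PAM1
# transition. Because the cycles form a Markov chain, the default
# implementation composes them into a single draw from PAM1^pam per
# position — distributionally identical and much cheaper; the literal
# per-cycle path is kept behind `cycles = "explicit"`.

#' Draw a random ancestor sequence
#'
#' Independent draws from the background composition (a Bernoulli-scheme
#' sequence), default length 200 residues — a typical polypeptide length.
#'
#' @param length Number of residues (>= 1).
#' @param freqs Residue frequencies (default [dayhoffFrequencies()]).
#' @return Amino-acid sequence as a single string.
#' @examples
#' set.seed(1)
#' generateAncestor(30)
#' @export
generateAncestor <- function(length = 200, freqs = dayhoffFrequencies()) {
  stopifnot(length >= 1)
  .int_to_aa(sample.int(20L, length, replace = TRUE, prob = freqs))
}

#' Per-position indel event probability at a given PAM distance
#'
#' The empirical saturating law `0.0224 - 0.0219 * exp(-0.01168 * pam)`:
#' each ancestor position suffers an insertion-or-deletion event with this
#' probability during one branch of length `pam`. Monotone increasing,
#' bounded by 0.0224.
#'
#' @param pam Non-negative PAM distance(s).
#' @return Event probability, same length as `pam`.
#' @examples
#' indelProbability(c(0, 30, 120))
#' @export
indelProbability <- function(pam) {
  if (any(!is.finite(pam)) || any(pam < 0))
    stop("'pam' must be non-negative")
  0.0224 - 0.0219 * exp(-0.01168 * pam)
}

#' Draw indel lengths from a truncated Zipf distribution
#'
#' `P(L)` proportional to `L^-exponent` on `1..maxLen`. Indel length in
#' real alignments is well described by such a power law, independent of
#' evolutionary distance; the defaults (exponent 1.7, truncation at 50
#' residues) are the package's calibrated simulation conditions.
#'
#' @param n Number of draws.
#' @param exponent Power-law exponent (> 1).
#' @param maxLen Truncation point (>= 1).
#' @return Integer vector of lengths in `1..maxLen`.
#' @examples
#' set.seed(1)
#' table(sampleIndelLength(100))
#' @export
sampleIndelLength <- function(n = 1, exponent = 1.7, maxLen = 50) {
  if (!is.finite(exponent) || exponent <= 1)
    stop("'exponent' must be > 1")
  if (!is.finite(maxLen) || maxLen < 1 || maxLen != round(maxLen))
    stop("'maxLen' must be a positive integer")
  w <- (1:maxLen)^(-exponent)
  sample.int(as.integer(maxLen), n, replace = TRUE, prob = w)
}

#' Evolve one descendant from an ancestor sequence
#'
#' Stage 1 scans ancestor positions left to right; at each position an
#' indel event occurs with probability [indelProbability()]`(pam)`, its type
#' (insertion before the position vs deletion starting at it) chosen
#' equiprobably and its length drawn from the truncated Zipf law. Deleted
#' positions are not re-checked; insertions do not create new event sites;
#' deletions truncate at the sequence end. Stage 2 passes every surviving
#' ancestral position through `pam` cycles of the PAM1 transition (composed
#' into one draw from `PAM1^pam` unless `cycles = "explicit"`); inserted
#' residues, drawn from the background composition, are never mutated.
#'
#' @param ancestor Amino-acid sequence (single string).
#' @param pam Non-negative integer PAM distance.
#' @param freqs Background composition for inserted residues.
#' @param zipfExponent,zipfMax Indel length distribution parameters.
#' @param indelChecks 1 (default) for one event check per position with the
#'   type chosen 50/50; 2 for independent insertion and deletion checks.
#' @param cycles `"compressed"` (one draw from `PAM1^pam`) or `"explicit"`
#'   (literal per-cycle transitions); the two are distribution-identical.
#' @return List with elements `seq` (descendant string) and `map` (integer
#'   vector over ancestor positions: descendant position or NA if deleted).
#' @examples
#' set.seed(1)
#' d <- mutateDescendant(generateAncestor(50), pam = 30)
#' d$seq
#' @export
mutateDescendant <- function(ancestor, pam, freqs = dayhoffFrequencies(),
                             zipfExponent = 1.7, zipfMax = 50,
                             indelChecks = 1,
                             cycles = c("compressed", "explicit")) {
  cycles <- match.arg(cycles)
  if (length(pam) != 1L || !is.finite(pam) || pam < 0 || pam != round(pam))
    stop("'pam' must be a single non-negative integer")
  anc <- .aa_to_int(ancestor)
  L0 <- length(anc)
  p_event <- indelProbability(pam)

  # stage 1: indels
  ins_len <- integer(L0)
  deleted <- logical(L0)
  if (indelChecks == 1) {
    u <- stats::runif(L0)
    cand <- which(u < p_event)
    del_until <- 0L
    for (k in cand) {
      if (k <= del_until) next
      if (stats::runif(1) < 0.5) {
        ins_len[k] <- ins_len[k] +
          sampleIndelLength(1, zipfExponent, zipfMax)
      } else {
        len <- sampleIndelLength(1, zipfExponent, zipfMax)
        end <- min(L0, k + len - 1L)
        deleted[k:end] <- TRUE
        del_until <- end
      }
    }
  } else if (indelChecks == 2) {
    u_ins <- stats::runif(L0)
    u_del <- stats::runif(L0)
    del_until <- 0L
    for (k in seq_len(L0)) {
      if (u_ins[k] < p_event)
        ins_len[k] <- ins_len[k] + sampleIndelLength(1, zipfExponent, zipfMax)
      if (k <= del_until) next
      if (u_del[k] < p_event) {
        len <- sampleIndelLength(1, zipfExponent, zipfMax)
        end <- min(L0, k + len - 1L)
        deleted[k:end] <- TRUE
        del_until <- end
      }
    }
  } else stop("'indelChecks' must be 1 or 2")

  survive <- !deleted
  n_ins <- sum(ins_len)
  ins_res <- if (n_ins)
    sample.int(20L, n_ins, replace = TRUE, prob = freqs) else integer()

  # stage 2: substitutions on surviving ancestral positions
  res <- anc[survive]
  if (pam > 0 && length(res)) {
    if (cycles == "compressed") {
      pm <- probMatrix(pamProbability(pam))
      res <- .transition_draw(res, pm)
    } else {
      p1 <- .pam1()
      for (cycle in seq_len(pam)) res <- .transition_draw(res, p1)
    }
  }

  pos <- cumsum(ins_len + survive)
  map <- ifelse(survive, pos, NA_integer_)
  total <- n_ins + sum(survive)
  seq_int <- integer(total)
  seq_int[pos[survive]] <- res
  if (n_ins)
    seq_int[setdiff(seq_len(total), pos[survive])] <- ins_res
  list(seq = .int_to_aa(seq_int), map = as.integer(map))
}

# One row-stochastic transition applied to integer-coded residues,
# vectorized by grouping positions on their current residue.
.transition_draw <- function(res, pm) {
  out <- res
  for (a in 1:20) {
    idx <- which(res == a)
    if (length(idx))
      out[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = pm[a, ])
  }
  out
}

#' Evolve a divergent pair from a common ancestor
#'
#' Draws one ancestor and evolves two descendants independently with
#' [mutateDescendant()] at the same PAM distance, so the evolutionary
#' separation of the pair is roughly twice `pam`.
#'
#' @param pam Non-negative integer PAM distance per branch.
#' @param length Ancestor length in residues.
#' @param seed Optional seed fixing this pair's random stream.
#' @param ... Passed to [mutateDescendant()].
#' @param freqs Background composition.
#' @return An [EvolvedPair-class].
#' @examples
#' evolvePair(30, length = 60, seed = 7)
#' @export
evolvePair <- function(pam, length = 200, seed = NULL,
                       freqs = dayhoffFrequencies(), ...) {
  if (!is.null(seed)) set.seed(seed)
  anc <- generateAncestor(length, freqs)
  d1 <- mutateDescendant(anc, pam, freqs = freqs, ...)
  d2 <- mutateDescendant(anc, pam, freqs = freqs, ...)
  new("EvolvedPair", ancestor = anc, s1 = d1$seq, s2 = d2$seq,
      map1 = d1$map, map2 = d2$map, pam = as.numeric(pam))
}

#' Reference alignment induced by shared ancestral positions
#'
#' Positions of the two descendants that derive from the same ancestor
#' position are matched; everything else is a gap. This is the true
#' alignment the simulation defines, against which algorithmic alignments
#' are scored.
#'
#' @param pair An [EvolvedPair-class].
#' @return A [PairAlignment-class].
#' @examples
#' referenceAlignment(evolvePair(60, length = 80, seed = 1))
#' @export
referenceAlignment <- function(pair) {
  stopifnot(is(pair, "EvolvedPair"))
  keep <- !is.na(pair@map1) & !is.na(pair@map2)
  new("PairAlignment",
      i = pair@map1[keep], j = pair@map2[keep],
      len1 = nchar(pair@s1), len2 = nchar(pair@s2))
}

#' Ancestor-to-descendant alignment of an evolved pair
#'
#' The alignment of the ancestor with one descendant implied by the
#' position map — the "sequential evolution" comparison, used for
#' calibration statistics.
#'
#' @param pair An [EvolvedPair-class].
#' @param descendant 1 or 2.
#' @return A [PairAlignment-class] (first sequence = ancestor).
#' @export
ancestorAlignment <- function(pair, descendant = 1) {
  stopifnot(is(pair, "EvolvedPair"), descendant %in% c(1, 2))
  map <- slot(pair, paste0("map", descendant))
  keep <- !is.na(map)
  new("PairAlignment",
      i = which(keep), j = map[keep],
      len1 = nchar(pair@ancestor),
      len2 = nchar(slot(pair, paste0("s", descendant))))
}

#' Generate a reproducible test set of divergent pairs
#'
#' Each pair gets its own derived seed
#' `(seed + 1000003 * index) mod (2^31 - 1)`, so the set is reproducible
#' and independent of generation order.
#'
#' @param pam Non-negative integer PAM distance per branch.
#' @param n Number of pairs.
#' @param length Ancestor length in residues.
#' @param seed Master seed (integer).
#' @param ... Passed to [mutateDescendant()] via [evolvePair()].
#' @return A [TestSet-class].
#' @examples
#' ts <- generateTestSet(30, n = 5, length = 100, seed = 42)
#' testSetStats(ts)$divergentId
#' @export
generateTestSet <- function(pam, n = 1000, length = 200, seed = 1, ...) {
  stopifnot(n >= 1)
  pairs <- vector("list", n)
  for (k in seq_len(n))
    pairs[[k]] <- evolvePair(pam, length = length,
                             seed = .pair_seed(seed, k), ...)
  new("TestSet", pam = as.numeric(pam), seed = as.integer(seed),
      pairs = pairs)
}

.pair_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
}

#' Calibration statistics of a test set
#'
#' Per-pair and mean identity and indel fractions for the sequential
#' (ancestor vs descendant) and divergent (descendant vs descendant)
#' comparisons, plus the PAM distance the divergent identity corresponds to
#' on the identity-versus-distance curve.
#'
#' @param ts A [TestSet-class].
#' @return List with a per-pair data.frame (`pairs`) and the means
#'   `sequentialId`, `sequentialIndel`, `divergentId`, `divergentIndel`,
#'   `pamFromDivergentId`.
#' @export
testSetStats <- function(ts) {
  stopifnot(is(ts, "TestSet"))
  rows <- lapply(ts@pairs, function(pr) {
    a1 <- ancestorAlignment(pr, 1)
    a2 <- ancestorAlignment(pr, 2)
    rf <- referenceAlignment(pr)
    data.frame(
      id01 = identityFraction(a1, pr@ancestor, pr@s1),
      id02 = identityFraction(a2, pr@ancestor, pr@s2),
      indel01 = indelFraction(a1, pr@ancestor, pr@s1),
      indel02 = indelFraction(a2, pr@ancestor, pr@s2),
      id12 = identityFraction(rf, pr@s1, pr@s2),
      indel12 = indelFraction(rf, pr@s1, pr@s2))
  })
  df <- do.call(rbind, rows)
  list(pairs = df,
       sequentialId = mean(c(df$id01, df$id02)),
       sequentialIndel = mean(c(df$indel01, df$indel02)),
       divergentId = mean(df$id12),
       divergentIndel = mean(df$indel12),
       pamFromDivergentId = pamFromIdentity(mean(df$id12)))
}
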