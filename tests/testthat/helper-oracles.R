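# Independent oracles for the dynamic-programming aligner.
#
# The enumeration oracle scores every monotone set of residue pairs in
# closed form (summed pair scores minus gop + (L-1)*gep per maximal gap
# run) and takes the maximum — no dynamic programming involved, so it is
# an independent check of both DP modes. Feasible for sequences up to ~7
# residues (C(14,7) = 3432 pair sets at 7x7).

aa_int <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], aminoAlphabet())

gap_run_cost <- function(L, gop, gep) ifelse(L > 0, gop + (L - 1) * gep, 0)

score_pair_set <- function(pi, pj, n, m, sc, v1, v2, gop, gep, mode) {
  if (length(pi) == 0) {
    if (mode == "local") return(0)
    return(-gap_run_cost(n, gop, gep) - gap_run_cost(m, gop, gep))
  }
  s <- sum(sc[cbind(v1[pi], v2[pj])])
  if (length(pi) > 1)
    s <- s - sum(gap_run_cost(diff(pi) - 1, gop, gep)) -
             sum(gap_run_cost(diff(pj) - 1, gop, gep))
  if (mode == "global")
    s <- s - gap_run_cost(pi[1] - 1, gop, gep) -
             gap_run_cost(pj[1] - 1, gop, gep) -
             gap_run_cost(n - pi[length(pi)], gop, gep) -
             gap_run_cost(m - pj[length(pj)], gop, gep)
  s
}

enum_optimum <- function(s1, s2, m, gop, gep, mode) {
  v1 <- aa_int(s1); v2 <- aa_int(s2)
  n <- length(v1); mm <- length(v2)
  sc <- scores(m)
  best <- score_pair_set(integer(), integer(), n, mm, sc, v1, v2,
                         gop, gep, mode)
  for (k in seq_len(min(n, mm))) {
    ci <- utils::combn(n, k)
    cj <- utils::combn(mm, k)
    for (a in seq_len(ncol(ci))) {
      for (b in seq_len(ncol(cj))) {
        s <- score_pair_set(ci[, a], cj[, b], n, mm, sc, v1, v2,
                            gop, gep, mode)
        if (s > best) best <- s
      }
    }
  }
  best
}

# simple linear-gap DP (cost g per gap residue); equals the affine DP when
# gop == gep == g
linear_dp <- function(s1, s2, m, g, mode) {
  v1 <- aa_int(s1); v2 <- aa_int(s2)
  n <- length(v1); mm <- length(v2)
  sc <- scores(m)
  H <- matrix(0, n + 1, mm + 1)
  if (mode == "global") {
    H[, 1] <- -g * (0:n)
    H[1, ] <- -g * (0:mm)
  }
  best <- 0
  for (i in 1:n) for (j in 1:mm) {
    h <- max(H[i, j] + sc[v1[i], v2[j]], H[i, j + 1] - g, H[i + 1, j] - g)
    if (mode == "local") h <- max(h, 0)
    H[i + 1, j + 1] <- h
    if (h > best) best <- h
  }
  if (mode == "global") H[n + 1, mm + 1] else best
}

random_aa <- function(len) paste(sample(aminoAlphabet(), len, replace = TRUE),
                                 collapse = "")
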