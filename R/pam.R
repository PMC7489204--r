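# The PAM evolutionary model: probability tables at arbitrary distance,
# the identity-versus-distance curve, and its numeric inverse.

# 20x20 matrix power by repeated squaring (exact for integer exponents).
.mat_pow <- function(p, n) {
  out <- diag(nrow(p))
  dimnames(out) <- dimnames(p)
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% base
    base <- base %*% base
    n <- n %/% 2
  }
  out
}

#' PAM mutation-probability matrix at a given evolutionary distance
#'
#' Raises the bundled Dayhoff PAM1 mutation-probability matrix to the
#' `distance`-th power (distance 0 gives the identity table) and
#' renormalizes rows to cancel floating-point drift.
#'
#' @param distance Non-negative integer PAM distance.
#' @return A [PamProbability-class].
#' @examples
#' p <- pamProbability(30)
#' sum(dayhoffFrequencies() * diag(probMatrix(p)))  # expected identity
#' @export
pamProbability <- function(distance) {
  if (length(distance) != 1L || !is.finite(distance) || distance < 0 ||
      distance != round(distance))
    stop("'distance' must be a single non-negative integer (PAM units)")
  p <- .mat_pow(.pam1(), as.integer(distance))
  p <- p / rowSums(p)
  new("PamProbability", distance = as.numeric(distance), prob = p)
}

#' Expected sequence identity after a given PAM distance
#'
#' The probability that a position drawn from the background composition is
#' observed unchanged after `distance` PAM of point substitution:
#' `sum_a f_a * P^distance[a, a]`. Strictly decreasing in distance, and
#' bounded below by [randomIdentity()] in the infinite-distance limit.
#'
#' @param distance Non-negative integer PAM distance.
#' @param freqs Background frequencies (default [dayhoffFrequencies()]).
#' @return Expected identity fraction in (0, 1].
#' @examples
#' expectedIdentity(0)    # 1
#' expectedIdentity(30)   # about 0.75
#' @export
expectedIdentity <- function(distance, freqs = dayhoffFrequencies()) {
  p <- pamProbability(distance)
  sum(freqs * diag(probMatrix(p)))
}

#' Expected identity of two unrelated sequences
#'
#' The chance that two positions drawn independently from the same residue
#' composition coincide: `sum_i f_i^2`. For the Dayhoff composition this is
#' 0.0601, the infinite-distance floor of the identity-versus-PAM curve.
#'
#' @param freqs Background frequencies (must be positive and sum to 1).
#' @return Identity fraction.
#' @examples
#' randomIdentity(rep(1/20, 20))       # 0.05
#' randomIdentity(dayhoffFrequencies())
#' @export
randomIdentity <- function(freqs = dayhoffFrequencies()) {
  if (any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("'freqs' must be positive and sum to 1")
  sum(freqs^2)
}

# Identity-vs-distance lookup tables, cached. The directly tabulated range
# runs to 328 PAM (where the curve reaches ~15% identity); beyond that a
# monotone cubic through six anchor points at id = 0.15, 0.14, ..., 0.10
# extrapolates, and identities below 10% are reported as right-censored.
.pam_id_tables <- function(freqs) {
  key <- paste0("idtab_", paste(signif(freqs, 10), collapse = ","))
  if (!is.null(.submat_cache[[key]])) return(.submat_cache[[key]])
  p1 <- .pam1()
  ids <- numeric(2001)
  acc <- diag(20)
  ids[1L] <- sum(freqs * diag(acc))
  for (d in 1:2000) {
    acc <- acc %*% p1
    ids[d + 1L] <- sum(freqs * diag(acc))
  }
  d_all <- 0:2000
  # guard against floating-point plateaus near the asymptote
  bad <- which(diff(ids) >= 0)
  if (length(bad)) {
    ids <- ids[seq_len(bad[1L])]
    d_all <- d_all[seq_len(bad[1L])]
  }
  # inverse over the full computed curve (used to place the anchors)
  inv_all <- stats::splinefun(rev(ids), rev(d_all), method = "hyman")
  id_tab_limit <- ids[329L]             # identity at 328 PAM
  anchors_id <- seq(0.15, 0.10, by = -0.01)
  anchors_id <- anchors_id[anchors_id >= min(ids)]
  anchors_d <- inv_all(anchors_id)
  tabs <- list(
    ids = ids, d = d_all,
    inv_tab = stats::splinefun(rev(ids[1:329]), rev(d_all[1:329]),
                               method = "hyman"),
    id_tab_limit = id_tab_limit,
    extrap = stats::splinefun(rev(anchors_id), rev(anchors_d),
                              method = "hyman"),
    id_floor = min(anchors_id),
    d_ceiling = max(anchors_d)
  )
  .submat_cache[[key]] <- tabs
  tabs
}

#' PAM distance corresponding to an observed identity fraction
#'
#' Numeric inverse of [expectedIdentity()]. Identities down to 15% are
#' inverted on the directly tabulated curve (up to 328 PAM); identities in
#' [10%, 15%) use a monotone cubic extrapolation through six anchor points
#' of the extended curve; identities below 10% saturate the usable range
#' and are returned as a right-censored bound, marked by the `"censored"`
#' attribute and rendered as `"> X"` by [formatPam()].
#'
#' @param id Identity fraction(s) in (0, 1].
#' @param freqs Background frequencies (default [dayhoffFrequencies()]).
#' @return Numeric PAM distance(s), with logical attribute `"censored"`.
#' @examples
#' pamFromIdentity(1)                         # 0
#' pamFromIdentity(expectedIdentity(120))     # 120
#' @export
pamFromIdentity <- function(id, freqs = dayhoffFrequencies()) {
  if (any(!is.finite(id)) || any(id <= 0) || any(id > 1))
    stop("'id' must lie in (0, 1]")
  tabs <- .pam_id_tables(freqs)
  out <- numeric(length(id))
  cens <- logical(length(id))
  for (k in seq_along(id)) {
    x <- id[k]
    if (x >= tabs$ids[1L]) {
      out[k] <- 0
    } else if (x >= tabs$id_tab_limit) {
      out[k] <- tabs$inv_tab(x)
    } else if (x >= tabs$id_floor) {
      out[k] <- tabs$extrap(x)
    } else {
      out[k] <- tabs$d_ceiling
      cens[k] <- TRUE
    }
  }
  out <- pmax(out, 0)
  attr(out, "censored") <- cens
  out
}

#' Render a (possibly right-censored) PAM distance
#'
#' @param pam Output of [pamFromIdentity()].
#' @param digits Rounding for the printed value.
#' @return Character vector; censored values render as `"> X"`.
#' @examples
#' formatPam(pamFromIdentity(0.38))
#' @export
formatPam <- function(pam, digits = 2) {
  cens <- attr(pam, "censored")
  if (is.null(cens)) cens <- rep(FALSE, length(pam))
  ifelse(cens, paste0("> ", round(as.numeric(pam))),
         formatC(round(as.numeric(pam), digits), format = "fg"))
}

#' Generate a log-odds score matrix from the Dayhoff PAM model
#'
#' Builds the score table `s(a, b) = log[ P^distance(a, b) / f_b ]` on the
#' chosen scale, symmetrized and rounded to integers as the published PAM
#' series are. `"halfbit"` matches the scale of the NCBI PAM distribution
#' files bundled with the package; `"dayhoff"` is the original
#' 10 * log10 scale. Generated tables can differ from the published ones
#' by rounding; the bundled canonical files are the benchmark default.
#'
#' @param distance Positive integer PAM distance.
#' @param scale `"halfbit"` or `"dayhoff"`.
#' @param freqs Background frequencies (default [dayhoffFrequencies()]).
#' @param round Round scores to integers (default TRUE, as published).
#' @return A [SubstitutionMatrix-class] named `"PAM<distance>_gen"`.
#' @examples
#' m <- pamLogOdds(250)
#' scores(m)["W", "W"]
#' @export
pamLogOdds <- function(distance, scale = c("halfbit", "dayhoff"),
                       freqs = dayhoffFrequencies(), round = TRUE) {
  scale <- match.arg(scale)
  p <- probMatrix(pamProbability(distance))
  odds <- sweep(p, 2, freqs, "/")
  lo <- switch(scale,
    halfbit = log2(odds) / 0.5,
    dayhoff = 10 * log10(odds))
  lo <- (lo + t(lo)) / 2
  if (round) lo <- round(lo)
  new("SubstitutionMatrix",
      name = paste0("PAM", distance, "_gen"), scores = lo,
      metadata = paste0("Generated from the Dayhoff PAM1 model at distance ",
                        distance, " (", scale, " units)"))
}
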