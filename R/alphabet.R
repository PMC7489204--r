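# Package-wide constants and bundled Dayhoff model tables.
# The alphabet order is the classical Dayhoff/NCBI matrix order and is fixed
# for every matrix, probability table and integer-coded sequence in the
# package.

.submat_cache <- new.env(parent = emptyenv())

.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The package amino-acid alphabet
#'
#' Twenty one-letter residue codes in the classical Dayhoff matrix order
#' (`A R N D C Q E G H I L K M F P S T W Y V`). All score matrices,
#' probability tables and integer-coded sequences in the package are indexed
#' in this order.
#'
#' @return Character vector of 20 residue codes.
#' @examples
#' aminoAlphabet()
#' @export
aminoAlphabet <- function() .AA_ORDER

#' Dayhoff amino-acid background frequencies
#'
#' The 1978 Dayhoff composition table bundled with the package, renormalized
#' to sum exactly to 1 (the printed values sum to 1.001).
#'
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @examples
#' f <- dayhoffFrequencies()
#' sum(f)
#' randomIdentity(f)
#' @export
dayhoffFrequencies <- function() {
  if (is.null(.submat_cache$freqs)) {
    path <- system.file("extdata", "dayhoff_freqs.txt",
                        package = "SubMatBench", mustWork = TRUE)
    tab <- utils::read.table(path, comment.char = "#", row.names = 1)
    f <- stats::setNames(tab[[1L]], rownames(tab))[.AA_ORDER]
    stopifnot(all(f > 0))
    .submat_cache$freqs <- f / sum(f)
  }
  .submat_cache$freqs
}

# Bundled Dayhoff PAM1 table in row-stochastic orientation:
# P[a, b] = P(ancestor residue a observed as b after 1 PAM).
.pam1 <- function() {
  if (is.null(.submat_cache$pam1)) {
    path <- system.file("extdata", "dayhoff_pam1.txt",
                        package = "SubMatBench", mustWork = TRUE)
    tab <- utils::read.table(path, comment.char = "#", header = TRUE,
                             row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)[.AA_ORDER, .AA_ORDER]
    p <- t(m) / 1e4            # printed columns are the source residue
    p <- p / rowSums(p)        # cancel printed-table rounding
    .submat_cache$pam1 <- p
  }
  .submat_cache$pam1
}

# Integer coding of sequences: 1..20 in alphabet order.
.aa_to_int <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1L]], .AA_ORDER)
  if (anyNA(v))
    stop("sequence contains symbols outside the 20-letter amino-acid alphabet")
  v
}

.int_to_aa <- function(v) paste(.AA_ORDER[v], collapse = "")
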