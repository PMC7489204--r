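#' Read a substitution matrix in NCBI/EMBOSS square text format
#'
#' Parses the standard square-matrix layout used by the NCBI and EMBOSS
#' distributions: `#` comment lines, a header row of residue symbols, then
#' one score row per residue. Extra columns such as `B`, `Z`, `X` and `*`
#' are accepted and dropped; the 20 standard residues must all be present.
#' Numerically asymmetric input is symmetrized by averaging when the
#' asymmetry is at most `1e-6`, and rejected otherwise.
#'
#' @param file Path to the matrix file, or a character vector of lines.
#' @param name Matrix name; defaults to the file base name.
#' @return A [SubstitutionMatrix-class].
#' @examples
#' m <- scoreMatrix("BLOSUM62")
#' scores(m)["W", "W"]
#' @seealso [writeScoreMatrix()], [scoreMatrix()]
#' @export
readScoreMatrix <- function(file, name = NULL) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file)
    if (is.null(name))
      name <- sub("\\.[^.]*$", "", basename(file))
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    if (is.null(name)) name <- "matrix"
  }
  meta <- sub("^#\\s?", "", lines[startsWith(trimws(lines), "#")])
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix format error: need a header row and at least one score row")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  alpha <- aminoAlphabet()
  missing_col <- setdiff(alpha, header)
  if (length(missing_col))
    stop("matrix format error: missing column(s) for residue(s) ",
         paste(missing_col, collapse = ", "))
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  row_sym <- vapply(rows, `[`, character(1), 1L)
  missing_row <- setdiff(alpha, row_sym)
  if (length(missing_row))
    stop("matrix format error: missing row(s) for residue(s) ",
         paste(missing_row, collapse = ", "))
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (length(v) != length(header) || anyNA(v))
      stop("matrix format error: row '", r[1L], "' has ", length(v),
           " scores for ", length(header), " columns")
    v
  })
  full <- do.call(rbind, vals)
  dimnames(full) <- list(row_sym, header)
  m <- full[alpha, alpha]
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop("matrix integrity error: asymmetry ", format(asym),
         " exceeds tolerance 1e-6")
  m <- (m + t(m)) / 2
  new("SubstitutionMatrix", name = name, scores = m, metadata = meta)
}

#' Write a substitution matrix in NCBI/EMBOSS square text format
#'
#' Integer-valued tables are written as integers so that bundled canonical
#' files round-trip identically through [readScoreMatrix()].
#'
#' @param m A [SubstitutionMatrix-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeScoreMatrix <- function(m, file) {
  stopifnot(is(m, "SubstitutionMatrix"))
  s <- scores(m)
  alpha <- aminoAlphabet()
  fmt <- function(x) {
    if (max(abs(x - round(x))) < 1e-9) sprintf("%3d", as.integer(round(x)))
    else sprintf("%6.2f", x)
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (line in m@metadata) writeLines(paste("#", line), con)
  writeLines(paste0("  ", paste(sprintf("%3s", alpha), collapse = " ")), con)
  for (a in alpha)
    writeLines(paste0(a, " ", paste(fmt(s[a, ]), collapse = " ")), con)
  invisible(file)
}
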