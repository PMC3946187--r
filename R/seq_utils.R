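# IUPAC nucleotide machinery. Bases are encoded as 4-bit masks
# (A=1, C=2, G=4, T/U=8); an ambiguity code is the OR of its expansion,
# and two codes are compatible iff their masks intersect.

.iupac_masks <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.iupac_lookup <- local({
  tab <- rep(NA_integer_, 128)
  codes <- utf8ToInt(paste(names(.iupac_masks), collapse = ""))
  tab[codes + 1L] <- unname(.iupac_masks)
  tab
})

#' Validate an IUPAC nucleotide string
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return invisibly TRUE; errors on the first illegal character,
#'   reporting its 1-based offset.
#' @export
validate_iupac <- function(x, what = "sequence") {
  for (i in seq_along(x)) {
    codes <- utf8ToInt(toupper(x[i]))
    if (length(codes) == 0) stop(what, " ", i, " is empty")
    bad <- which(is.na(.iupac_lookup[codes + 1L]))
    if (length(bad) > 0) {
      stop(sprintf("illegal character '%s' in %s %d at offset %d",
                   intToUtf8(codes[bad[1]]), what, i, bad[1]))
    }
  }
  invisible(TRUE)
}

# string -> integer mask vector (NA for illegal characters)
seq_to_mask <- function(x) {
  .iupac_lookup[utf8ToInt(toupper(x)) + 1L]
}

#' Reverse complement of an IUPAC string
#'
#' @param x character vector of IUPAC nucleotide strings.
#' @return character vector of reverse complements (upper case).
#' @export
revcomp <- function(x) {
  validate_iupac(x)
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Number of exact sequences a degenerate primer expands to
#'
#' Product of the per-base IUPAC cardinalities (N contributes 4, R
#' contributes 2, ...).
#'
#' @param primer IUPAC string.
#' @return integer expansion count.
#' @export
degeneracy <- function(primer) {
  validate_iupac(primer, "primer")
  m <- seq_to_mask(primer)
  # popcount of 4-bit masks
  card <- vapply(m, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0), 0L)
  prod(card)
}

#' Expand a degenerate IUPAC string to all exact sequences
#'
#' Brute-force expansion; intended for small degeneracies (testing and
#' oracle checks).
#'
#' @param primer IUPAC string.
#' @return character vector of plain ACGT sequences.
#' @export
expand_iupac <- function(primer) {
  validate_iupac(primer, "primer")
  sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(primer), "")[[1]]
  combos <- expand.grid(lapply(chars, function(ch) sets[[ch]]),
                        stringsAsFactors = FALSE)
  apply(combos, 1, paste, collapse = "")
}

# Ungapped identity between two sequences: the shorter sequence is slid
# along the longer at every full-overlap offset; identity is the maximal
# number of exactly matching positions divided by the shorter length.
# Ambiguity codes must match literally (cd-hit-like strictness).
seq_identity <- function(a, b) {
  va <- utf8ToInt(toupper(a))
  vb <- utf8ToInt(toupper(b))
  if (length(va) > length(vb)) { tmp <- va; va <- vb; vb <- tmp }
  s <- length(va); l <- length(vb)
  best <- 0L
  for (off in 0:(l - s)) {
    m <- sum(va == vb[(1 + off):(s + off)])
    if (m > best) best <- m
    if (best == s) break
  }
  best / s
}
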