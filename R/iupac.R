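# IUPAC nucleotide ambiguity codes as 4-bit masks (A=1, C=2, G=4, T=8).
# Kept in R (mirroring src/align.cpp) for base calling and motif matching.

.IUPAC_MASKS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# mask (1..15) -> single-letter code; index i is the code whose mask is i
.IUPAC_CODES <- c("A", "C", "M", "G", "R", "S", "V",
                  "T", "W", "Y", "H", "K", "D", "B", "N")

#' Convert nucleotide characters to IUPAC bit masks
#'
#' Each base maps to a 4-bit set over {A, C, G, T} (A=1, C=2, G=4, T=8);
#' ambiguity codes map to the union of their bases (e.g. M = A|C = 3).
#'
#' @param x character vector of single characters, or a single string which
#'   is split into characters.
#' @return integer vector of masks in 1..15.
#' @seealso [iupac_code()], [iupac_match()]
#' @export
iupac_mask <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  m <- .IUPAC_MASKS[toupper(x)]
  if (anyNA(m)) {
    bad <- unique(x[is.na(m)])
    stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' IUPAC code for a set of bases
#'
#' @param mask integer vector of masks in 1..15 (see [iupac_mask()]).
#' @return character vector of single-letter codes.
#' @export
iupac_code <- function(mask) {
  if (any(mask < 1L | mask > 15L)) stop("mask out of range 1..15")
  .IUPAC_CODES[mask]
}

#' Do two IUPAC characters share at least one base?
#'
#' An ambiguity code matches a plain base when the base is contained in the
#' code's set; two codes match when their sets intersect.
#'
#' @param a,b character vectors of IUPAC characters (recycled).
#' @return logical vector.
#' @export
iupac_match <- function(a, b) {
  bitwAnd(iupac_mask(a), iupac_mask(b)) > 0L
}

#' Locate a motif in a nucleotide string
#'
#' All start positions (1-based) where `motif` (plain A/C/G/T) occurs in
#' `seq`. With `iupac = TRUE` the match is IUPAC-aware: a motif base
#' matches an ambiguous sequence character whose set contains it.
#' Overlapping occurrences are counted.
#'
#' @param seq nucleotide string to search.
#' @param motif motif string.
#' @param iupac IUPAC-aware matching flag.
#' @return integer vector of start positions.
#' @export
find_motif <- function(seq, motif, iupac = FALSE) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(motif, "", fixed = TRUE)[[1]]
  n <- length(s); k <- length(p)
  if (k == 0L || k > n) return(integer(0))
  sm <- iupac_mask(s)
  pm <- iupac_mask(p)
  hits <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    win <- sm[i:(i + k - 1L)]
    ok <- if (iupac) all(bitwAnd(win, pm) > 0L) else all(win == pm)
    if (ok) hits <- c(hits, i)
  }
  hits
}
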