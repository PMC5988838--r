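#' Global-alignment percent identity
#'
#' Needleman-Wunsch global alignment with affine gaps (Gotoh), the in-repo
#' replacement for a local BLAST search: queries and references are the
#' same near-full-length marker region, where local and global identity
#' coincide. Scoring: match +1, mismatch -1, gap open -2, gap extend -1 (a
#' gap of length g costs 2 + (g-1)). A query IUPAC ambiguity code matches a
#' reference base contained in its set. Identity is matched columns over
#' all aligned columns (gap columns included, the BLAST convention), in
#' percent. Traceback ties are broken deterministically: diagonal, then up,
#' then left.
#'
#' @param seq_a query nucleotide string (IUPAC codes permitted).
#' @param seq_b reference nucleotide string.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `identity` (percent), `alignment_length`, `matches`,
#'   `score`.
#' @examples
#' pairwise_identity("ACGT", "ACGT")$identity  # 100
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap_open = -2, gap_extend = -1) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L)
    stop("seq_a and seq_b must be single strings")
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("empty sequence")
  res <- nw_align_c(seq_a, seq_b, match, mismatch, gap_open, gap_extend)
  res$alignment_length <- as.integer(res$alignment_length)
  res$matches <- as.integer(res$matches)
  res
}
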